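test_that("trace generator honors configured responder counts and determinism", {
  cfg <- trace_gen_config(n_cells = 40, responder_fraction = 0, seed = 11)
  s0 <- gen_traces(cfg)
  expect_false(any(s0$truth$responder))

  cfg1 <- trace_gen_config(n_cells = 40, responder_fraction = 0.25, seed = 12)
  s1 <- gen_traces(cfg1)
  expect_identical(sum(s1$truth$responder), 10L)  # exact, by construction

  s1b <- gen_traces(cfg1)
  expect_identical(s1$traces, s1b$traces)  # same seed, bit-identical
  expect_identical(s1$truth, s1b$truth)

  # different seed differs
  cfg2 <- trace_gen_config(n_cells = 40, responder_fraction = 0.25, seed = 13)
  expect_false(identical(gen_traces(cfg2)$traces, s1$traces))
})

test_that("trace generator rejects windows that do not fit in the sweep", {
  expect_error(trace_gen_config(n_cells = 5, stimulus_onsets_s = 16.5),
               "fit within the sweep")
  expect_error(trace_gen_config(n_cells = 5, responder_fraction = 1.5),
               "responder_fraction")
})

test_that("saturated noise-free responders always exceed any finite threshold", {
  cfg <- trace_gen_config(n_cells = 10, responder_fraction = 1,
                          transient_amplitude_sd_units = 10,
                          baseline_sd = 1e-9, seed = 3)
  s <- gen_traces(cfg)
  calls <- analyze_session(s)
  oct <- calls[calls$odor == "OCT", ]
  expect_true(all(oct$responded))
})

test_that("cohort allocation pins the pooled responder count exactly", {
  cfg <- trace_gen_config(n_cells = 30, responder_fraction = 0.058)
  sessions <- gen_imaging_cohort(16, cfg, seed = 5)
  total_resp <- sum(vapply(sessions, function(s) sum(s$truth$responder),
                           integer(1)))
  expect_identical(total_resp, as.integer(round(0.058 * 16 * 30)))
})

test_that("movie painting reproduces the generating trace inside each ROI", {
  cfg <- trace_gen_config(n_cells = 3, responder_fraction = 1,
                          transient_amplitude_sd_units = 6, seed = 21)
  mv <- gen_movie(cfg, image_shape = c(64, 64), pixel_noise_sd = 0)
  for (i in 1:3) {
    roi_mean <- apply(mv$stack, 3, function(fr) mean(fr[mv$masks[[i]]]))
    expect_equal(roi_mean, mv$session$traces[i, , mv$sweep],
                 tolerance = 1e-12)
  }
  # background is the constant baseline
  bg <- !Reduce(`|`, mv$masks)
  bg_sd <- apply(mv$stack, 3, function(fr) stats::sd(fr[bg]))
  expect_true(all(bg_sd == 0))
})

test_that("movie ROI means track traces within pixel-noise tolerance", {
  cfg <- trace_gen_config(n_cells = 2, responder_fraction = 1,
                          transient_amplitude_sd_units = 6, seed = 22)
  mv <- gen_movie(cfg, image_shape = c(64, 64), pixel_noise_sd = 0.5)
  npx <- sum(mv$masks[[1]])
  tol <- 5 * 0.5 / sqrt(npx)
  roi_mean <- apply(mv$stack, 3, function(fr) mean(fr[mv$masks[[1]]]))
  expect_true(max(abs(roi_mean - mv$session$traces[1, , 1])) < tol)
  expect_error(gen_movie(trace_gen_config(n_cells = 500), c(32, 32)),
               "too small")
})

test_that("T-maze generator matches its closed-form expectations", {
  # pure odor bias: single-group indices near +/-40, reciprocal mean near 0
  cfg <- tmaze_gen_config(n_flies_per_group = 4000, odor_bias = 0.4,
                          n_reciprocal_pairs = 40, seed = 31)
  pairs <- gen_tmaze_counts(cfg)
  pa <- vapply(pairs, function(p) performance_index(p$group_a), numeric(1))
  pb <- vapply(pairs, function(p) performance_index(p$group_b), numeric(1))
  fin <- vapply(pairs, function(p) reciprocal_average(p)$value, numeric(1))
  # binomial SE of a group index at p=0.7: 100*2*sqrt(p(1-p)/n)
  se_group <- 200 * sqrt(0.7 * 0.3 / 4000) / sqrt(40)
  expect_lt(abs(mean(pa) - 40), 3 * se_group)
  expect_lt(abs(mean(pb) + 40), 3 * se_group)
  expect_lt(abs(mean(fin) - expected_final_peri(0, 0.4)), 3 * se_group)

  # pure memory: final index near 50
  cfg2 <- tmaze_gen_config(n_flies_per_group = 4000,
                           latent_memory_strength = 0.5,
                           n_reciprocal_pairs = 40, seed = 32)
  fin2 <- vapply(gen_tmaze_counts(cfg2),
                 function(p) reciprocal_average(p)$value, numeric(1))
  expect_lt(abs(mean(fin2) - 50), 3 * se_group)

  # conservation: arm counts sum to group size
  g <- pairs[[1]]$group_a
  expect_identical(g$n_cs_plus_arm + g$n_cs_minus_arm, 4000L)
})

test_that("T-maze config rejects probabilities pushed outside [0,1]", {
  expect_error(tmaze_gen_config(latent_memory_strength = 0.8,
                                odor_bias = 0.8),
               "outside \\[0, 1\\]")
})

test_that("arena generator conserves flies and follows the protocol", {
  cfg <- arena_gen_config(n_flies = 20, n_trials = 3, seed = 41)
  series <- gen_arena_series(cfg)
  expect_length(series, 3)
  for (s in series) {
    expect_true(all(rowSums(s[, c("q1", "q2", "q3", "q4")]) == 20))
    expect_identical(
      s$illuminated_pair,
      rep(c("none", "pairA", "none", "pairB"), each = 30))
  }
  # determinism
  series_b <- gen_arena_series(arena_gen_config(n_flies = 20, n_trials = 3,
                                                seed = 41))
  expect_identical(series[[2]]$q1, series_b[[2]]$q1)
})

test_that("arena stationary occupancy matches the configured light bias", {
  cfg <- arena_gen_config(n_trials = 150, light_bias = -0.25, seed = 42)
  pis <- vapply(gen_arena_series(cfg),
                function(s) total_light_pi(s)$total_pi, numeric(1))
  se <- stats::sd(pis) / sqrt(length(pis))
  expect_lt(abs(mean(pis) - (-25)), 3 * se)

  cfg0 <- arena_gen_config(n_trials = 150, light_bias = 0, seed = 43)
  pis0 <- vapply(gen_arena_series(cfg0),
                 function(s) total_light_pi(s)$total_pi, numeric(1))
  expect_lt(abs(mean(pis0)), 3 * stats::sd(pis0) / sqrt(length(pis0)))
})

test_that("hemisphere count generator is calibrated and respects its limits", {
  # law-of-large-numbers mean recovery
  cfg <- count_gen_config(n_flies = 10000, mean_cells_per_hemisphere = 5,
                          dispersion = 0.2, seed = 51)
  counts <- gen_hemisphere_counts(cfg)
  se <- sqrt((5 + 0.2 * 25) / 10000)
  expect_lt(abs(mean(counts$left) - 5), 3 * se)
  expect_true(all(counts$left >= 0 & counts$left == round(counts$left)))

  # degenerate noise: deterministic counts
  cfg0 <- count_gen_config(n_flies = 20, mean_cells_per_hemisphere = 4.6,
                           dispersion = 0, seed = 52)
  c0 <- gen_hemisphere_counts(cfg0)
  expect_true(all(c0$left == 5 & c0$right == 5))

  # zero bias: right/left exceedance symmetric
  b <- hemisphere_bias(counts)
  p_hat <- b$fraction_right_biased
  n_nontie <- b$n_right_biased + b$n_left_biased
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / n_nontie))

  # multiplicative right bias raises the right mean
  cfgb <- count_gen_config(n_flies = 5000, mean_cells_per_hemisphere = 5,
                           dispersion = 0.1, right_bias = 0.3, seed = 53)
  cb <- gen_hemisphere_counts(cfgb)
  expect_gt(mean(cb$right), mean(cb$left))
  bb <- hemisphere_bias(cb)
  expect_gt(bb$fraction_right_biased, 0.5)
})

test_that("generated artifacts round-trip through their readers", {
  tmp <- withr::local_tempdir()

  s <- gen_traces(trace_gen_config(n_cells = 6, responder_fraction = 0.5,
                                   seed = 61))
  write_traces(s, tmp, prefix = "rt")
  s2 <- read_traces(file.path(tmp, "rt.csv"))
  expect_equal(s2$traces, s$traces, tolerance = 1e-12)
  expect_identical(s2$sweeps$odor, s$sweeps$odor)
  expect_identical(s2$frame_rate_hz, s$frame_rate_hz)
  expect_equal(s2$truth$responder, s$truth$responder)

  pairs <- gen_tmaze_counts(tmaze_gen_config(seed = 62))
  f <- file.path(tmp, "tm.csv")
  write_tmaze_counts(pairs, f)
  pairs2 <- read_tmaze_counts(f)
  expect_identical(pairs2[[3]]$group_a$n_cs_minus_arm,
                   pairs[[3]]$group_a$n_cs_minus_arm)
  expect_equal(reciprocal_average(pairs2[[1]])$value,
               reciprocal_average(pairs[[1]])$value)

  series <- gen_arena_series(arena_gen_config(n_trials = 2, seed = 63))
  fa <- file.path(tmp, "ar.csv")
  write_arena_series(series, fa)
  series2 <- read_arena_series(fa)
  expect_equal(total_light_pi(series2[[2]])$total_pi,
               total_light_pi(series[[2]])$total_pi)

  counts <- gen_hemisphere_counts(count_gen_config(n_flies = 25, seed = 64))
  fh <- file.path(tmp, "hc.csv")
  write_hemisphere_counts(counts, fh)
  counts2 <- read_hemisphere_counts(fh)
  expect_identical(counts2$left, counts$left)

  # TIFF round-trip at 16-bit quantization tolerance
  mv <- gen_movie(trace_gen_config(n_cells = 2, seed = 65), c(48, 48))
  ft <- file.path(tmp, "mv.tif")
  sc <- write_movie_tiff(mv, ft)
  stack2 <- read_movie_tiff(ft, offset = sc$offset, scale = sc$scale)
  expect_lt(max(abs(stack2 - mv$stack)), sc$scale / 2^15)
})
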
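test_that("dF/F normalization matches its defining formula", {
  # constant trace: dff identically 0, zero baseline SD
  nt <- normalize_dff(rep(80, 140))
  expect_equal(nt$dff, rep(0, 140))
  expect_equal(nt$baseline_sd, 0)

  # direct evaluation: f0 = 100, a 150 sample gives dff = 0.5
  f <- rep(100, 140); f[60] <- 150
  nt2 <- normalize_dff(f)
  expect_equal(nt2$f0, 100)
  expect_equal(nt2$dff[60], 0.5)

  # baseline-mean invariant: dff over baseline frames has mean ~ 0
  set.seed(71)
  nt3 <- normalize_dff(rnorm(140, 100, 5))
  expect_lt(abs(mean(nt3$dff[1:28])), 1e-12)

  expect_error(normalize_dff(rep(100, 20)), "shorter than baseline")
  expect_error(normalize_dff(rep(0, 140)), "positive")
  expect_error(normalize_dff(rep(-5, 140)), "positive")
})

test_that("running average is centered with symmetrically shrinking edges", {
  # constant unchanged
  expect_equal(smooth_running(rep(3, 9)), rep(3, 9))
  # impulse: 0.2 at 0-based positions 2..6
  imp <- c(0, 0, 0, 0, 1, 0, 0, 0, 0)
  expect_equal(smooth_running(imp),
               c(0, 0, 0.2, 0.2, 0.2, 0.2, 0.2, 0, 0))
  # linear ramp unchanged everywhere (symmetric window, shrinking edges)
  expect_equal(smooth_running(as.numeric(1:10)), as.numeric(1:10))
  expect_error(smooth_running(1:10, window = 4), "odd")
  expect_error(smooth_running(1:3, window = 5), "length")
})

test_that("response scoring follows peak > 2.33 x baseline SD on 0-4.5 s", {
  ev <- list(odor_label = "OCT", onset_s = 5, presentation_index = 1L)
  # noise-free flat trace: zero peak, strict inequality, no response
  nt <- normalize_dff(rep(100, 140))
  call <- detect_response(nt, ev)
  expect_false(call$responded)
  expect_equal(call$threshold, 0)
  expect_identical(call$window_frames, c(35, 66))  # round(5*7), round(9.5*7)

  # 10 x SD injected transient is detected
  set.seed(72)
  cfg <- trace_gen_config(n_cells = 1, responder_fraction = 1,
                          transient_amplitude_sd_units = 10, seed = 73)
  s <- gen_traces(cfg)
  nt2 <- normalize_dff(s$traces[1, , 1])
  expect_true(detect_response(nt2, ev)$responded)

  # window beyond sweep is an input error
  expect_error(detect_response(nt, list(onset_s = 18)), "beyond the sweep")

  # tie at threshold is not a response: engineer peak == 2.33 * sd
  nt3 <- nt2
  nt3$smoothed <- rep(0, 140); nt3$smoothed[40] <- 2.33
  nt3$baseline_sd <- 1
  expect_false(detect_response(nt3, ev)$responded)
})

test_that("detection is invariant to positive rescaling of the raw trace", {
  set.seed(74)
  f <- rnorm(140, 100, 5) + 30 * c(rep(0, 40), exp(-(1:100) / 10))
  ev <- list(odor_label = "OCT", onset_s = 5, presentation_index = 1L)
  for (a in c(0.01, 1, 250)) {
    nt <- normalize_dff(a * f)
    call <- detect_response(nt, ev)
    ref <- detect_response(normalize_dff(f), ev)
    expect_equal(call$peak_value, ref$peak_value, tolerance = 1e-12)
    expect_equal(call$threshold, ref$threshold, tolerance = 1e-12)
    expect_identical(call$responded, ref$responded)
  }
})

test_that("detect_response agrees exactly with a brute-force oracle", {
  set.seed(75)
  for (case in 1:1000) {
    n <- sample(60:200, 1)
    rate <- runif(1, 4, 10)
    max_onset <- (n - 1) / rate - 4.6
    onset <- runif(1, 0, max(0.1, max_onset))
    f <- rnorm(n, 100, 5)
    if (runif(1) < 0.5) {  # sometimes add a transient of random size
      t <- (seq_len(n) - 1) / rate - onset
      f <- f + runif(1, 0, 30) * ifelse(t < 0, 0, exp(-t / 0.4) - exp(-t / 0.1))
    }
    nt <- normalize_dff(f, frame_rate_hz = rate)
    got <- detect_response(nt, list(onset_s = onset))
    want <- brute_force_detect(f, onset, rate)
    expect_equal(got$peak_value, want$peak, tolerance = 1e-12)
    expect_identical(got$responded, want$responded)
  }
})

test_that("detection probability is nondecreasing in injected amplitude", {
  set.seed(76)
  n_tr <- 150
  noise <- matrix(rnorm(n_tr * 140, 100, 5), nrow = n_tr)
  t <- (0:139) / 7 - 5
  kern <- ifelse(t < 0, 0, exp(-t / 0.4) - exp(-t / 0.1))
  kern <- kern / max(kern)
  rates <- vapply(c(0, 1, 2, 3, 4, 5, 6, 8), function(a) {
    m <- noise + 5 * a * matrix(kern, n_tr, 140, byrow = TRUE)
    s <- session_from_matrix(m)
    mean(analyze_session(s)$responded)
  }, numeric(1))
  # same noise realization under every amplitude: exactly monotone
  expect_true(all(diff(rates) >= 0))
  expect_equal(rates[1], 0, tolerance = 0.02)   # near-zero false positives
  expect_gt(rates[length(rates)], 0.99)
})

test_that("stimulus-specificity uses the 2-of-3 rule with indeterminate guard", {
  mk <- function(outcomes, odor = "OCT")
    data.frame(odor_label = odor, responded = outcomes)
  expect_identical(
    classify_stimulus_specific(mk(c(TRUE, FALSE, TRUE)))$stimulus_specific_for,
    "OCT")
  expect_length(
    classify_stimulus_specific(mk(c(TRUE, FALSE, FALSE)))$stimulus_specific_for,
    0)
  expect_length(
    classify_stimulus_specific(mk(c(FALSE, FALSE, FALSE)))$stimulus_specific_for,
    0)
  # fewer presentations than min_hits: indeterminate, not FALSE
  prof <- classify_stimulus_specific(mk(TRUE), min_hits = 2)
  expect_true(is.na(prof$per_odor$specific))
  # monotone: adding a responded presentation never removes an odor
  base <- mk(c(TRUE, TRUE, FALSE))
  more <- mk(c(TRUE, TRUE, FALSE, TRUE))
  expect_true(all(classify_stimulus_specific(base)$stimulus_specific_for %in%
                    classify_stimulus_specific(more)$stimulus_specific_for))
})

test_that("session summaries compute fractions and pooling conventions", {
  cfg <- trace_gen_config(n_cells = 20, responder_fraction = 0.05,
                          transient_amplitude_sd_units = 8, seed = 77)
  s <- gen_traces(cfg)  # exactly 1 responder of 20
  ss <- session_summary(s, mode = "allkc")
  expect_equal(ss$fraction_pct[ss$odor == "OCT"], 5)
  expect_true(ss$animal_has_responder[ss$odor == "OCT"])
  expect_false(ss$animal_has_responder[ss$odor == "MCH"])

  # pooled fraction is total responsive / total cells, not mean of fractions
  cfg_a <- trace_gen_config(n_cells = 10, responder_fraction = 0.5,
                            transient_amplitude_sd_units = 8, seed = 78)
  cfg_b <- trace_gen_config(n_cells = 40, responder_fraction = 0.1,
                            transient_amplitude_sd_units = 8, seed = 79)
  co <- cohort_summary(list(gen_traces(cfg_a), gen_traces(cfg_b)),
                       mode = "allkc")
  oct <- co$pooled[co$pooled$odor == "OCT", ]
  expect_equal(oct$fraction_pct, 100 * (5 + 4) / 50)
  expect_equal(oct$mean_session_fraction_pct, mean(c(50, 10)))
  expect_false(isTRUE(all.equal(oct$fraction_pct,
                                oct$mean_session_fraction_pct)))
})

test_that("difference image ranks the active ROI first", {
  cfg <- trace_gen_config(n_cells = 4, responder_fraction = 0.25,
                          transient_amplitude_sd_units = 10, seed = 80)
  mv <- gen_movie(cfg, image_shape = c(64, 64), pixel_noise_sd = 0.2)
  res <- diff_image_responders(mv$stack, mv$rois)
  active <- mv$session$truth$cell_id[mv$session$truth$responder]
  expect_identical(res$roi_table$cell_id[1], active)

  # static stack: difference bounded by noise; background region near zero
  static <- array(rnorm(32 * 32 * 5, 100, 0.1), dim = c(32, 32, 5))
  res0 <- diff_image_responders(static,
                                data.frame(cell_id = 1, cx = 16, cy = 16,
                                           r = 4))
  expect_lt(abs(res0$roi_table$mean_diff[1]), 0.5)
  bg <- !Reduce(`|`, mv$masks)
  expect_lt(abs(mean(res$diff_image[bg])), 0.5)

  expect_error(diff_image_responders(static[, , 1, drop = FALSE], mv$rois),
               "at least 2 frames")
})

test_that("responder-fraction recovery holds at 5 x SD amplitude", {
  cfg <- trace_gen_config(n_cells = 300, responder_fraction = 0.1,
                          transient_amplitude_sd_units = 5, seed = 81)
  s <- gen_traces(cfg)
  ss <- session_summary(s, mode = "allkc")
  p <- 0.1
  se <- sqrt(p * (1 - p) / 300)
  expect_lt(abs(ss$fraction_pct[ss$odor == "OCT"] / 100 - p), 3 * se)
})
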
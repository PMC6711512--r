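#' Run a reproducible end-to-end experiment
#'
#' Dispatches on `cfg$assay`: simulates the requested inputs (or reads them
#' from `cfg$inputs`), runs the matching analysis, applies the statistics
#' plan, and writes tidy result tables plus a run manifest (config echo,
#' seed, per-file checksums) under `cfg$out`. Result files contain no
#' timestamps, so identical config + seed yields identical checksums.
#'
#' @param cfg configuration list, or a path to a YAML file with the same
#'   structure. Required fields: `assay` (one of `"calcium"`, `"tmaze"`,
#'   `"arena"`, `"counts"`), `seed`, `out`; assay-specific generator and
#'   analysis parameters are documented with the generators.
#' @return invisibly, a list with `results` and the `manifest`.
#' @export
run_experiment <- function(cfg) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  if (is.null(cfg$assay) ||
      !cfg$assay %in% c("calcium", "tmaze", "arena", "counts"))
    stop_input("config error: assay must be one of calcium, tmaze, arena, ",
               "counts")
  if (is.null(cfg$seed)) stop_input("config error: seed is required")
  if (is.null(cfg$out)) stop_input("config error: out directory is required")
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)

  results <- switch(cfg$assay,
    calcium = run_calcium_stage(cfg),
    tmaze = run_tmaze_stage(cfg),
    arena = run_arena_stage(cfg),
    counts = run_counts_stage(cfg)
  )

  files <- list.files(cfg$out, full.names = TRUE, recursive = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    assay = cfg$assay,
    seed = cfg$seed,
    config = cfg,
    package_version = as.character(utils::packageVersion("engramassay")),
    timestamp = format(Sys.time(), tz = "UTC"),
    files = data.frame(path = basename(files),
                       md5 = unname(tools::md5sum(files)),
                       stringsAsFactors = FALSE)
  )
  jsonlite::write_json(manifest, file.path(cfg$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(list(results = results, manifest = manifest))
}

run_calcium_stage <- function(cfg) {
  mode <- cfg$mode %||% "allkc"
  k <- cfg$k %||% 2.33
  baseline_frames <- cfg$baseline_frames %||% 28
  if (!is.null(cfg$inputs)) {
    sessions <- list(read_traces(cfg$inputs$traces_csv,
                                 cfg$inputs$events_json))
  } else {
    g <- cfg$generator
    if (is.null(g)) stop_input("config error: calcium assay needs either ",
                               "inputs or a generator block")
    tc <- trace_gen_config(
      n_cells = g$n_cells %||% 30,
      responder_fraction = g$responder_fraction %||% 0.05,
      n_presentations_per_stimulus = g$n_presentations_per_stimulus %||%
        (if (mode == "camel") 1 else 3),
      odor_labels = g$odor_labels %||% c("OCT", "MCH"),
      transient_amplitude_sd_units = g$transient_amplitude_sd_units %||% 5
    )
    sessions <- gen_imaging_cohort(g$n_sessions %||% 8, tc, seed = cfg$seed)
  }
  calls <- do.call(rbind, lapply(seq_along(sessions), function(i) {
    cl <- analyze_session(sessions[[i]], k = k,
                          baseline_n_frames = baseline_frames)
    cl$animal_id <- sessions[[i]]$animal_id %||% i
    cl
  }))
  summ <- cohort_summary(sessions, mode = mode, k = k,
                         baseline_n_frames = baseline_frames)
  utils::write.csv(calls, file.path(cfg$out, "response_calls.csv"),
                   row.names = FALSE)
  jsonlite::write_json(summ, file.path(cfg$out, "session_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       pretty = TRUE)
  summ
}

run_tmaze_stage <- function(cfg) {
  if (!is.null(cfg$inputs)) {
    pairs <- read_tmaze_counts(cfg$inputs$counts_csv)
  } else {
    g <- cfg$generator
    tc <- tmaze_gen_config(
      n_flies_per_group = g$n_flies_per_group %||% 100,
      latent_memory_strength = g$latent_memory_strength %||% 0,
      odor_bias = g$odor_bias %||% 0,
      n_reciprocal_pairs = g$n_reciprocal_pairs %||% 8,
      seed = cfg$seed
    )
    pairs <- gen_tmaze_counts(tc)
  }
  finals <- vapply(pairs, function(p) reciprocal_average(p)$value, numeric(1))
  res <- data.frame(pair = seq_along(pairs), final_peri = finals)
  report <- if (length(finals) >= 2 && stats::sd(finals) > 0)
    one_sample_test(finals, mu0 = 0) else NULL
  utils::write.csv(res, file.path(cfg$out, "performance_indices.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(mean_final_peri = mean(finals),
         one_sample_p = if (!is.null(report)) report$p_value else NA),
    file.path(cfg$out, "tmaze_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(final_peri = finals, report = report)
}

run_arena_stage <- function(cfg) {
  g <- cfg$generator
  if (is.null(g)) stop_input("config error: arena assay needs a generator ",
                             "block")
  mk <- function(bias, seed, condition) {
    ac <- arena_gen_config(n_flies = g$n_flies %||% 20,
                           light_bias = bias,
                           n_trials = g$n_trials %||% 18,
                           seed = seed)
    gen_arena_series(ac, condition = condition)
  }
  paired <- mk(g$paired_light_bias %||% 0, derive_seed(cfg$seed, 1), "paired")
  unpaired <- mk(g$unpaired_light_bias %||% 0, derive_seed(cfg$seed, 2),
                 "unpaired")
  pi_p <- lapply(paired, total_light_pi)
  pi_u <- lapply(unpaired, total_light_pi)
  dp <- delta_pi(pi_p, pi_u)
  res <- data.frame(
    condition = rep(c("paired", "unpaired"),
                    c(length(pi_p), length(pi_u))),
    trial = c(seq_along(pi_p), seq_along(pi_u)),
    total_pi = c(dp$paired_values, dp$unpaired_values)
  )
  utils::write.csv(res, file.path(cfg$out, "light_preference.csv"),
                   row.names = FALSE)
  cmp <- compare_two(dp$paired_values, dp$unpaired_values)
  jsonlite::write_json(
    list(delta_pi = dp$delta_pi, paired_mean = dp$paired_mean,
         unpaired_mean = dp$unpaired_mean,
         group_test = list(name = cmp$test_name, p = cmp$p_value)),
    file.path(cfg$out, "arena_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  c(dp, list(report = cmp))
}

run_counts_stage <- function(cfg) {
  if (!is.null(cfg$inputs)) {
    counts <- read_hemisphere_counts(cfg$inputs$counts_csv)
  } else {
    g <- cfg$generator
    cc <- count_gen_config(
      n_flies = g$n_flies %||% 150,
      mean_cells_per_hemisphere = g$mean_cells_per_hemisphere %||% 5,
      dispersion = g$dispersion %||% 0.1,
      right_bias = g$right_bias %||% 0,
      condition_label = g$condition_label %||% "control",
      seed = cfg$seed
    )
    counts <- gen_hemisphere_counts(cc)
  }
  bias <- hemisphere_bias(counts)
  write_hemisphere_counts(counts, file.path(cfg$out,
                                            "hemisphere_counts.csv"))
  jsonlite::write_json(
    bias[c("n", "n_right_biased", "n_left_biased", "n_ties",
           "fraction_right_biased", "mean_left", "mean_right")],
    file.path(cfg$out, "hemisphere_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  bias
}

#' Write seed-fixed fixture datasets for the test suite
#'
#' @param preset one of `"innate_calcium"`, `"paired_vs_unpaired_calcium"`,
#'   `"tmaze_memory"`, `"arena_avoidance"`, `"hemisphere_age"`.
#' @param out output directory.
#' @param seed integer seed.
#' @return invisibly, the paths written.
#' @export
make_fixtures <- function(preset, out, seed = 20190704) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  pr <- assay_presets()
  paths <- switch(preset,
    innate_calcium = {
      tc <- trace_gen_config(n_cells = 30,
                             responder_fraction = pr$innate_camel_oct_pct / 100,
                             n_presentations_per_stimulus = 1,
                             seed = seed)
      sessions <- gen_imaging_cohort(8, tc, seed = seed,
                                     condition = "unpaired")
      unlist(lapply(seq_along(sessions), function(i)
        write_traces(sessions[[i]], out,
                     prefix = sprintf("innate_%02d", i))))
    },
    paired_vs_unpaired_calcium = {
      # paired-condition responder rate is a synthetic illustrative choice:
      # the elevated CS+ rate is not printed numerically in the source data
      mk <- function(frac, cond, k) {
        tc <- trace_gen_config(n_cells = 30, responder_fraction = frac,
                               n_presentations_per_stimulus = 1)
        gen_imaging_cohort(8, tc, seed = derive_seed(seed, k),
                           condition = cond)
      }
      sessions <- c(mk(0.15, "paired", 1),
                    mk(pr$innate_camel_oct_pct / 100, "unpaired", 2))
      unlist(lapply(seq_along(sessions), function(i)
        write_traces(sessions[[i]], out,
                     prefix = sprintf("%s_%02d",
                                      sessions[[i]]$training_condition, i))))
    },
    tmaze_memory = {
      tc <- tmaze_gen_config(n_flies_per_group = 100,
                             latent_memory_strength = 0.3, odor_bias = 0.1,
                             n_reciprocal_pairs = 8, seed = seed)
      write_tmaze_counts(gen_tmaze_counts(tc),
                         file.path(out, "tmaze_memory.csv"))
    },
    arena_avoidance = {
      mk <- function(bias, cond, k) {
        ac <- arena_gen_config(n_trials = 18, light_bias = bias,
                               seed = derive_seed(seed, k))
        gen_arena_series(ac, condition = cond)
      }
      series <- c(mk(pr$delta_pi_2d / 100, "paired", 1),
                  mk(0, "unpaired", 2))
      write_arena_series(series, file.path(out, "arena_avoidance.csv"))
    },
    hemisphere_age = {
      mk <- function(mu, bias, cond, k)
        gen_hemisphere_counts(count_gen_config(
          n_flies = 150, mean_cells_per_hemisphere = mu, dispersion = 0.15,
          right_bias = bias, condition_label = cond,
          seed = derive_seed(seed, k)))
      counts <- rbind(mk(2.5, 0, "day1", 1), mk(5.5, 0, "day7", 2),
                      mk(6.0, 0.25, "day14", 3))
      counts$fly_id <- seq_len(nrow(counts))
      write_hemisphere_counts(counts, file.path(out, "hemisphere_age.csv"))
    },
    stop_input("unknown preset: ", preset)
  )
  invisible(paths)
}
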
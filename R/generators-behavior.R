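#' Configuration for synthetic T-maze choice counts
#'
#' Models the reciprocal two-group conditioning design: within each
#' reciprocal pair, one group is trained with odor X as CS+ and the other
#' with odor Y as CS+. Memory shifts flies toward the CS- arm in both
#' groups; an innate odor bias enters with opposite sign in the two groups,
#' which is exactly what reciprocal averaging is meant to cancel.
#'
#' @param n_flies_per_group flies loaded per group.
#' @param latent_memory_strength probability shift toward the CS- arm, in
#'   `[-1, 1]`; expected final performance index is `100 *
#'   latent_memory_strength`.
#' @param odor_bias innate attractiveness asymmetry between the two physical
#'   odors, in `[-1, 1]`; sign flips between the reciprocal groups.
#' @param n_reciprocal_pairs number of reciprocal pairs (replicates).
#' @param seed integer RNG seed.
#' @return object of class `tmaze_gen_config`.
#' @export
tmaze_gen_config <- function(n_flies_per_group = 100,
                             latent_memory_strength = 0,
                             odor_bias = 0,
                             n_reciprocal_pairs = 8,
                             seed = NULL) {
  check_scalar_num(n_flies_per_group, "n_flies_per_group", 1, integer = TRUE)
  check_scalar_num(latent_memory_strength, "latent_memory_strength", -1, 1)
  check_scalar_num(odor_bias, "odor_bias", -1, 1)
  check_scalar_num(n_reciprocal_pairs, "n_reciprocal_pairs", 1, integer = TRUE)
  p_a <- 0.5 + latent_memory_strength / 2 + odor_bias / 2
  p_b <- 0.5 + latent_memory_strength / 2 - odor_bias / 2
  if (p_a < 0 || p_a > 1 || p_b < 0 || p_b > 1)
    stop_input("combined memory and bias terms push a choice probability ",
               "outside [0, 1]")
  structure(list(n_flies_per_group = as.integer(n_flies_per_group),
                 latent_memory_strength = latent_memory_strength,
                 odor_bias = odor_bias,
                 n_reciprocal_pairs = as.integer(n_reciprocal_pairs),
                 seed = seed),
            class = "tmaze_gen_config")
}

#' Generate reciprocal T-maze arm counts
#'
#' For each reciprocal pair, draws the number of flies choosing the CS- arm
#' in each group from a binomial with
#' `P(CS-) = 0.5 + memory/2 +/- odor_bias/2` (sign flipped between the
#' reciprocal groups).
#'
#' @param cfg a [tmaze_gen_config()].
#' @param timepoint_label,protocol metadata stored on every group.
#' @return list of `reciprocal_pair` objects, each with `group_a`/`group_b`
#'   arm-count records and the ground-truth memory strength.
#' @export
gen_tmaze_counts <- function(cfg, timepoint_label = "2 d",
                             protocol = "spaced") {
  stopifnot(inherits(cfg, "tmaze_gen_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_flies_per_group
  p_a <- 0.5 + cfg$latent_memory_strength / 2 + cfg$odor_bias / 2
  p_b <- 0.5 + cfg$latent_memory_strength / 2 - cfg$odor_bias / 2
  lapply(seq_len(cfg$n_reciprocal_pairs), function(i) {
    x_a <- stats::rbinom(1, n, p_a)  # flies in CS- arm, group A
    x_b <- stats::rbinom(1, n, p_b)
    ga <- arm_counts(n_cs_plus_arm = n - x_a, n_cs_minus_arm = x_a,
                     odor_role = "X_as_CSplus",
                     group_id = sprintf("pair%02d_A", i),
                     timepoint_label = timepoint_label, protocol = protocol)
    gb <- arm_counts(n_cs_plus_arm = n - x_b, n_cs_minus_arm = x_b,
                     odor_role = "Y_as_CSplus",
                     group_id = sprintf("pair%02d_B", i),
                     timepoint_label = timepoint_label, protocol = protocol)
    structure(list(group_a = ga, group_b = gb,
                   truth = list(memory = cfg$latent_memory_strength,
                                odor_bias = cfg$odor_bias)),
              class = "reciprocal_pair")
  })
}

#' Configuration for the synthetic four-quadrant light-preference arena
#'
#' Emulates the optogenetic place-preference assay: ~20 flies in a circular
#' arena, a 30 s dark / 30 s light-on (one diagonal quadrant pair) / 30 s
#' dark / 30 s light-on (other pair) illumination protocol, occupancy
#' sampled at 1 Hz. Flies relocate as a Markov process whose stationary
#' occupancy of the illuminated pair is `0.5 + light_bias/2` during light-on
#' and 0.5 in the dark.
#'
#' @param n_flies flies per trial (default 20).
#' @param sampling_rate_hz occupancy sampling rate (default 1 Hz, which gives
#'   the canonical 10 scored samples: 5 s tails of 2 light-on episodes).
#' @param protocol data.frame with columns `duration_s` and `light`
#'   (`"none"`, `"pairA"`, `"pairB"`); default 30 s none/pairA/none/pairB.
#' @param light_bias signed stationary occupancy bias toward illuminated
#'   quadrants in `[-1, 1]`; negative means avoidance. Expected total
#'   preference index is `100 * light_bias`.
#' @param switching_rate_hz per-second fly relocation rate.
#' @param n_trials independent trials (experiments) to simulate.
#' @param seed integer RNG seed.
#' @return object of class `arena_gen_config`.
#' @export
arena_gen_config <- function(n_flies = 20,
                             sampling_rate_hz = 1,
                             protocol = default_arena_protocol(),
                             light_bias = 0,
                             switching_rate_hz = 0.5,
                             n_trials = 18,
                             seed = NULL) {
  check_scalar_num(n_flies, "n_flies", 1, integer = TRUE)
  check_scalar_num(sampling_rate_hz, "sampling_rate_hz", lower = 1e-9)
  check_scalar_num(light_bias, "light_bias", -1, 1)
  check_scalar_num(switching_rate_hz, "switching_rate_hz", lower = 1e-9)
  check_scalar_num(n_trials, "n_trials", 1, integer = TRUE)
  if (!is.data.frame(protocol) ||
      !all(c("duration_s", "light") %in% names(protocol)) ||
      any(protocol$duration_s <= 0) ||
      !all(protocol$light %in% c("none", "pairA", "pairB")))
    stop_input("protocol must be a data.frame(duration_s > 0, ",
               "light in {none, pairA, pairB})")
  structure(list(n_flies = as.integer(n_flies),
                 sampling_rate_hz = sampling_rate_hz,
                 protocol = protocol,
                 light_bias = light_bias,
                 switching_rate_hz = switching_rate_hz,
                 n_trials = as.integer(n_trials),
                 seed = seed),
            class = "arena_gen_config")
}

#' @rdname arena_gen_config
#' @export
default_arena_protocol <- function() {
  data.frame(duration_s = c(30, 30, 30, 30),
             light = c("none", "pairA", "none", "pairB"),
             stringsAsFactors = FALSE)
}

# quadrants 1..4; diagonal pairs: pairA = {1,3}, pairB = {2,4}
quadrants_of_pair <- function(pair) {
  switch(pair, pairA = c(1L, 3L), pairB = c(2L, 4L),
         stop_input("unknown quadrant pair: ", pair))
}

#' Generate synthetic arena occupancy series
#'
#' Each step, every fly relocates with probability
#' `min(1, switching_rate_hz / sampling_rate_hz)`; the destination quadrant
#' is drawn from the current target distribution (illuminated pair with
#' probability `0.5 + light_bias/2` during light-on, uniform otherwise), so
#' occupancy converges geometrically to the configured stationary bias
#' within each illumination epoch.
#'
#' @param cfg an [arena_gen_config()].
#' @param condition,retinal,timepoint_label metadata stored on each trial.
#' @return list of `arena_series` objects: data.frames with `time_s`,
#'   `q1..q4`, `illuminated_pair`, plus trial metadata attributes.
#' @export
gen_arena_series <- function(cfg, condition = NA_character_, retinal = TRUE,
                             timepoint_label = NA_character_) {
  stopifnot(inherits(cfg, "arena_gen_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  dt <- 1 / cfg$sampling_rate_hz
  steps_per_epoch <- round(cfg$protocol$duration_s * cfg$sampling_rate_hz)
  light_per_step <- rep(cfg$protocol$light, times = steps_per_epoch)
  n_steps <- length(light_per_step)
  move_p <- min(1, cfg$switching_rate_hz / cfg$sampling_rate_hz)
  p_on <- 0.5 + cfg$light_bias / 2

  quadrant_probs <- function(light) {
    if (light == "none") return(rep(0.25, 4))
    q <- rep((1 - p_on) / 2, 4)
    q[quadrants_of_pair(light)] <- p_on / 2
    q
  }

  lapply(seq_len(cfg$n_trials), function(trial) {
    pos <- sample.int(4, cfg$n_flies, replace = TRUE)
    counts <- matrix(0L, nrow = n_steps, ncol = 4)
    for (s in seq_len(n_steps)) {
      probs <- quadrant_probs(light_per_step[s])
      moving <- stats::runif(cfg$n_flies) < move_p
      if (any(moving))
        pos[moving] <- sample.int(4, sum(moving), replace = TRUE, prob = probs)
      counts[s, ] <- tabulate(pos, nbins = 4)
    }
    out <- data.frame(time_s = seq_len(n_steps) * dt,
                      q1 = counts[, 1], q2 = counts[, 2],
                      q3 = counts[, 3], q4 = counts[, 4],
                      illuminated_pair = light_per_step,
                      stringsAsFactors = FALSE)
    structure(out, class = c("arena_series", "data.frame"),
              trial_id = trial, condition = condition, retinal = retinal,
              timepoint_label = timepoint_label,
              n_flies = cfg$n_flies, truth = list(light_bias = cfg$light_bias))
  })
}

#' Configuration for synthetic per-hemisphere labeled-cell counts
#'
#' Emulates per-fly counts of reporter-labeled Kenyon cells in the left and
#' right brain hemispheres, with condition-dependent mean and an optional
#' lateral bias applied multiplicatively to the right-hemisphere mean
#' (`mean_right = mean * exp(right_bias)`), which keeps counts nonnegative.
#'
#' @param n_flies flies (brains) to simulate.
#' @param mean_cells_per_hemisphere expected labeled cells per hemisphere.
#' @param dispersion overdispersion: counts are negative binomial with
#'   variance `mu + dispersion * mu^2`; `dispersion = 0` gives deterministic
#'   counts equal to `round(mean)` (noise-free limit).
#' @param right_bias additive shift on the log-mean of the right hemisphere.
#' @param condition_label metadata label (e.g. an age or treatment).
#' @param seed integer RNG seed.
#' @return object of class `count_gen_config`.
#' @export
count_gen_config <- function(n_flies,
                             mean_cells_per_hemisphere = 5,
                             dispersion = 0.1,
                             right_bias = 0,
                             condition_label = "control",
                             seed = NULL) {
  check_scalar_num(n_flies, "n_flies", 1, integer = TRUE)
  check_scalar_num(mean_cells_per_hemisphere, "mean_cells_per_hemisphere",
                   lower = 1e-9)
  check_scalar_num(dispersion, "dispersion", lower = 0)
  check_scalar_num(right_bias, "right_bias")
  structure(list(n_flies = as.integer(n_flies),
                 mean_cells_per_hemisphere = mean_cells_per_hemisphere,
                 dispersion = dispersion,
                 right_bias = right_bias,
                 condition_label = condition_label,
                 seed = seed),
            class = "count_gen_config")
}

#' Generate per-hemisphere labeled-cell counts
#'
#' @param cfg a [count_gen_config()].
#' @return data.frame of class `hemisphere_counts` with columns `fly_id`,
#'   `condition`, `left`, `right`.
#' @export
gen_hemisphere_counts <- function(cfg) {
  stopifnot(inherits(cfg, "count_gen_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  mu_l <- cfg$mean_cells_per_hemisphere
  mu_r <- mu_l * exp(cfg$right_bias)
  draw <- function(mu) {
    if (cfg$dispersion == 0) rep(as.integer(round(mu)), cfg$n_flies)
    else as.integer(stats::rnbinom(cfg$n_flies, size = 1 / cfg$dispersion,
                                   mu = mu))
  }
  out <- data.frame(fly_id = seq_len(cfg$n_flies),
                    condition = cfg$condition_label,
                    left = draw(mu_l), right = draw(mu_r),
                    stringsAsFactors = FALSE)
  class(out) <- c("hemisphere_counts", "data.frame")
  out
}
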
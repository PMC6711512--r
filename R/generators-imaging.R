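#' Configuration for synthetic calcium-trace generation
#'
#' Describes a two-photon-like acquisition: fixed-rate sweeps with
#' stimulus-locked, GCaMP6f-like transients injected into a configurable
#' fraction of cells on top of Gaussian baseline noise and optional linear
#' drift. Defaults mirror a 7 Hz, 20-second sweep protocol with three
#' presentations per odor and a detection-analysis window of 0-4.5 s after
#' stimulus onset.
#'
#' @param n_cells number of ROIs (cells) per session.
#' @param responder_fraction fraction of cells in `[0, 1]` that carry a
#'   stimulus-locked transient on every presentation of their assigned odor.
#'   The realized number of responders is `round(responder_fraction * n_cells)`
#'   unless `n_responders` overrides it.
#' @param frame_rate_hz acquisition rate (frames per second).
#' @param sweep_duration_s duration of one sweep in seconds.
#' @param stimulus_onsets_s stimulus onset time(s) within each sweep, seconds.
#'   Every onset must leave room for the 4.5 s response window.
#' @param n_presentations_per_stimulus presentations (sweeps) per odor.
#' @param odor_labels character vector of odor labels, one sweep block each.
#' @param responder_odor the odor responder cells are tuned to.
#' @param transient_amplitude_sd_units transient peak amplitude expressed as a
#'   multiple of the baseline noise SD.
#' @param amplitude_cv trial-to-trial coefficient of variation of the
#'   transient amplitude within a responding cell (default 0: identical
#'   amplitude on every presentation).
#' @param rise_tau_s,decay_tau_s kinetics of the difference-of-exponentials
#'   transient (GCaMP6f-like defaults 0.1 s and 0.4 s).
#' @param baseline_mean,baseline_sd raw-fluorescence baseline mean and noise SD
#'   (arbitrary units; the mean must be positive so \eqn{\Delta F/F} is defined).
#' @param drift_slope linear drift in raw units per second.
#' @param n_responders optional integer overriding the rounded responder
#'   count (used to allocate an exact pooled count across a cohort).
#' @param seed integer RNG seed; identical seeds give bit-identical sessions.
#' @return an object of class `trace_gen_config`.
#' @export
trace_gen_config <- function(n_cells,
                             responder_fraction = 0.05,
                             frame_rate_hz = 7,
                             sweep_duration_s = 20,
                             stimulus_onsets_s = 5,
                             n_presentations_per_stimulus = 3,
                             odor_labels = c("OCT", "MCH"),
                             responder_odor = odor_labels[1],
                             transient_amplitude_sd_units = 5,
                             amplitude_cv = 0,
                             rise_tau_s = 0.1,
                             decay_tau_s = 0.4,
                             baseline_mean = 100,
                             baseline_sd = 5,
                             drift_slope = 0,
                             n_responders = NULL,
                             seed = NULL) {
  check_scalar_num(n_cells, "n_cells", lower = 1, integer = TRUE)
  check_scalar_num(responder_fraction, "responder_fraction", 0, 1)
  check_scalar_num(frame_rate_hz, "frame_rate_hz", lower = 1e-9)
  check_scalar_num(sweep_duration_s, "sweep_duration_s", lower = 1e-9)
  check_scalar_num(n_presentations_per_stimulus,
                   "n_presentations_per_stimulus", lower = 1, integer = TRUE)
  check_scalar_num(transient_amplitude_sd_units,
                   "transient_amplitude_sd_units", lower = 0)
  check_scalar_num(amplitude_cv, "amplitude_cv", lower = 0)
  check_scalar_num(rise_tau_s, "rise_tau_s", lower = 1e-9)
  check_scalar_num(decay_tau_s, "decay_tau_s", lower = 1e-9)
  check_scalar_num(baseline_mean, "baseline_mean", lower = 1e-9)
  check_scalar_num(baseline_sd, "baseline_sd", lower = 0)
  check_scalar_num(drift_slope, "drift_slope")
  if (!is.numeric(stimulus_onsets_s) || length(stimulus_onsets_s) < 1 ||
      any(stimulus_onsets_s < 0))
    stop_input("stimulus_onsets_s must be nonnegative times (seconds)")
  if (any(stimulus_onsets_s + 4.5 > sweep_duration_s))
    stop_input("every stimulus onset + 4.5 s must fit within the sweep")
  if (!responder_odor %in% odor_labels)
    stop_input("responder_odor must be one of odor_labels")
  if (!is.null(n_responders)) {
    check_scalar_num(n_responders, "n_responders", 0, n_cells, integer = TRUE)
  }
  structure(list(
    n_cells = as.integer(n_cells),
    responder_fraction = responder_fraction,
    frame_rate_hz = frame_rate_hz,
    sweep_duration_s = sweep_duration_s,
    stimulus_onsets_s = stimulus_onsets_s,
    n_presentations_per_stimulus = as.integer(n_presentations_per_stimulus),
    odor_labels = odor_labels,
    responder_odor = responder_odor,
    transient_amplitude_sd_units = transient_amplitude_sd_units,
    amplitude_cv = amplitude_cv,
    rise_tau_s = rise_tau_s,
    decay_tau_s = decay_tau_s,
    baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    drift_slope = drift_slope,
    n_responders = if (is.null(n_responders)) NULL else as.integer(n_responders),
    seed = seed
  ), class = "trace_gen_config")
}

# unit-peak difference-of-exponentials transient kernel, t in seconds >= 0
transient_kernel <- function(t, rise_tau, decay_tau) {
  if (abs(decay_tau - rise_tau) < 1e-12) rise_tau <- rise_tau * (1 - 1e-6)
  t_peak <- rise_tau * decay_tau / (decay_tau - rise_tau) *
    log(decay_tau / rise_tau)
  peak <- exp(-t_peak / decay_tau) - exp(-t_peak / rise_tau)
  h <- ifelse(t < 0, 0, exp(-t / decay_tau) - exp(-t / rise_tau))
  h / peak
}

#' Generate a synthetic imaging session
#'
#' Produces one session of raw-fluorescence sweeps: one sweep per
#' (odor, presentation) combination, each an `n_cells` x `n_frames` matrix.
#' Exactly `round(responder_fraction * n_cells)` cells (or `n_responders`
#' when given) are true responders: they carry a stimulus-locked
#' difference-of-exponentials transient with peak amplitude
#' `transient_amplitude_sd_units * baseline_sd` on every presentation of
#' their assigned odor. Ground-truth responder labels are returned with the
#' data.
#'
#' @param cfg a [trace_gen_config()].
#' @param animal_id identifier stored with the session.
#' @param training_condition optional label (e.g. `"paired"`, `"unpaired"`).
#' @return an object of class `imaging_session`: list with `traces`
#'   (3-d array cell x frame x sweep), `sweeps` (data.frame of odor,
#'   presentation, onset), `frame_rate_hz`, `truth` (per-cell responder flag
#'   and assigned odor) and metadata.
#' @export
gen_traces <- function(cfg, animal_id = "sim", training_condition = NA_character_) {
  stopifnot(inherits(cfg, "trace_gen_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  n_frames <- round(cfg$frame_rate_hz * cfg$sweep_duration_s)
  t <- (seq_len(n_frames) - 1) / cfg$frame_rate_hz
  sweeps <- expand.grid(
    presentation = seq_len(cfg$n_presentations_per_stimulus),
    odor = cfg$odor_labels,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("odor", "presentation")]
  sweeps$onset_s <- cfg$stimulus_onsets_s[1]
  n_sweeps <- nrow(sweeps)

  n_resp <- cfg$n_responders %||% as.integer(round(cfg$responder_fraction * cfg$n_cells))
  responder <- rep(FALSE, cfg$n_cells)
  if (n_resp > 0) responder[sample.int(cfg$n_cells, n_resp)] <- TRUE

  # stimulus-locked transient template (sum over onsets, usually one)
  template <- rowSums(vapply(
    cfg$stimulus_onsets_s,
    function(o) transient_kernel(t - o, cfg$rise_tau_s, cfg$decay_tau_s),
    numeric(n_frames)
  ))

  traces <- array(0, dim = c(cfg$n_cells, n_frames, n_sweeps))
  drift <- cfg$drift_slope * t
  for (s in seq_len(n_sweeps)) {
    m <- matrix(stats::rnorm(cfg$n_cells * n_frames, sd = cfg$baseline_sd),
                nrow = cfg$n_cells)
    m <- m + rep(cfg$baseline_mean + drift, each = cfg$n_cells)
    if (sweeps$odor[s] == cfg$responder_odor && any(responder)) {
      amp <- cfg$transient_amplitude_sd_units * cfg$baseline_sd
      amps <- amp * pmax(0, 1 + cfg$amplitude_cv * stats::rnorm(sum(responder)))
      m[responder, ] <- m[responder, , drop = FALSE] +
        outer(amps, template)
    }
    traces[, , s] <- m
  }

  structure(list(
    animal_id = animal_id,
    training_condition = training_condition,
    traces = traces,
    sweeps = sweeps,
    frame_rate_hz = cfg$frame_rate_hz,
    truth = data.frame(
      cell_id = seq_len(cfg$n_cells),
      responder = responder,
      odor = ifelse(responder, cfg$responder_odor, NA_character_),
      stringsAsFactors = FALSE
    ),
    config = cfg
  ), class = "imaging_session")
}

#' Generate a cohort of imaging sessions with an exact pooled responder count
#'
#' Allocates `round(pooled_fraction * n_sessions * n_cells)` true responders
#' across sessions as evenly as possible (largest-remainder allocation), so
#' the pooled injected responder rate equals the configured rate by
#' construction rather than in expectation. Each session gets a sub-seed
#' derived deterministically from `seed`.
#'
#' @param n_sessions number of sessions (animals / conditioning rounds).
#' @param cfg a [trace_gen_config()] used for every session; its
#'   `responder_fraction` is the pooled target.
#' @param seed integer seed for the cohort.
#' @param condition label stored on every session.
#' @return list of `imaging_session` objects.
#' @export
gen_imaging_cohort <- function(n_sessions, cfg, seed = 1L,
                               condition = NA_character_) {
  check_scalar_num(n_sessions, "n_sessions", lower = 1, integer = TRUE)
  total <- n_sessions * cfg$n_cells
  n_resp_total <- round(cfg$responder_fraction * total)
  # even split with largest-remainder rounding
  bounds <- round(seq(0, n_resp_total, length.out = n_sessions + 1))
  per_session <- diff(bounds)
  lapply(seq_len(n_sessions), function(i) {
    cfg_i <- cfg
    cfg_i$n_responders <- as.integer(per_session[i])
    cfg_i$seed <- derive_seed(seed, i)
    gen_traces(cfg_i, animal_id = sprintf("animal_%02d", i),
               training_condition = condition)
  })
}

#' Paint a synthetic image stack from generated traces
#'
#' Renders the first sweep of a generated session as a movie in which each
#' cell is a disk ROI whose per-frame mean intensity equals its trace value,
#' plus independent pixel noise; the background is the constant baseline
#' mean. ROI centers and radii are returned as ground truth.
#'
#' @param cfg a [trace_gen_config()].
#' @param image_shape integer `(height, width)` in pixels.
#' @param roi_radius_px disk radius in pixels.
#' @param pixel_noise_sd SD of iid pixel noise added on top of the trace value.
#' @param sweep which sweep of the session to render (default 1).
#' @return list with `stack` (array height x width x frames), `rois`
#'   (data.frame cell_id, cx, cy, r), `masks` (list of logical matrices) and
#'   the generating `session`.
#' @export
gen_movie <- function(cfg, image_shape = c(128, 128), roi_radius_px = 4,
                      pixel_noise_sd = 0, sweep = 1L) {
  session <- gen_traces(cfg)
  h <- image_shape[1]; w <- image_shape[2]
  r <- roi_radius_px
  spacing <- 2 * r + 3
  cx <- cy <- integer(0)
  # raster placement on a grid: guarantees non-overlap
  xs <- seq(r + 2, w - r - 1, by = spacing)
  ys <- seq(r + 2, h - r - 1, by = spacing)
  if (length(xs) * length(ys) < cfg$n_cells)
    stop_input("image_shape too small to place ", cfg$n_cells,
               " non-overlapping ROIs of radius ", r)
  grid <- expand.grid(x = xs, y = ys)[seq_len(cfg$n_cells), ]
  rois <- data.frame(cell_id = seq_len(cfg$n_cells),
                     cx = grid$x, cy = grid$y, r = r)

  xx <- matrix(rep(seq_len(w), each = h), nrow = h)
  yy <- matrix(rep(seq_len(h), times = w), nrow = h)
  masks <- lapply(seq_len(cfg$n_cells), function(i) {
    (xx - rois$cx[i])^2 + (yy - rois$cy[i])^2 <= r^2
  })

  n_frames <- dim(session$traces)[2]
  stack <- array(cfg$baseline_mean, dim = c(h, w, n_frames))
  for (f in seq_len(n_frames)) {
    frame <- matrix(cfg$baseline_mean, h, w)
    for (i in seq_len(cfg$n_cells)) {
      frame[masks[[i]]] <- session$traces[i, f, sweep]
    }
    if (pixel_noise_sd > 0)
      frame <- frame + matrix(stats::rnorm(h * w, sd = pixel_noise_sd), h, w)
    stack[, , f] <- frame
  }
  list(stack = stack, rois = rois, masks = masks, session = session,
       sweep = sweep)
}
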
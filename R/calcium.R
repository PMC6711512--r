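#' Normalize a raw fluorescence trace to \eqn{\Delta F/F}
#'
#' The baseline `f0` is the mean of the first `baseline_n_frames` raw values;
#' the normalized trace is `(f - f0) / f0`. The baseline SD is the SD of the
#' normalized trace over the baseline frames (computed on the unsmoothed
#' trace by default; see `sd_on_smoothed`), and a centered 5-point running
#' average of the normalized trace is attached for peak extraction.
#'
#' @param f numeric raw fluorescence series, or a list with elements `f` and
#'   `frame_rate_hz`.
#' @param baseline_n_frames number of initial frames defining the baseline
#'   (default 28, i.e. the first 4 s at 7 Hz).
#' @param smooth_window running-average window (odd, default 5).
#' @param sd_on_smoothed if `TRUE`, the baseline SD is taken on the smoothed
#'   normalized trace instead of the raw normalized trace.
#' @param frame_rate_hz acquisition rate carried through to detection.
#' @return object of class `normalized_trace`: list with `dff`, `f0`,
#'   `baseline_sd`, `smoothed`, `frame_rate_hz`.
#' @export
normalize_dff <- function(f, baseline_n_frames = 28, smooth_window = 5,
                          sd_on_smoothed = FALSE, frame_rate_hz = 7) {
  if (is.list(f)) {
    frame_rate_hz <- f$frame_rate_hz %||% frame_rate_hz
    f <- f$f
  }
  if (!is.numeric(f)) stop_input("f must be a numeric series")
  check_scalar_num(baseline_n_frames, "baseline_n_frames", 1, integer = TRUE)
  if (length(f) < baseline_n_frames)
    stop_input("trace (", length(f), " frames) shorter than baseline window (",
               baseline_n_frames, " frames)")
  f0 <- mean(f[seq_len(baseline_n_frames)])
  if (!is.finite(f0) || f0 <= 0)
    stop_input("baseline mean fluorescence must be positive; got ", f0)
  dff <- (f - f0) / f0
  smoothed <- smooth_running(dff, window = smooth_window)
  base_series <- if (sd_on_smoothed) smoothed else dff
  baseline_sd <- stats::sd(base_series[seq_len(baseline_n_frames)])
  structure(list(dff = dff, f0 = f0, baseline_sd = baseline_sd,
                 smoothed = smoothed, frame_rate_hz = frame_rate_hz,
                 baseline_n_frames = baseline_n_frames),
            class = "normalized_trace")
}

#' Centered running average with shrinking edges
#'
#' Centered moving mean of odd width; at the series edges the window shrinks
#' symmetrically to the available points, so the output has the same length
#' as the input and a constant series is returned unchanged.
#'
#' @param x numeric series.
#' @param window odd positive window width (default 5).
#' @return numeric series of the same length.
#' @export
smooth_running <- function(x, window = 5) {
  check_scalar_num(window, "window", 1, integer = TRUE)
  if (window %% 2 == 0) stop_input("window must be odd")
  n <- length(x)
  if (window > n) stop_input("window exceeds series length")
  h <- (window - 1) / 2
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  hh <- pmin(h, i - 1, n - i)   # symmetric shrink at the edges
  (cs[i + hh + 1] - cs[i - hh]) / (2 * hh + 1)
}

# 0-based inclusive frame-index range of the response window
response_window_frames <- function(onset_s, frame_rate_hz,
                                   window_s = c(0, 4.5)) {
  c(round((onset_s + window_s[1]) * frame_rate_hz),
    round((onset_s + window_s[2]) * frame_rate_hz))
}

#' Score one stimulus presentation as response / no response
#'
#' The peak of the smoothed normalized trace is taken over frames whose
#' onset-relative time lies in `window_s` (default 0-4.5 s post onset,
#' inclusive rounded frame range); the presentation is scored a response
#' when that peak strictly exceeds `k` times the baseline SD.
#'
#' @param nt a [normalize_dff()] result.
#' @param event list with `odor_label`, `onset_s`, `presentation_index`.
#' @param window_s response window relative to stimulus onset, seconds.
#' @param k threshold multiplier (default 2.33, the one-sided z for
#'   alpha = 0.01).
#' @param cell_id identifier copied into the call record.
#' @return object of class `response_call`: list with `peak_value`,
#'   `threshold`, `responded`, `window_frames` (0-based inclusive) and the
#'   event metadata.
#' @export
detect_response <- function(nt, event, window_s = c(0, 4.5), k = 2.33,
                            cell_id = NA) {
  stopifnot(inherits(nt, "normalized_trace"))
  onset <- event$onset_s
  if (is.null(onset) || onset < 0) stop_input("event$onset_s must be >= 0")
  wf <- response_window_frames(onset, nt$frame_rate_hz, window_s)
  n <- length(nt$smoothed)
  if (wf[2] > n - 1)
    stop_input("response window extends beyond the sweep (frames ",
               wf[1], "-", wf[2], " of ", n, ")")
  idx <- (wf[1]:wf[2]) + 1L
  peak <- max(nt$smoothed[idx])
  threshold <- k * nt$baseline_sd
  structure(list(cell_id = cell_id,
                 odor_label = event$odor_label %||% NA_character_,
                 presentation_index = event$presentation_index %||% NA_integer_,
                 peak_value = peak,
                 window_frames = wf,
                 threshold = threshold,
                 responded = peak > threshold),
            class = "response_call")
}

#' Classify a cell's stimulus specificity from its presentation calls
#'
#' A cell is stimulus specific for an odor when at least `min_hits` of that
#' odor's presentations were scored as responses (default 2, the 2-of-3
#' rule). Odors with fewer presentations than `min_hits` are marked
#' indeterminate (`NA`), not negative.
#'
#' @param calls data.frame with columns `odor_label` and `responded` (one
#'   row per presentation of one cell), or a list of `response_call`s.
#' @param min_hits minimum responding presentations (default 2).
#' @param cell_id identifier for the profile.
#' @return object of class `cell_profile`: list with `per_odor` (data.frame
#'   odor, n_presentations, n_responded, specific) and
#'   `stimulus_specific_for` (character vector of odors).
#' @export
classify_stimulus_specific <- function(calls, min_hits = 2, cell_id = NA) {
  if (!is.data.frame(calls)) {
    calls <- do.call(rbind, lapply(calls, function(cl)
      data.frame(odor_label = cl$odor_label, responded = cl$responded,
                 stringsAsFactors = FALSE)))
  }
  check_scalar_num(min_hits, "min_hits", 1, integer = TRUE)
  agg <- stats::aggregate(responded ~ odor_label, data = calls,
                          FUN = function(x) c(n = length(x), hits = sum(x)))
  per_odor <- data.frame(
    odor = agg$odor_label,
    n_presentations = agg$responded[, "n"],
    n_responded = agg$responded[, "hits"],
    stringsAsFactors = FALSE
  )
  per_odor$specific <- ifelse(per_odor$n_presentations < min_hits, NA,
                              per_odor$n_responded >= min_hits)
  structure(list(cell_id = cell_id, per_odor = per_odor,
                 stimulus_specific_for =
                   per_odor$odor[which(per_odor$specific)]),
            class = "cell_profile")
}

#' Run response calling over a whole imaging session
#'
#' Vectorized application of [normalize_dff()] and [detect_response()] to
#' every (cell, sweep) trace of a session.
#'
#' @param session an `imaging_session` (see [gen_traces()] or
#'   [read_traces()]).
#' @param k,window_s,baseline_n_frames,smooth_window,sd_on_smoothed detection
#'   parameters, as in [normalize_dff()] and [detect_response()].
#' @return data.frame of per-presentation calls: `cell_id`, `odor`,
#'   `presentation`, `peak`, `threshold`, `responded`.
#' @export
analyze_session <- function(session, k = 2.33, window_s = c(0, 4.5),
                            baseline_n_frames = 28, smooth_window = 5,
                            sd_on_smoothed = FALSE) {
  stopifnot(inherits(session, "imaging_session"))
  rate <- session$frame_rate_hz
  n_cells <- dim(session$traces)[1]
  n_frames <- dim(session$traces)[2]
  out <- vector("list", nrow(session$sweeps))
  for (s in seq_len(nrow(session$sweeps))) {
    m <- session$traces[, , s, drop = FALSE]
    dim(m) <- c(n_cells, n_frames)
    f0 <- rowMeans(m[, seq_len(baseline_n_frames), drop = FALSE])
    if (any(f0 <= 0))
      stop_input("nonpositive baseline mean in sweep ", s)
    dff <- m / f0 - 1
    sm <- t(apply(dff, 1, smooth_running, window = smooth_window))
    base <- if (sd_on_smoothed) sm else dff
    bsd <- apply(base[, seq_len(baseline_n_frames), drop = FALSE], 1,
                 stats::sd)
    wf <- response_window_frames(session$sweeps$onset_s[s], rate, window_s)
    if (wf[2] > n_frames - 1)
      stop_input("response window extends beyond sweep ", s)
    idx <- (wf[1]:wf[2]) + 1L
    peak <- apply(sm[, idx, drop = FALSE], 1, max)
    out[[s]] <- data.frame(
      cell_id = seq_len(n_cells),
      odor = session$sweeps$odor[s],
      presentation = session$sweeps$presentation[s],
      peak = peak,
      threshold = k * bsd,
      responded = peak > k * bsd,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Summarize responder fractions for one session
#'
#' In `"allkc"` mode a cell counts as responsive to an odor when at least
#' `min_hits` of its presentations responded (the 2-of-3 rule). In `"camel"`
#' mode — mirroring the conditioning-round protocol in which each odor is
#' presented once in the automated routine — a single responding
#' presentation suffices.
#'
#' @param session an `imaging_session`.
#' @param mode `"camel"` or `"allkc"`.
#' @param min_hits hits required in `"allkc"` mode (default 2).
#' @param calls optional precomputed [analyze_session()] table.
#' @param ... detection parameters passed to [analyze_session()].
#' @return object of class `session_summary`: data.frame per odor with
#'   `n_cells`, `n_responsive`, `fraction_pct`, `animal_has_responder`.
#' @export
session_summary <- function(session, mode = c("camel", "allkc"),
                            min_hits = 2, calls = NULL, ...) {
  mode <- match.arg(mode)
  if (is.null(calls)) calls <- analyze_session(session, ...)
  n_cells <- length(unique(calls$cell_id))
  if (n_cells == 0) stop_input("session contains no cells")
  hits_needed <- if (mode == "camel") 1L else as.integer(min_hits)
  agg <- stats::aggregate(responded ~ cell_id + odor, data = calls, FUN = sum)
  odors <- sort(unique(calls$odor))
  out <- do.call(rbind, lapply(odors, function(o) {
    resp <- agg$responded[agg$odor == o] >= hits_needed
    data.frame(odor = o,
               n_cells = n_cells,
               n_responsive = sum(resp),
               fraction_pct = 100 * sum(resp) / n_cells,
               animal_has_responder = any(resp),
               stringsAsFactors = FALSE)
  }))
  attr(out, "animal_id") <- session$animal_id
  attr(out, "mode") <- mode
  class(out) <- c("session_summary", "data.frame")
  out
}

#' Pool responder fractions over a cohort of sessions
#'
#' Reports both pooling conventions: the grand-pooled fraction (total
#' responsive cells / total cells) and the mean of per-session fractions
#' (one value per conditioning round, the primary convention for group
#' comparisons).
#'
#' @param sessions list of `imaging_session`s.
#' @param ... passed to [session_summary()].
#' @return list with `per_session` (stacked summaries), `pooled` (per-odor
#'   pooled fraction), `per_session_mean` (per-odor mean of session
#'   fractions) and `n_animals_responding` per odor.
#' @export
cohort_summary <- function(sessions, ...) {
  sums <- lapply(sessions, session_summary, ...)
  per_session <- do.call(rbind, lapply(seq_along(sums), function(i) {
    s <- as.data.frame(sums[[i]])
    s$animal_id <- attr(sums[[i]], "animal_id") %||% i
    s
  }))
  odors <- sort(unique(per_session$odor))
  pooled <- do.call(rbind, lapply(odors, function(o) {
    sub <- per_session[per_session$odor == o, ]
    data.frame(odor = o,
               n_cells = sum(sub$n_cells),
               n_responsive = sum(sub$n_responsive),
               fraction_pct = 100 * sum(sub$n_responsive) / sum(sub$n_cells),
               mean_session_fraction_pct = mean(sub$fraction_pct),
               n_animals_responding = sum(sub$animal_has_responder),
               stringsAsFactors = FALSE)
  }))
  list(per_session = per_session, pooled = pooled)
}

#' Responder map from a difference image
#'
#' Identifies the frame of peak global activity (maximum whole-frame mean),
#' subtracts the baseline frame from it, and reports the mean difference
#' inside each ROI, ranked in decreasing order.
#'
#' @param stack array `height x width x frames` (e.g. from [gen_movie()]).
#' @param rois data.frame with `cell_id`, `cx`, `cy`, `r`, or a list of
#'   logical mask matrices.
#' @param baseline_frame index of the baseline frame (default 1, the first).
#' @return list with `diff_image`, `peak_frame`, and `roi_table`
#'   (data.frame cell_id, mean_diff, rank).
#' @export
diff_image_responders <- function(stack, rois, baseline_frame = 1) {
  if (length(dim(stack)) != 3 || dim(stack)[3] < 2)
    stop_input("stack must have at least 2 frames")
  frame_means <- apply(stack, 3, mean)
  peak_frame <- which.max(frame_means)
  diff_image <- stack[, , peak_frame] - stack[, , baseline_frame]
  masks <- if (is.data.frame(rois)) {
    h <- dim(stack)[1]; w <- dim(stack)[2]
    xx <- matrix(rep(seq_len(w), each = h), nrow = h)
    yy <- matrix(rep(seq_len(h), times = w), nrow = h)
    lapply(seq_len(nrow(rois)), function(i)
      (xx - rois$cx[i])^2 + (yy - rois$cy[i])^2 <= rois$r[i]^2)
  } else rois
  mean_diff <- vapply(masks, function(m) mean(diff_image[m]), numeric(1))
  roi_table <- data.frame(cell_id = seq_along(masks), mean_diff = mean_diff)
  roi_table <- roi_table[order(-roi_table$mean_diff), ]
  roi_table$rank <- seq_len(nrow(roi_table))
  list(diff_image = diff_image, peak_frame = peak_frame,
       roi_table = roi_table)
}
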
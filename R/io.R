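#' Write an imaging session to CSV + JSON sidecar
#'
#' The CSV holds one row per (cell, odor, presentation) sweep trace: id
#' columns followed by the frame columns `f_1..f_n`. The JSON sidecar holds
#' the frame rate, the stimulus-event table and (when present) the
#' ground-truth responder labels.
#'
#' @param session an `imaging_session`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_traces <- function(session, dir, prefix = "traces") {
  stopifnot(inherits(session, "imaging_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_cells <- dim(session$traces)[1]
  n_frames <- dim(session$traces)[2]
  rows <- do.call(rbind, lapply(seq_len(nrow(session$sweeps)), function(s) {
    m <- matrix(session$traces[, , s], nrow = n_cells)
    df <- data.frame(cell_id = seq_len(n_cells),
                     odor = session$sweeps$odor[s],
                     presentation = session$sweeps$presentation[s],
                     stringsAsFactors = FALSE)
    cbind(df, as.data.frame(m))
  }))
  names(rows)[-(1:3)] <- paste0("f_", seq_len(n_frames))
  csv <- file.path(dir, paste0(prefix, ".csv"))
  utils::write.csv(rows, csv, row.names = FALSE)
  sidecar <- list(
    frame_rate_hz = session$frame_rate_hz,
    animal_id = session$animal_id,
    training_condition = session$training_condition,
    events = lapply(seq_len(nrow(session$sweeps)), function(s) list(
      odor_label = session$sweeps$odor[s],
      onset_s = session$sweeps$onset_s[s],
      presentation_index = session$sweeps$presentation[s]
    )),
    truth = session$truth
  )
  js <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(sidecar, js, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(csv = csv, json = js))
}

#' Read an imaging session written by [write_traces()]
#'
#' @param csv path to the trace CSV.
#' @param json path to the JSON sidecar (defaults to the CSV path with a
#'   `.json` extension).
#' @return an `imaging_session`.
#' @export
read_traces <- function(csv, json = sub("\\.csv$", ".json", csv)) {
  rows <- utils::read.csv(csv, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(json, simplifyVector = TRUE)
  frame_cols <- grep("^f_", names(rows))
  sweeps <- unique(rows[, c("odor", "presentation")])
  sweeps <- sweeps[order(match(sweeps$odor, unique(rows$odor)),
                         sweeps$presentation), ]
  ev <- meta$events
  if (is.data.frame(ev)) {
    onset <- ev$onset_s
    odor_ev <- ev$odor_label
    pres_ev <- ev$presentation_index
  } else {
    onset <- vapply(ev, function(e) e$onset_s, numeric(1))
    odor_ev <- vapply(ev, function(e) e$odor_label, character(1))
    pres_ev <- vapply(ev, function(e) e$presentation_index, numeric(1))
  }
  sweeps$onset_s <- onset[match(paste(sweeps$odor, sweeps$presentation),
                                paste(odor_ev, pres_ev))]
  n_cells <- length(unique(rows$cell_id))
  n_frames <- length(frame_cols)
  traces <- array(0, dim = c(n_cells, n_frames, nrow(sweeps)))
  for (s in seq_len(nrow(sweeps))) {
    sub <- rows[rows$odor == sweeps$odor[s] &
                  rows$presentation == sweeps$presentation[s], ]
    sub <- sub[order(sub$cell_id), ]
    traces[, , s] <- as.matrix(sub[, frame_cols])
  }
  truth <- if (!is.null(meta$truth)) as.data.frame(meta$truth) else NULL
  structure(list(animal_id = meta$animal_id,
                 training_condition = meta$training_condition,
                 traces = traces,
                 sweeps = as.data.frame(sweeps, stringsAsFactors = FALSE),
                 frame_rate_hz = as.numeric(meta$frame_rate_hz),
                 truth = truth, config = NULL),
            class = "imaging_session")
}

#' Write / read T-maze arm-count tables
#'
#' CSV columns: `group`, `replicate`, `count_cs_plus_arm`,
#' `count_cs_minus_arm`, `odor_role`.
#'
#' @param pairs list of `reciprocal_pair`s (see [gen_tmaze_counts()]).
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_tmaze_counts <- function(pairs, path) {
  rows <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    do.call(rbind, lapply(list(p$group_a, p$group_b), function(g)
      data.frame(group = g$group_id, replicate = i,
                 count_cs_plus_arm = g$n_cs_plus_arm,
                 count_cs_minus_arm = g$n_cs_minus_arm,
                 odor_role = g$odor_role, stringsAsFactors = FALSE)))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tmaze_counts
#' @export
read_tmaze_counts <- function(path) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(unique(rows$replicate), function(i) {
    sub <- rows[rows$replicate == i, ]
    mk <- function(r) arm_counts(r$count_cs_plus_arm, r$count_cs_minus_arm,
                                 odor_role = r$odor_role, group_id = r$group)
    structure(list(group_a = mk(sub[1, ]), group_b = mk(sub[2, ])),
              class = "reciprocal_pair")
  })
}

#' Write / read arena occupancy series
#'
#' CSV columns: `trial`, `condition`, `time_s`, `q1..q4`,
#' `illuminated_pair`.
#'
#' @param series list of `arena_series`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_arena_series <- function(series, path) {
  rows <- do.call(rbind, lapply(series, function(s) {
    df <- as.data.frame(s)
    df$trial <- attr(s, "trial_id")
    df$condition <- attr(s, "condition") %||% NA_character_
    df[, c("trial", "condition", "time_s", "q1", "q2", "q3", "q4",
           "illuminated_pair")]
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_arena_series
#' @export
read_arena_series <- function(path) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  # trial numbering restarts per condition, so split on both
  key <- paste(rows$condition, rows$trial, sep = "\r")
  lapply(unique(key), function(kk) {
    sub_all <- rows[key == kk, ]
    sub <- sub_all[, c("time_s", "q1", "q2", "q3", "q4", "illuminated_pair")]
    rownames(sub) <- NULL
    structure(sub, class = c("arena_series", "data.frame"),
              trial_id = sub_all$trial[1], condition = sub_all$condition[1],
              n_flies = sum(sub[1, c("q1", "q2", "q3", "q4")]))
  })
}

#' Write / read hemisphere count tables
#'
#' CSV columns: `fly_id`, `condition`, `left`, `right`.
#'
#' @param counts a `hemisphere_counts` data.frame (or several rbound).
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_hemisphere_counts <- function(counts, path) {
  utils::write.csv(as.data.frame(counts)[, c("fly_id", "condition", "left",
                                             "right")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hemisphere_counts
#' @export
read_hemisphere_counts <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("hemisphere_counts", "data.frame")
  out
}

#' Write a synthetic movie as a multi-page TIFF
#'
#' Intensities are scaled linearly to `[0, 1]` by the stack range; the
#' scale and offset are returned so the trace values can be recovered.
#'
#' @param movie a [gen_movie()] result.
#' @param path output TIFF path.
#' @return invisibly, list with `path`, `offset`, `scale`.
#' @export
write_movie_tiff <- function(movie, path) {
  stack <- movie$stack
  lo <- min(stack); hi <- max(stack)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(stack)[3]), function(f)
    (stack[, , f] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(list(path = path, offset = lo, scale = scale))
}

#' @rdname write_movie_tiff
#' @param offset,scale the values returned by [write_movie_tiff()].
#' @export
read_movie_tiff <- function(path, offset = 0, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  stack <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) stack[, , f] <- pages[[f]] * scale + offset
  stack
}
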
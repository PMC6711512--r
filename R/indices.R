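#' T-maze arm counts
#'
#' Fly headcounts in a two-arm odor choice after conditioning, with the
#' odor-role metadata needed for reciprocal averaging.
#'
#' @param n_cs_plus_arm,n_cs_minus_arm nonnegative integer headcounts.
#' @param odor_role which physical odor served as CS+ in this group.
#' @param group_id,timepoint_label,protocol metadata.
#' @return object of class `arm_counts`.
#' @export
arm_counts <- function(n_cs_plus_arm, n_cs_minus_arm,
                       odor_role = NA_character_, group_id = NA_character_,
                       timepoint_label = NA_character_,
                       protocol = NA_character_) {
  check_scalar_num(n_cs_plus_arm, "n_cs_plus_arm", lower = 0)
  check_scalar_num(n_cs_minus_arm, "n_cs_minus_arm", lower = 0)
  structure(list(n_cs_plus_arm = n_cs_plus_arm,
                 n_cs_minus_arm = n_cs_minus_arm,
                 odor_role = odor_role, group_id = group_id,
                 timepoint_label = timepoint_label, protocol = protocol),
            class = "arm_counts")
}

#' Performance index of one T-maze group
#'
#' `PerI = (#flies(CS-) - #flies(CS+)) / (#flies(CS+) + #flies(CS-)) * 100`:
#' positive values mean avoidance of the previously shock-paired odor.
#'
#' @param c an [arm_counts()] object, or the CS+ arm count when
#'   `n_cs_minus_arm` is given.
#' @param n_cs_minus_arm optional CS- arm count for the two-number call form.
#' @return performance index in `[-100, 100]`.
#' @export
performance_index <- function(c, n_cs_minus_arm = NULL) {
  if (!inherits(c, "arm_counts"))
    c <- arm_counts(c, n_cs_minus_arm)
  total <- c$n_cs_plus_arm + c$n_cs_minus_arm
  if (total <= 0) stop_input("undefined performance index: zero total flies")
  (c$n_cs_minus_arm - c$n_cs_plus_arm) / total * 100
}

#' Reciprocally averaged performance index
#'
#' Averages the performance indices of the two reciprocal groups (each
#' physical odor served once as CS+ and once as CS-), cancelling innate
#' odor bias.
#'
#' @param p a `reciprocal_pair` (list with `group_a` and `group_b`
#'   [arm_counts()]).
#' @return object of class `performance_index_final`: list with `value`,
#'   the two group indices and provenance.
#' @export
reciprocal_average <- function(p) {
  ga <- p$group_a; gb <- p$group_b
  if (!is.na(ga$odor_role) && !is.na(gb$odor_role) &&
      identical(ga$odor_role, gb$odor_role))
    stop_input("reciprocal groups must have opposite odor roles")
  pa <- performance_index(ga)
  pb <- performance_index(gb)
  structure(list(value = mean(c(pa, pb)),
                 group_values = c(a = pa, b = pb),
                 provenance = "reciprocal_average", corrected = FALSE),
            class = "performance_index_final")
}

#' Forgetting factor from two control genotypes
#'
#' `F = (dPerI(5d - 7d, control 1) + dPerI(5d - 7d, control 2)) / 2`: the
#' average natural 5-to-7-day memory decline of the controls.
#'
#' @param control1_5d,control1_7d,control2_5d,control2_7d performance-index
#'   values of the two control genotypes at 5 and 7 days.
#' @return object of class `forgetting_factor` (list with `value`).
#' @export
forgetting_factor <- function(control1_5d, control1_7d,
                              control2_5d, control2_7d) {
  vals <- c(control1_5d, control1_7d, control2_5d, control2_7d)
  if (any(!is.finite(vals))) stop_input("all four control values are required")
  structure(list(value = ((control1_5d - control1_7d) +
                            (control2_5d - control2_7d)) / 2,
                 day_pair = c(5, 7)),
            class = "forgetting_factor")
}

#' Apply the forgetting-factor correction to a 7-day performance index
#'
#' Adds the average natural forgetting of the controls back onto a raw
#' 7-day value, making 7-day scores directly comparable to 5-day scores.
#'
#' @param peri_7d raw 7-day performance index.
#' @param f a [forgetting_factor()] (or its numeric value).
#' @return corrected performance index.
#' @export
apply_forgetting_correction <- function(peri_7d, f) {
  fv <- if (inherits(f, "forgetting_factor")) f$value else f
  peri_7d + fv
}

#' Avoidance score for odor-acuity and shock-responsiveness controls
#'
#' `AS = (#flies(experimental tube) - #flies(control tube)) / total * 100`:
#' negative values mean avoidance of the experimental (odor or shock) tube.
#'
#' @param n_experimental_tube,n_control_tube nonnegative headcounts.
#' @return avoidance score in `[-100, 100]`.
#' @export
avoidance_score <- function(n_experimental_tube, n_control_tube) {
  if (is.list(n_experimental_tube)) {
    a <- n_experimental_tube
    n_control_tube <- a$n_control_tube
    n_experimental_tube <- a$n_experimental_tube
  }
  total <- n_experimental_tube + n_control_tube
  if (total <= 0) stop_input("undefined avoidance score: zero total flies")
  (n_experimental_tube - n_control_tube) / total * 100
}

#' Instantaneous light preference index at one arena sample
#'
#' `PI = (#flies(illuminated quadrants) - #flies(dark quadrants)) / total *
#' 100` for one occupancy snapshot during a light-on epoch.
#'
#' @param counts numeric length-4 quadrant counts `(q1, q2, q3, q4)`.
#' @param illuminated_pair `"pairA"` (quadrants 1 and 3) or `"pairB"`
#'   (quadrants 2 and 4); `"none"` is an error — the index is only defined
#'   while the light is on.
#' @return preference index in `[-100, 100]`.
#' @export
instant_pi <- function(counts, illuminated_pair) {
  if (identical(illuminated_pair, "none"))
    stop_input("instant_pi called during a light-off epoch")
  qi <- quadrants_of_pair(illuminated_pair)
  total <- sum(counts)
  if (total <= 0) stop_input("undefined preference index: zero flies")
  n_ill <- sum(counts[qi])
  (n_ill - (total - n_ill)) / total * 100
}

#' Total light preference index of one arena trial
#'
#' Instantaneous indices are computed at every sample falling in the final
#' `tail_s` seconds of each light-on episode; the total index is their mean
#' (10 samples at the 1 Hz / 30 s-episode defaults).
#'
#' @param s an `arena_series` (data.frame with `time_s`, `q1..q4`,
#'   `illuminated_pair`).
#' @param tail_s scored tail of each light-on episode, seconds (default 5).
#' @return object of class `light_preference`: list with `total_pi`,
#'   `instantaneous_pi`, `n_samples_used`.
#' @export
total_light_pi <- function(s, tail_s = 5) {
  stopifnot(is.data.frame(s))
  on <- s$illuminated_pair != "none"
  if (!any(on)) stop_input("series contains no light-on episode")
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ep_on <- which(r$values)
  if (length(ep_on) < 2)
    stop_input("protocol error: fewer than 2 light-on episodes")
  sel <- integer(0)
  for (e in ep_on) {
    i0 <- starts[e]; i1 <- ends[e]
    t_end <- s$time_s[i1]
    keep <- i0:i1
    keep <- keep[s$time_s[keep] > t_end - tail_s]
    sel <- c(sel, keep)
  }
  if (length(sel) == 0) stop_input("no samples fall in the scored tails")
  pis <- vapply(sel, function(i)
    instant_pi(as.numeric(s[i, c("q1", "q2", "q3", "q4")]),
               s$illuminated_pair[i]), numeric(1))
  structure(list(total_pi = mean(pis), instantaneous_pi = pis,
                 n_samples_used = length(pis),
                 condition = attr(s, "condition"),
                 trial_id = attr(s, "trial_id")),
            class = "light_preference")
}

#' Group difference in light preference (paired minus unpaired)
#'
#' @param paired,unpaired lists of [total_light_pi()] results (or numeric
#'   vectors of total indices), one per trial.
#' @return list with `delta_pi`, per-group means, and the per-trial values
#'   retained for statistics.
#' @export
delta_pi <- function(paired, unpaired) {
  as_vals <- function(x) {
    if (is.numeric(x)) return(x)
    vapply(x, function(p) p$total_pi, numeric(1))
  }
  pv <- as_vals(paired); uv <- as_vals(unpaired)
  if (length(pv) == 0 || length(uv) == 0)
    stop_input("both groups must be nonempty")
  list(delta_pi = mean(pv) - mean(uv),
       paired_mean = mean(pv), unpaired_mean = mean(uv),
       paired_values = pv, unpaired_values = uv)
}

#' Hemisphere lateral-bias summary
#'
#' Classifies each fly as right-biased, left-biased or tied by its labeled
#' cell counts, and reports the fraction right-biased among non-tied flies
#' (ties reported separately) together with the per-fly right-minus-left
#' differences used for testing.
#'
#' @param counts a `hemisphere_counts` data.frame (columns `left`, `right`).
#' @return list with `n`, `n_right_biased`, `n_left_biased`, `n_ties`,
#'   `fraction_right_biased` (ties excluded), `diff_right_minus_left`,
#'   and per-hemisphere summaries.
#' @export
hemisphere_bias <- function(counts) {
  stopifnot(is.data.frame(counts), all(c("left", "right") %in% names(counts)))
  if (nrow(counts) == 0) stop_input("empty count table")
  d <- counts$right - counts$left
  n_r <- sum(d > 0); n_l <- sum(d < 0); n_t <- sum(d == 0)
  list(n = nrow(counts),
       n_right_biased = n_r, n_left_biased = n_l, n_ties = n_t,
       fraction_right_biased = if (n_r + n_l > 0) n_r / (n_r + n_l) else NA_real_,
       diff_right_minus_left = d,
       mean_left = mean(counts$left), mean_right = mean(counts$right))
}
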
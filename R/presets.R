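#' Published effect-size presets for the engram assays
#'
#' Effect sizes reported for sparse Kenyon-cell engram labeling, used as
#' injection targets for the synthetic generators in recovery analyses:
#' innate odor-responder rates of reporter-labeled cells and of the full
#' labeled KC population (percent of cells), and the optogenetic-reactivation
#' light-avoidance effects (preference-index units, paired minus unpaired)
#' 2 and 4 days after spaced training in retinal-fed flies.
#'
#' @return named list of numeric presets:
#'   `innate_camel_oct_pct` (4.1), `innate_camel_mch_pct` (5.5),
#'   `allkc_oct_pct` (5.8), `allkc_mch_pct` (3.9),
#'   `delta_pi_2d` (-12.44), `delta_pi_4d` (-12.06).
#' @export
assay_presets <- function() {
  list(
    innate_camel_oct_pct = 4.1,
    innate_camel_mch_pct = 5.5,
    allkc_oct_pct = 5.8,
    allkc_mch_pct = 3.9,
    delta_pi_2d = -12.44,
    delta_pi_4d = -12.06
  )
}
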
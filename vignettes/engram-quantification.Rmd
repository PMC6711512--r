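---
title: "Quantifying sparse memory-engram assays: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sparse memory-engram assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(engramassay)
```

# The problem

Sparse-engram studies in the *Drosophila* mushroom body ask whether a small,
tagged subset of Kenyon cells (KCs) carries an aversive olfactory long-term
memory. Answering that requires four quantitative pipelines, each of which
this package implements end to end:

1. **Calcium response calling** — deciding, per cell and per odor
   presentation, whether a GCaMP \eqn{\Delta F/F} trace contains a
   stimulus-locked response, and aggregating those calls into responder
   fractions per animal and per cohort.
2. **T-maze behavioral indices** — the performance index (PerI) with
   reciprocal-group averaging, the avoidance score (AS) for sensory
   controls, and a forgetting-factor correction for cross-day comparisons.
3. **Optogenetic light-preference quantification** — time-resolved
   preference indices (PI) in a four-quadrant arena and the
   paired-minus-unpaired group difference ΔPI.
4. **Hemisphere-resolved cell-count analysis** — per-fly left/right labeled
   KC counts and lateral-bias summaries.

A fifth component, the **statistics dispatcher**, reproduces the
normality-gated choice between parametric and nonparametric tests with
Bonferroni (after ANOVA) or Dunn's (after Kruskal-Wallis) corrections that
this class of study applies uniformly.

Because live-fly data cannot be regenerated, every pipeline is paired with
a **synthetic-data generator** whose injected ground truth the pipeline
must recover. The generators are first-class, tested code: their defaults
encode the study conditions, and the recovery analyses under `analysis/`
are the package's primary outputs.

# Calcium response calling

## The procedure

For each cell and sweep, the raw fluorescence trace \eqn{f(t)} is
normalized as \eqn{(f - f_0)/f_0}, where \eqn{f_0} is the mean of the
first 28 frames (4 s at the 7 Hz default). The baseline SD is the standard
deviation of the normalized trace over those 28 frames. A centered 5-point
running average of the normalized trace is used for peak extraction: the
peak is the maximum of the smoothed trace over frames whose onset-relative
time lies in 0–4.5 s (inclusive rounded frame range), and a presentation is
scored a **response** when the peak strictly exceeds 2.33 × baseline SD.
2.33 is the one-sided Gaussian quantile for α = 0.01, so the criterion is a
per-presentation exceedance test at nominal 1% on independent samples
(smoothing makes the realized false-positive rate far lower; the
Monte-Carlo calibration test quantifies this).

A cell is **stimulus specific** for an odor when ≥ 2 of its 3
presentations of that odor responded (`classify_stimulus_specific`,
`min_hits = 2`). Cells with fewer presentations than `min_hits` are marked
indeterminate rather than negative. Two session modes reflect the two
acquisition protocols: `"allkc"` applies the 2-of-3 rule; `"camel"` (the
conditioning-round routine, where each odor appears once in the automated
sequence) scores a cell responsive on its single presentation.

## Numerical choices

* **Baseline SD on the unsmoothed normalized trace.** The procedure
  defines the SD "of the baseline" before introducing the smoothed trace,
  so the default computes it unsmoothed; `sd_on_smoothed = TRUE` switches.
* **Window anchored at stimulus onset**, as the analysis-window markers in
  this assay class start at presentation onset. The frame range is the
  inclusive `[round(onset·rate), round((onset+4.5)·rate)]`.
* **Edge handling of the running average**: the centered window shrinks
  symmetrically at the ends, so constants and linear ramps pass through
  unchanged and the output length equals the input length.
* **Ties at threshold are not responses** (strict inequality), which also
  makes the degenerate zero-noise, zero-peak trace a deterministic
  non-response.
* **Manual window adjustments** that a human analyst might make are
  deliberately out of scope; all calls are algorithmic.

## The trace generator

Transient shape is not dictated by the detection rule, so the generator
uses a difference of exponentials \eqn{e^{-t/\tau_d} - e^{-t/\tau_r}}
normalized to unit peak, with GCaMP6f-like defaults
\eqn{\tau_r = 0.1} s, \eqn{\tau_d = 0.4} s. Only the peak amplitude
relative to baseline SD matters for the detector, and amplitude is
parameterized directly in SD units. Cells are 7 Hz / 20 s sweeps of
Gaussian noise (optionally with linear drift) and exactly
`round(responder_fraction × n_cells)` true responders; a cohort generator
allocates `round(fraction × total cells)` responders across sessions by
largest-remainder rounding so the *pooled* injected rate is exact by
construction. Trial-to-trial amplitude variability within a responder is
exposed as `amplitude_cv` (default 0, since the source assays report no
within-cell variability value).

What the generator does **not** emulate: motion artifacts and
registration error, correlated (shot-noise, neuropil) backgrounds,
overlapping ROIs, and odor-offset responses. Recovery tests passing here
show the calling logic is correct and calibrated, not that it is robust to
those real-data failure modes.

# Behavioral indices

All indices live on the ×100 percent scale and share the same structure,
`(a − b)/(a + b) × 100`:

* **PerI** uses CS− minus CS+ arm counts, so avoidance of the
  shock-paired odor is positive. Each experiment trains two groups with
  the odor roles swapped; the **final PerI** is the mean of the two group
  PerIs. In the generator, innate odor bias enters the choice probability
  with opposite sign in the two groups, so reciprocal averaging cancels it
  exactly in expectation — the null-index property test verifies this at
  10,000 simulated pairs.
* **AS** uses experimental-tube minus control-tube counts (odor or shock
  acuity controls).
* **Instantaneous PI** uses illuminated-minus-dark quadrant counts and is
  defined only during light-on epochs; the **total PI** of a trial is the
  mean of the instantaneous PIs over the final 5 s of each of the two
  light-on episodes — 10 samples at the 1 Hz default, which is the rate
  that makes the canonical "10 PIs" arithmetic come out. **ΔPI** is the
  paired-group mean minus the unpaired-group mean.
* **Forgetting factor** `F = (ΔPerI(5d−7d, control 1) + ΔPerI(5d−7d,
  control 2))/2`; the corrected 7-day score is `raw + F`. The direction
  (adding to 7-day rather than subtracting from 5-day values) is chosen so
  corrected 7-day control means equal their 5-day means identically — an
  algebraic identity the tests assert on random inputs. Zero-total runs
  raise errors rather than returning 0, since a zero index is a meaningful
  behavioral statement.

## The arena generator

Flies relocate as a Markov process: each 1 Hz step a fly relocates with
probability `min(1, switching_rate/sampling_rate)` (default 0.5) and draws
its destination from the current target distribution — illuminated pair
with probability `0.5 + light_bias/2` during light-on, uniform in the
dark. The stationary illuminated-pair occupancy during light-on is
therefore exactly `0.5 + light_bias/2`, so the expected total PI equals
`100 × light_bias`, and equilibration error at the scored tails decays as
`(1 − move_p)^t` (≈ 3×10⁻⁸ after 25 s at defaults). Any relocation model
with controllable stationary bias would do, since the assay only consumes
occupancy snapshots; the Markov form adds realistic autocorrelation
between the 5 tail samples of an episode. Real flies additionally show
wall-following, thigmotaxis, and startle responses at light transitions;
none of these are modeled, and ΔPI recovery here validates the index
arithmetic and sampling design, not fly behavior.

## The hemisphere-count generator

Counts are negative binomial with mean μ per hemisphere and variance
`μ + dispersion·μ²`; `dispersion = 0` is implemented as the deterministic
noise-free limit (`left = right = round(μ)` exactly). The lateral bias is
additive on the log-mean (`mean_right = μ·e^{bias}`), which keeps counts
nonnegative for any bias. Ties are excluded from the right-biased-fraction
denominator and reported separately, because the scientific claim is about
which hemisphere holds *more* cells.

# Statistics dispatch

The implemented content is the *policy*, not the tests: each group is
screened with Shapiro-Wilk (n ≥ 3) and the D'Agostino-Pearson omnibus
(n ≥ 8; skewness z per D'Agostino 1970, kurtosis z per Anscombe & Glynn
1983, `K² = z_s² + z_k²` against χ²₂ — implemented here and verified to
10 decimals against an independent reference implementation). A group is
non-normal when **either** applicable test rejects at α = 0.05 (the
disjunctive reading; `rule = "both"` is available), and the family is
nonparametric when **any** group is non-normal or untestable (n < 3 gives
an indeterminate verdict and a conservative nonparametric family).

Dispatch: unpaired pooled-variance t test vs Mann-Whitney for two groups;
one-way ANOVA with pooled-MSE pairwise t tests and Bonferroni correction
vs Kruskal-Wallis with Dunn's rank z tests for ≥ 3 groups. The
"relevant groups" to compare must be named explicitly — there is no
all-pairs default, so the correction family is exactly the declared set,
and corrected p is `min(1, raw × m)` in both branches. A type-I
calibration test (2,000 null simulations) checks the dispatched two-group
path holds 5%.

# Problem sizes and reproducibility

Recovery analyses use the assay-scale designs: 8 sessions × 30 cells for
single-presentation mode, 16 × 30 for the 2-of-3 mode, 18 trials × 20
flies per arena group, 150 flies per count cohort, with transients at
5 × baseline SD. The acceptance script raises the arena simulation to
2,000 trials per group — a Monte-Carlo size chosen so the standard error
of the recovered ΔPI (≈ 0.2 PI units) is small relative to the injected
effect; the per-trial design is unchanged. Every generator takes an
integer seed and is bit-reproducible; `run_experiment()` records the seed
and per-file checksums in a manifest, and identical config + seed yields
identical result checksums.

# Known limitations

* Generators model measurement structure, not biology: memory is a latent
  scalar, plasticity has no mechanism, and calcium transients are
  noise-plus-kernel, so passing recovery says nothing about ROI
  segmentation or registration quality on real movies.
* The detection false-positive rate at the default threshold is
  effectively zero because smoothing shrinks noise ~√5-fold while the
  threshold is set on unsmoothed baseline SD; the calibration suite
  therefore also probes k = 1, where exceedances actually occur.
* The hemisphere analysis at n = 150 has visible type-I risk for lateral
  bias (the bundled driver reproduces exactly such a false positive and
  labels it), which is an argument for the replication the assays use,
  not a defect of the index.
* D'Agostino-Pearson is skipped below n = 8, where only Shapiro-Wilk
  gates; at n < 3 the family defaults to nonparametric.
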
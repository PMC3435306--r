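---
title: "Biomarker panel discovery from MALDI-TOF profile spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biomarker panel discovery from MALDI-TOF profile spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maldirf)
```

## The problem

Linear MALDI-TOF profiling of a biofluid's low-molecular-weight proteome
yields, per sample, an intensity-versus-m/z profile spectrum (here m/z
1,000–10,000 Da). Given a labeled case/control cohort of such spectra, the
goal is threefold: find the reproducible mass peaks, build a multivariate
classifier from their intensities, and reduce the peak set to a small
biomarker panel whose cross-validated discrimination is at least as good as
the full set. `maldirf` implements that workflow end to end, together with
a synthetic-cohort generator with known ground truth, so that every stage
is testable without access to any particular instrument's raw data.

## The processing model

**Preprocessing.** Raw spectra are linearly resampled onto a common 1 Da
grid, quality-controlled (raw total ion count below a threshold, or Pearson
correlation to the cohort mean below 0.5, excludes a spectrum), baseline
corrected, and normalized to a common total ion count (TIC, target 1). The
baseline estimator is a rolling minimum over a 200 Da window followed by a
moving average of the same width, clamped to never exceed the spectrum;
subtraction clamps at zero since intensities are physically non-negative.
These operators are deliberately simple and monotone: the rolling minimum
tracks any baseline that is slowly varying relative to the window, and its
closed-form behavior on an exponential decay is used as a numerical test
oracle (within 5% away from the edges at the default window). The pipeline
order is fixed — resample, QC, baseline, normalize — and normalization is
idempotent.

**Peak detection** operates on the *mean* preprocessed spectrum, so peak
positions are defined cohort-wide and every sample is quantified at the
same masses. A local maximum of the lightly smoothed (5 Da) mean spectrum
is a peak if its height reaches `snr_min` (default 2) times the local
noise, estimated as 1.4826 times the running median absolute deviation of
the detrended signal in a 250 Da window. Height is measured above a
running-median trend over the same window: per-spectrum baseline
correction clamps negative noise at zero, which leaves a small positive
offset in signal-free regions of the mean spectrum, and without the trend
step that offset masquerades as signal-to-noise. Retained maxima are
thinned to a 5 Da minimum separation (higher peak wins, ties to lower
m/z). One consequence of trend-relative heights is worth knowing: a small
peak within roughly six peak-widths of a much larger neighbor can be
shadowed by the neighbor's flank; on default synthetic cohorts this costs
0–4 of 153 planted peaks.

**Quantification.** Each peak gets a window of half the distance to its
nearest neighbor, capped at 0.3% of its mass. A sample's feature value is
the maximum preprocessed intensity in the window — robust to the ~0.5 Da
m/z jitter between acquisitions, which an area integral would smear —
averaged over the sample's technical replicates. Peak identifiers are
masses rounded to two decimals ("8398.49"), with letter suffixes on
collisions.

Because features are TIC-normalized, they are compositional: a marker's
own fold change slightly shifts its group's total signal, so a planted
fold change FC is recovered as FC × (TIC~control~/TIC~case~), an ~1%
coupling at 153 peaks. Tests assert recovery within that bound; exact
equality is impossible under TIC normalization.

**Classification.** A Random Forest (500 trees by default,
`mtry = floor(sqrt(p))`, bootstrap sampling with replacement; tree
induction delegated to the `randomForest` package) exposes out-of-bag
(OOB) vote fractions — the share of trees voting "case", read as a degree
of class membership — the OOB error, and permutation importance as mean
decrease in accuracy (MDA), both raw and as a z-score (MDA divided by its
standard error). Class assignment is by strict major vote: a sample is a
case only if *more* than 50% of trees say so; exactly 50% is a control
call. The ROC/AUC is rank-based on vote fractions (ties count one half),
and the trapezoidal area under the returned ROC points equals that AUC
identically.

**Cross-validation.** Generalization is estimated by 10 independent
repetitions of stratified 10-fold CV, so each sample is in the test set
exactly 10 times; a 58-sample cohort yields 580 pooled predictions (350 on
cases, 230 on controls). Predictions are pooled across repetitions before
computing AUC and the major-vote accuracy/sensitivity/specificity, which
are reported as percentages to one decimal. Any feature selection that
uses class information can be passed as an in-fold selector, in which case
it runs on training folds only.

**Panel selection.** Recursive feature elimination fits a forest, removes
every feature whose MDA is *strictly below* the median MDA of the current
set, and repeats until fewer than two features would remain. With pairwise
distinct importances this halves the set each round — from 153 features
the recorded sizes are 153, 77, 39, 20, 10, 5, 3, 2, with the second step
at the "top 25%" scale. Features exactly at the median are kept, which
makes the schedule deterministic; in practice ties at zero MDA among
uninformative features slow the halving somewhat. Every recorded set is
scored by the repeated CV above and the highest pooled AUC wins, ties
going to the smaller set. Because that selection sees the full data, an
unbiased estimate for a panel of the selected *size* comes from
`nested_performance()`, which reruns the elimination schedule inside every
training fold and keeps the set whose size fraction matches the globally
selected one; disabling the selector reduces it to plain `repeated_cv()`
exactly.

**Univariate screening** is a two-sided Wilcoxon rank-sum test per feature
plus a fold change (case mean / control mean; below 1 is down-regulated).
Raw p ≤ 0.05 is tiered "significant" and 0.05 < p ≤ 0.1 "trend", the
conventional raw-p tiers for this assay; a Benjamini–Hochberg column is
appended as clearly supplementary output. The exact null distribution is
enumerated when the smaller group has at most 8 tie-free observations,
otherwise the normal approximation with tie and continuity corrections is
used; the worst-case disagreement between the two modes is 0.0102 at group
sizes 8/9 and below 0.01 from 9/10 upward.

## What the synthetic generator emulates

`sim_config()` defaults describe a discovery cohort of 35 cases and 23
controls on a 1 Da grid over 1,000–10,000 Da with 153 peaks, five of which
are markers with fold changes 0.79, 0.90, 0.94, 0.96 and 1.5:

* **Peaks** are Gaussians with sd = 0.002 × m/z (linear-TOF resolution),
  centers drawn log-uniformly (denser at low mass, like matrix-assisted
  spectra) with at least 4 sd separation so peaks never fuse; base
  amplitudes are log-uniform on 10–100 arbitrary units.
* **Baseline** 20·exp(−(m−1000)/3000): a matrix-cluster background
  dominating low m/z.
* **Additive noise** sd 1 per grid point, i.e. signal-to-noise 10 at the
  smallest peaks.
* **Per-sample intensity scale**, log-normal with log-sd 0.2, shared by a
  sample's technical replicates — the multiplicative instrument variation
  that TIC normalization is designed to remove.
* **Per-sample biological variability**: every peak's amplitude in every
  sample carries a log-normal factor with log-sd 0.35 (~36% inter-subject
  CV, mid-range for biofluid peptide abundances), also shared by
  replicates. This term is what makes replicates cluster by biological
  origin in a PCA, and it keeps case/control separation imperfect: with
  the configured marker effects the expected panel discrimination is
  Φ(√(Σ log²FC)/0.35/√2) ≈ 0.84, the AUC regime typical of real profiling
  cohorts of this size. Without it, synthetic cohorts are perfectly
  separable and panel selection degenerates to two peaks.
* **m/z jitter** sd 0.5 Da per spectrum and peak (calibration drift).

All draws flow from one seed in a fixed, documented order, so cohorts are
bit-reproducible. The generator does **not** emulate isotope patterns,
adducts, detector saturation, autocorrelated chemical noise, or
heavy-tailed outlier samples; passing tests on synthetic cohorts therefore
demonstrate the statistical machinery (bookkeeping, selection behavior,
calibration under the null), not robustness to every artifact of real
spectra.

A consequence of realistic biological variability worth stating plainly:
markers with fold changes 0.94–0.96 are statistically invisible at n = 58
(per-feature standardized effect ≈ 0.12), so selected panels reliably
contain the strong markers (FC 1.5, 0.79) but not the weak ones. Only an
implausibly noise-free cohort would make all five recoverable — and such a
cohort saturates the AUC, at which point the smaller-set tie-break
truncates the panel instead. Panel *membership* recovery of weak effects
at this sample size is not an achievable guarantee; panel *performance*
is.

## Numerical and design choices

* Windows given in Da are converted to odd point counts; edge windows
  shrink (rolling minimum and moving average) rather than extrapolate.
* Vote fraction exactly 0.5 → control; AUC ties count 0.5; equal-height
  detection maxima keep the lower mass — every tie-break is deterministic.
* Forest seeds, fold assignments and repetition seeds are derived from one
  master seed through a fixed splitting scheme, so adding draws in one
  stage never perturbs another and reports are byte-identical across runs.
* An all-zero spectrum raises a QC condition on normalization rather than
  propagating silently; QC refuses to exclude the entire cohort.
* Degenerate inputs: empty peak sets are legal detection output (all-zero
  mean spectrum); constant features get p = 1 with a warning; fold changes
  with non-positive control means are errors (single features) or NA with
  a warning (tables).

The test suite runs forests at 40–100 trees and cohorts of 16–58 samples
with 12–153 peaks; these sizes were chosen so the full suite exercises the
default 35/23-cohort geometry (580 pooled predictions) while completing in
a few minutes. The CV geometry itself (10 × stratified 10-fold) is never
reduced where a check concerns bookkeeping or selection structure.

## Known limitations

* Detection quantifies at cohort-wide mean-spectrum positions; there is no
  per-spectrum re-centering, deisotoping or recalibration, and alignment
  beyond common-grid resampling is out of scope.
* The quantification statistic is the windowed maximum (an area option
  exists at the API level via the window widths but the maximum is the
  tested default).
* TIC normalization makes features compositional (see above).
* `wilcoxon_two_sided()` switches to the exact mode only for small
  tie-free groups; concentration tables with heavy rounding always use the
  corrected normal approximation.
* mzML input/output is not implemented; the interchange formats are the
  two-column text spectrum, the sample-sheet CSV, and CSV/JSON artifacts.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(sim = sim_config(seed = 11), n_trees = 100, seed = 11)
report <- run_pipeline(cfg, outdir = "run11")
report
```

The report prints the QC summary, the detected peak count, full-set and
selected-panel pooled CV performance, the nested estimate, and — for
simulated input — how many planted markers ended up in the selected panel.
All artifacts (peak list, feature matrix, ranked panel with MDA z-scores,
ROC points, univariate table, RFE trace, report JSON) are written to the
output directory and round-trip through their readers.
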
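---
title: "Decoding hippocampal subfield activity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding hippocampal subfield activity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`hippmvpa` implements a complete multi-voxel pattern analysis (MVPA)
pipeline for region-of-interest fMRI decoding, of the kind used to ask
whether hippocampal subfields (CA1, CA3, dentate gyrus, subiculum) carry
information about perceived and internally reconstructed scenes. Because no
scanner data ship with the package, a synthetic cohort generator with known
ground truth stands in for acquisition: every downstream stage can be tested
end-to-end, including its statistical calibration.

This vignette records the scientific model of each stage, the parameters
that matter, and the design decisions that were genuinely open.

## The experimental design being emulated

The generator reproduces the structure of a scene-morph decision experiment:

* 16 subjects; 9 stimulus categories — two original scenes ("A", coded as
  morph fraction 1.0, and "B", fraction 0.0) and seven morphs
  (fractions 0.7, 0.6, 0.55, 0.5, 0.45, 0.4, 0.3) — each presented 40 times
  in a pseudo-random order with exactly balanced counts;
* each trial occupies a fixed 7.5-s block: 2.5 s stimulus/decision window,
  3 s confidence rating, 2 s rest;
* functional volumes at TR 3.5 s with 1.5 mm isotropic voxels;
* four bilateral subfield ROIs, with per-hemisphere voxel counts near the
  group means reported for manual segmentation at this resolution
  (CA1 267, CA3 248, DG 183, SUB 111), jittered ±5% per subject.

Behavior follows a logistic psychometric function: the probability of
choosing scene A is `plogis(slope * (f - 0.5))` with `f` the scene-A
fraction and `slope = 10` by default, which gives near-perfect accuracy on
the originals and coin-flip choices on the 50% morph, with a sigmoid in
between. Confidence (1 = not sure, 2 = fairly sure, 3 = very sure) comes
from an ordinal model whose expected rating increases with evidence
`|f - 0.5|`; the default intercepts were set so that the standard exclusion
rules remove roughly 9% of original-scene trials and roughly 24% of 50%-morph
trials, the magnitudes typical of this paradigm. Both rates remain free
parameters (`no_decision_rate`, `conf_intercepts`, `conf_slope`) because the
per-category post-exclusion counts of real experiments are not part of the
generator's contract.

## Forward model of the BOLD signal

Each ROI receives i.i.d. standard-normal multivoxel patterns: one for scene
A, one for scene B. Intermediate morphs use the graded mixture
`f * pattern_A + (1 - f) * pattern_B`. The fully ambiguous 50% morph is
special: each trial is assigned a latent decision state (the simulated
choice), and its pattern is a *decision-state* pattern constructed as

```
pattern_50 = w * pattern_scene + sqrt(1 - w^2) * pattern_independent
```

so that its correlation with the corresponding scene pattern equals `w =
morph_pattern_share` by construction. The weights are `(w, sqrt(1 - w^2))`
rather than a convex pair `(w, 1 - w)` precisely so the `share` parameter
*is* the correlation; the two limits are unchanged (identical patterns at
`w = 1`, independent at `w = 0`).

The default is `morph_pattern_share = 0`. That choice encodes the
dissociation this paradigm is designed to detect: a classifier trained on
the original scenes does not transfer to choice-labelled 50% morphs (ruling
out a motor account of scene decoding), while the 50% morphs are themselves
highly decodable from their own decision-state patterns. Setting `share`
towards 1 moves cross-decoding from chance to the within-condition ceiling,
which is what the cross-decoding tests exploit.

Trial patterns are scaled by `pattern_amplitude`, placed as boxcars of the
stimulus duration, convolved with the canonical HRF, and summed with i.i.d.
Gaussian noise (`noise_sd`, default 1) on every grid voxel, plus an optional
linear drift. The default `pattern_amplitude = 0.3` (in noise-SD units per
voxel) is a moderate multivoxel effect: well above chance but below ceiling
for ROIs of a few hundred voxels. The noise is deliberately white — no
autocorrelation, motion, or physiological structure — because the
pipeline's acceptance properties (chance calibration, leakage freedom,
signal recovery, cross-condition dissociation) do not depend on noise
color, and white noise keeps every calibration argument exact. Passing
tests on this generator therefore demonstrates the *procedures* are
correct, not that real scanner noise is benign.

Masks are grown as random 6-connected blobs inside disjoint spatial
compartments (left/right along x, one subfield per y-z quadrant). Only the
properties downstream code relies on are guaranteed — counts,
disjointness, connectedness — since real subfield anatomy neither can nor
needs to be reproduced for testing the analysis machinery.

## Per-trial GLM (beta series)

Volumes are smoothed with an isotropic Gaussian kernel (default FWHM 3 mm,
`sigma = FWHM / (2 sqrt(2 ln 2))`, truncated at 3 sigma, renormalized).
Boundaries are handled by half-sample reflection, which makes the filter
mass-preserving: constants stay constant and the image sum is unchanged.

Each trial is its own regressor: a boxcar of the stimulus duration at the
trial onset convolved with the canonical double-gamma HRF (peak delay 6 s,
undershoot delay 16 s, unit dispersions, undershoot ratio 1/6, 32 s
support — the conventional meaning of "canonical"). Convolution runs on a
grid 16x finer than the TR and is evaluated through the kernel's cumulative
sum, which is algebraically identical to convolve-then-decimate but O(1)
per sample; onsets therefore need not align with the TR. Columns are trial
regressors in event order, then any nuisance regressors, then an intercept.
Per-voxel coefficients come from ordinary least squares via a QR
decomposition; rank deficiency is an error that names the collinear
columns. No high-pass filter or autocorrelation model is applied: the
synthetic noise is white, and the contracts tested (exact noiseless
recovery, residual orthogonality) are properties of OLS itself. One run per
subject is assumed; nothing in the interfaces precludes concatenating runs
with per-run nuisance columns.

Trial exclusions mirror the two analysis families: original-scene analyses
keep correct, decided, at-least-fairly-sure trials of the two originals;
50%-morph analyses keep decided, at-least-fairly-sure morph trials, with no
correctness rule because the ambiguous stimulus has no right answer.

## Two-step decoding: searchlight selection inside nested LOO

Decoding is the two-step procedure: feature selection by an ROI-restricted
searchlight, then a linear support vector machine on the selected voxels.

* **Searchlight.** A sphere of radius 3 voxels (123 offsets) is centred on
  every ROI voxel and intersected with the ROI, so spheres shrink near
  borders. Each center is scored by the leave-one-out cross-validated
  accuracy of a linear SVM on its sphere's features, computed strictly
  within the training trials of the current outer fold.
* **Selection rule.** Reported mean selected-voxel counts in this
  literature (~164 of ~267 CA1 voxels) exceed a single radius-3 sphere
  (123), so a single best sphere cannot be the mechanism. The default rule
  ranks centers by score — ties broken lexicographically by center
  coordinate, for determinism — and takes the union of top-ranked
  neighborhoods, stopping once the union covers `target_fraction` (default
  0.6) of the ROI. On CA1-sized ROIs this selects ~160–175 voxels,
  straddling the reported means. A `single_best` rule is retained as an
  option.
* **Classifier.** Linear SVM with fixed cost C = 1, no hyperparameter
  search. The dual problem is solved on precomputed Gram matrices by an SMO
  solver with maximal-violating-pair working-set selection (KKT tolerance
  1e-4, fixed trial order), written for this package because the nested
  procedure needs on the order of 10^4–10^6 small fits per decoding run.
  The solver is cross-checked in the test suite against libsvm (via e1071)
  on identical Gram matrices; decision-value ties resolve to the first
  class label.
* **Outer loop.** Leave one trial out; within each fold, searchlight
  scoring and selection see only the n - 1 training trials ("no double
  dipping"); the held-out trial is predicted once. Accuracy is the fraction
  of correct held-out predictions. Cross-condition decoding trains
  selection and SVM once on the full training condition and evaluates once
  on the disjoint test condition.

### A note on null calibration

Under *i.i.d.* random relabeling, any leakage-free decoder has exactly 50%
expected accuracy — the held-out label is independent of everything the
classifier sees. Under an *exactly balanced* label permutation, however,
leave-one-out is systematically anti-biased: the held-out trial's class is
always the training minority, and on pure noise a margin classifier drifts
toward the training majority, driving accuracy far below chance (to 0 in
the worst case). This is a property of balanced LOO itself, not of any
implementation. The chance-calibration tests and the acceptance script
therefore use i.i.d. label randomization as the null; the near-balanced
choice labels of real designs sit between the two regimes, which is worth
remembering when comparing empirical accuracies against 50%.

## Group statistics

Per-subject, per-ROI, per-hemisphere accuracies are analysed exactly as in
conventional reports: a per-region two-level repeated-measures ANOVA
comparing hemispheres (numerically identical to the squared paired t, an
identity the tests verify to 1e-8), after which hemispheres are averaged
regardless of outcome, with the test reported alongside; two-sided
one-sample t-tests against 50% chance; a one-way repeated-measures ANOVA
across the four subfields with `F = MS_region / MS_(subject x region)` and
dfs `(r - 1, (r - 1)(n - 1))`; and all six pairwise paired t-tests. No
sphericity correction is applied by default (a Greenhouse–Geisser option
exists) and no multiple-comparison correction is applied across the six
pairwise tests — both choices mirror conventional reporting and are
deliberate caveats, not oversights. Degenerate inputs (zero-variance
accuracy vectors or difference columns) are reported as explicit degenerate
cases rather than fabricated p-values. Dice overlap, used for
segmentation-reliability bookkeeping, is `2|A∩B| / (|A| + |B|)` — the
"overlap over mean volume" phrasing is algebraically the classical Dice
coefficient — with a slice-restricted variant for the five-consecutive-slice
reliability protocol; which slices constitute the body of the structure is
an explicit input, since no anatomy exists in the generator.

## Problem sizes and numerical choices

The full paper-scale configuration (16 subjects, 360 trials, eight ROIs of
100–300 voxels) is the generator's default and runs in hours, dominated by
the inner searchlight LOO. The test suite and the acceptance script use
reduced-scale cohorts — single-ROI layouts of 60–80 voxels on grids around
14x14x10, 12–20 repeats per category — chosen so the whole suite runs in a
few minutes while every procedure (forward model, smoothing, GLM,
exclusion rules, nested selection, SVM, group tests) executes exactly as at
full scale. The signal-recovery sweep uses amplitudes 0.05–0.25 because
that range spans chance to ceiling at this ROI size; the monotonicity check
compares level means over 20 replicates per level.

Numerical conventions worth knowing: voxel coordinates are 0-based in beta
series and mask sidecars (NIfTI convention) and 1-based inside R code;
smoothing boundary handling is half-sample reflection; SVM decision ties
break to the first class; score ties in selection break lexicographically;
all randomness flows from explicit seeds through an internal child-seed
derivation, so identical configs are bit-identical, and seed arguments
never disturb the caller's RNG state.

## Known limitations

* The generator's noise is white and its patterns are stationary across
  trials; habituation, drift of representations, and correlated noise are
  out of scope, so real-data effect sizes cannot be extrapolated from
  synthetic accuracies.
* Anatomical segmentation is simulated, not automated: the Dice machinery
  measures agreement between masks however produced; it does not segment.
* The exact mechanism behind reported selected-voxel counts is not
  documented in this literature; the union rule is one mechanism consistent
  with the printed numbers, and both rules are exposed so the choice is a
  config field rather than a hidden constant.
* The repeated-measures error dfs follow `(r - 1)(n - 1)`; published tables
  sometimes print smaller error dfs for the same design, and no attempt is
  made to emulate that.
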
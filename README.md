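# hippmvpa

Multi-voxel pattern analysis (MVPA) for region-of-interest fMRI decoding,
built for the hippocampal-subfield setting: can the distributed pattern of
activity across the voxels of CA1, CA3, dentate gyrus (DG) and subiculum
(SUB) predict which of two highly similar scenes a participant is viewing —
and, on fully ambiguous 50% morphs of the two scenes, which scene the
participant *decides* they are seeing?

The package is aimed at researchers who want a tested, reproducible
implementation of the classic two-step ROI decoding pipeline, together with
a synthetic cohort generator with known ground truth so that every stage —
including its statistical calibration — can be verified without scanner
data.

## What it implements

1. **Synthetic cohort generator** (`sim_config()`, `simulate_subject()`,
   `run_cohort()`): subfield masks as random connected blobs at realistic
   voxel counts, balanced pseudo-random event schedules (9 morph categories
   x 40 presentations, 2.5 s / 3 s / 2 s trial blocks), logistic
   psychometric behavior with ordinal confidence, and BOLD at TR 3.5 s with
   embedded multivoxel patterns plus Gaussian noise.
2. **Per-trial GLM** (`smooth_gaussian()`, `build_design()`,
   `fit_beta_series()`): 3-mm FWHM smoothing, one regressor per trial
   (boxcar convolved with the canonical double-gamma HRF), nuisance and
   intercept columns, per-voxel OLS giving the trials x voxels *beta
   series*; trial exclusion rules via `filter_trials()`.
3. **Two-step decoding** (`searchlight_scores()`, `select_features()`,
   `loo_decode()`, `cross_decode()`): an ROI-restricted searchlight
   (radius 3, 123-voxel sphere clipped at ROI borders) scores every voxel
   by the leave-one-out accuracy of a linear SVM (fixed C = 1) on its local
   neighborhood — computed on the training trials of the current fold only;
   top-ranked neighborhoods are merged into the selected voxel set; an
   outer leave-one-trial-out loop yields a cross-validated accuracy that is
   free of selection leakage. Cross-condition decoding (train on 100%
   scenes, test on choice-labelled 50% morphs) implements the motor-confound
   control.
4. **Segmentation reliability** (`dice()`, `dice_on_slices()`): the Dice
   overlap `2|A∩B|/(|A|+|B|)`, including the five-consecutive-slice
   protocol used for intra-/inter-rater comparisons.
5. **Group statistics** (`ttest_vs_chance()`, `rm_anova()`,
   `paired_ttests()`, `hemisphere_check_and_collapse()`): t-tests against
   50% chance, one-way repeated-measures ANOVA across subfields, pairwise
   paired t-tests, and the hemisphere comparison-then-collapse step.

The decoder's inner loop solves the SVM dual by SMO on precomputed Gram
matrices (C++), cross-checked against libsvm in the test suite.

## Worked example

A four-subject cohort at reduced scale (small grid, 20 repeats per
category, moderate pattern amplitude 0.25 in noise-SD units):

```r
library(hippmvpa)
cfg <- sim_config(n_subjects = 4, grid_dims = c(20, 20, 12),
                  n_repeats_per_stimulus = 20,
                  pattern_amplitude = 0.25, noise_sd = 1,
                  target_counts = c(CA1 = 50, CA3 = 45, DG = 35, SUB = 25),
                  seed = 12)
run <- run_cohort(cfg)
summary(run)
```

```
<cohort_run> 4 subjects, analyses: scenes, cross, morph50
  cross    CA1 0.598  CA3 0.610  DG 0.476  SUB 0.556
  morph50  CA1 0.710  CA3 0.744  DG 0.651  SUB 0.592
  scenes   CA1 1.000  CA3 0.939  DG 0.944  SUB 0.813

-- scenes: t-tests vs chance (50%) --
 subfield        t df           p mean_accuracy
      CA1       NA  3          NA     1.0000000
      CA3 7.210526  3 0.005499044     0.9391026
       DG 8.000000  3 0.004076578     0.9444444
      SUB 4.933720  3 0.015965255     0.8132173
ANOVA across subfields: F(3, 9) = 2.531, p = 0.1227

-- morph50: t-tests vs chance (50%) --
 subfield        t df          p mean_accuracy
      CA1 2.119405  3 0.12425253     0.7095238
      CA3 2.548660  3 0.08404111     0.7438375
       DG 3.511094  3 0.03916703     0.6507003
      SUB 3.185968  3 0.04986504     0.5918768
ANOVA across subfields: F(3, 9) = 1.469, p = 0.2872

-- cross: t-tests vs chance (50%) --
 subfield          t df         p mean_accuracy
      CA1  0.8412759  3 0.4619620     0.5983894
      CA3  1.0903228  3 0.3553137     0.6095588
       DG -0.8823306  3 0.4425715     0.4758929
      SUB  0.4667420  3 0.6724901     0.5555497
ANOVA across subfields: F(3, 9) = 0.525, p = 0.6757
```

Reading the output: decoding of the two original scenes (`scenes`) is far
above the 50% chance level in every subfield (a t of `NA` marks the
degenerate all-subjects-at-ceiling case, which is reported rather than
given a fabricated p-value). Decoding the participant's *decision* on
identical 50% morph stimuli (`morph50`) also succeeds, because the
generator embeds decision-state patterns. But a classifier trained on the
original scenes does not transfer to those choice-labelled morph trials
(`cross` hovers at chance): with the default
`morph_pattern_share = 0` the decision-state patterns share nothing with
the scene patterns, so nothing transfers — the dissociation that rules out
a motor-response account of scene decoding. `plot(run)` draws the
per-subfield accuracy bars with standard errors and the chance line.

## Notes

* Identical configurations (including the seed) reproduce cohorts
  bit-for-bit; seed arguments never disturb the caller's RNG state.
* Masks and BOLD read/write NIfTI-1 (`RNifti`); event tables are
  tab-delimited text; decoding and group results export as JSON/CSV from
  `run_cohort(..., out_dir = )`.
* See the methods vignette (`vignettes/hippmvpa-methods.Rmd`) for the
  forward model, the feature-selection rule, null-calibration caveats of
  leave-one-out decoding, and all design decisions.
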
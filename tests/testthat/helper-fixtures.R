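# shared fixtures, all generated in code

# single connected test ROI (L hemisphere of a one-subfield layout)
test_mask <- function(dims = c(12, 12, 8), n_vox = 60, seed = 3) {
  make_subfield_masks(dims, c(ROI = n_vox), seed = seed, jitter = 0)$ROI_L
}

# beta series of pure-noise features on a mask
noise_betas <- function(mask, n_trials, seed = 1) {
  set.seed(seed)
  coords <- which(mask$data != 0, arr.ind = TRUE) - 1L
  beta_series(matrix(rnorm(n_trials * nrow(coords)), n_trials), coords)
}

# i.i.d. fair-coin labels with at least `min_per_class` per class
coin_labels <- function(n, seed, min_per_class = 2L) {
  set.seed(seed)
  repeat {
    lab <- ifelse(runif(n) < 0.5, "A", "B")
    if (min(table(factor(lab, c("A", "B")))) >= min_per_class) return(lab)
  }
}

# one fully simulated subject-ROI decoding run (smooth + GLM + nested LOO)
run_subject_roi <- function(seed, amplitude, null_labels = FALSE,
                            n_repeats = 15L, roi_vox = 70L,
                            grid = c(14L, 14L, 10L)) {
  cfg <- sim_config(n_subjects = 1, grid_dims = grid,
                    n_repeats_per_stimulus = n_repeats,
                    pattern_amplitude = amplitude, noise_sd = 1,
                    target_counts = c(ROI = roi_vox),
                    signal_subfields = "ROI", seed = seed)
  sim <- simulate_subject(cfg, 1)
  b <- smooth_gaussian(sim$bold, 3)
  X <- build_design(sim$events, dim(b$data)[4], cfg$tr_s)
  bs <- fit_beta_series(b, X, sim$masks$ROI_L)
  ev <- filter_trials(sim$events, "original_scenes")
  lab <- if (null_labels) coin_labels(nrow(ev), seed + 1L) else ev$choice
  loo_decode(subset_trials(bs, attr(ev, "trial_index")), lab,
             searchlight_spec(sim$masks$ROI_L, 3))
}
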
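#' Simulation configuration for a synthetic scene-decision cohort
#'
#' Defines the study conditions the generator emulates: 16 subjects viewing
#' 9 stimulus categories (two original scenes plus seven morphs) 40 times
#' each in 7.5-s trial blocks (2.5 s stimulus / 3 s confidence / 2 s rest),
#' scanned at TR 3.5 s with 1.5 mm isotropic voxels, with four bilateral
#' subfield ROIs (CA1, CA3, DG, SUB) at realistic voxel counts.
#'
#' @param n_subjects Number of subjects (default 16).
#' @param grid_dims Voxel grid (default `c(40, 40, 24)`, large enough for
#'   the eight default masks).
#' @param voxel_size_mm Isotropic voxel size (default 1.5).
#' @param tr_s Repetition time in seconds (default 3.5).
#' @param n_repeats_per_stimulus Presentations per category (default 40).
#' @param pattern_amplitude Amplitude of the embedded category patterns in
#'   units of the noise SD (>= 0; default 0.3, a moderate multivoxel effect).
#' @param noise_sd SD of the i.i.d. Gaussian scanner noise (> 0; default 1).
#' @param morph_pattern_share Correlation, by construction, between the
#'   50%-morph decision-state patterns and the corresponding 100% scene
#'   patterns, in \[0, 1\]. Default 0: decision states are represented by
#'   patterns unrelated to the perceptual scene patterns, which is the
#'   configuration that reproduces the observed dissociation (high
#'   within-morph decoding, chance cross-decoding).
#' @param psychometric_slope Slope of the logistic choice function
#'   (default 10).
#' @param no_decision_rate Fraction of trials without a decision.
#' @param drift_amplitude Peak-to-peak linear drift added to every voxel
#'   (default 0, i.e. off).
#' @param baseline Baseline signal level (default 100).
#' @param target_counts Per-hemisphere subfield voxel-count targets.
#' @param signal_subfields Subfields carrying embedded patterns (default
#'   all).
#' @param stimulus_dur_s,confidence_dur_s,rest_dur_s Trial phase durations.
#' @param seed Integer master seed; identical configs (including seed) give
#'   bit-identical cohorts.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 16L,
                       grid_dims = c(40L, 40L, 24L),
                       voxel_size_mm = 1.5,
                       tr_s = 3.5,
                       n_repeats_per_stimulus = 40L,
                       pattern_amplitude = 0.3,
                       noise_sd = 1,
                       morph_pattern_share = 0,
                       psychometric_slope = 10,
                       no_decision_rate = 0.02,
                       drift_amplitude = 0,
                       baseline = 100,
                       target_counts = default_subfield_counts(),
                       signal_subfields = names(target_counts),
                       stimulus_dur_s = 2.5,
                       confidence_dur_s = 3,
                       rest_dur_s = 2,
                       seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects), grid_dims = as.integer(grid_dims),
              voxel_size_mm = voxel_size_mm, tr_s = tr_s,
              n_repeats_per_stimulus = as.integer(n_repeats_per_stimulus),
              pattern_amplitude = pattern_amplitude, noise_sd = noise_sd,
              morph_pattern_share = morph_pattern_share,
              psychometric_slope = psychometric_slope,
              no_decision_rate = no_decision_rate,
              drift_amplitude = drift_amplitude, baseline = baseline,
              target_counts = target_counts, signal_subfields = signal_subfields,
              stimulus_dur_s = stimulus_dur_s, confidence_dur_s = confidence_dur_s,
              rest_dur_s = rest_dur_s, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 1L, length(cfg$grid_dims) == 3L,
            all(cfg$grid_dims >= 1L), cfg$voxel_size_mm > 0, cfg$tr_s > 0,
            cfg$n_repeats_per_stimulus >= 1L, cfg$pattern_amplitude >= 0,
            cfg$noise_sd > 0,
            cfg$morph_pattern_share >= 0, cfg$morph_pattern_share <= 1,
            cfg$psychometric_slope > 0,
            cfg$no_decision_rate >= 0, cfg$no_decision_rate < 1)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d subjects, grid %s, TR %.2g s, %d trials (%d x 9), amp %.3g, noise %.3g, share %.2g, seed %d\n",
              x$n_subjects, paste(x$grid_dims, collapse = "x"), x$tr_s,
              9L * x$n_repeats_per_stimulus, x$n_repeats_per_stimulus,
              x$pattern_amplitude, x$noise_sd, x$morph_pattern_share, x$seed))
  invisible(x)
}

#' Ground-truth pattern structure for one synthetic subject
#'
#' For every ROI: a scene-A and a scene-B multivoxel pattern (i.i.d.
#' standard normal over the ROI voxels) and a pair of 50%-morph
#' decision-state patterns constructed as
#' `share * scene_pattern + sqrt(1 - share^2) * independent_pattern`, so
#' their correlation with the matching scene pattern equals `share` by
#' construction (exactly 1 when `share = 1`, independent when 0).
#' Also records the per-trial latent decision state: for unambiguous trials
#' the scene side of the morph fraction; for 50% morphs the simulated
#' choice (or a fair coin if no decision was made).
#'
#' @param masks List of [roi_mask()]s.
#' @param events Event table with behavior filled in.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Object of class `ground_truth`: per-ROI pattern list, per-trial
#'   `latent_state` ("A"/"B"), per-ROI `signal` flag.
#' @export
make_ground_truth <- function(masks, events, config, seed = NULL) {
  check_events(events)
  w <- config$morph_pattern_share
  with_seed(seed, {
    patterns <- lapply(masks, function(m) {
      nv <- roi_voxel_count(m)
      pa <- rnorm(nv); pb <- rnorm(nv)
      p50a <- w * pa + sqrt(1 - w^2) * rnorm(nv)
      p50b <- w * pb + sqrt(1 - w^2) * rnorm(nv)
      list(A = pa, B = pb, M50A = p50a, M50B = p50b)
    })
    f <- events$morph_fraction
    state <- ifelse(f > 0.5, "A", "B")
    amb <- f == 0.5
    state[amb] <- ifelse(events$choice[amb] %in% c("A", "B"),
                         events$choice[amb],
                         sample(c("A", "B"), sum(amb), replace = TRUE))
    signal <- vapply(masks, function(m) m$subfield %in% config$signal_subfields,
                     logical(1))
    structure(list(patterns = patterns, latent_state = state, signal = signal),
              class = "ground_truth")
  })
}

# pattern key of each trial given its morph fraction and latent state
trial_pattern_key <- function(fraction, state) {
  ifelse(fraction == 1, "A",
         ifelse(fraction == 0, "B",
                ifelse(fraction == 0.5, paste0("M50", state),
                       paste0("F", fraction))))
}

#' Simulate a BOLD run with embedded multivoxel patterns
#'
#' Forward model: every trial adds its category's spatial pattern (for 50%
#' morphs, its latent decision state's pattern) scaled by
#' `pattern_amplitude` to the ROI voxels, as a boxcar of the stimulus
#' duration convolved with the canonical HRF and sampled at the TR.
#' Intermediate morphs carry the graded mixture
#' `f * pattern_A + (1 - f) * pattern_B`. On top of the signal: a constant
#' baseline, optional linear drift, and i.i.d. Gaussian noise of SD
#' `noise_sd` at every grid voxel.
#'
#' @param events Event table (behavior filled in).
#' @param masks List of [roi_mask()]s (pairwise disjoint).
#' @param truth A [make_ground_truth()] object matching `masks`.
#' @param config A [sim_config()].
#' @param seed Integer seed for the noise.
#' @param n_scans Number of volumes; default just covers the run plus the
#'   HRF tail.
#' @return A [bold4d()].
#' @export
simulate_bold <- function(events, masks, truth, config, seed = NULL,
                          n_scans = NULL) {
  check_events(events)
  hrf <- hrf_params()
  block <- config$stimulus_dur_s + config$confidence_dur_s + config$rest_dur_s
  if (is.null(n_scans))
    n_scans <- ceiling((max(events$onset_s) + block + hrf$length_s) / config$tr_s)
  X <- build_design(events, n_scans, config$tr_s,
                    stimulus_dur_s = config$stimulus_dur_s, hrf = hrf)
  Xt <- X[, attr(X, "task_cols"), drop = FALSE]
  keys <- trial_pattern_key(events$morph_fraction, truth$latent_state)
  ukeys <- unique(keys)
  Z <- matrix(sapply(ukeys, function(k) as.numeric(keys == k)),
              ncol = length(ukeys))
  R <- Xt %*% Z  # n_scans x n_conditions
  dims <- config$grid_dims
  with_seed(seed, {
    dat <- array(rnorm(prod(dims) * n_scans, mean = config$baseline,
                       sd = config$noise_sd),
                 dim = c(dims, n_scans))
    if (config$drift_amplitude != 0) {
      drift <- config$drift_amplitude * seq(-0.5, 0.5, length.out = n_scans)
      dat <- dat + rep(drift, each = prod(dims))
    }
    if (config$pattern_amplitude > 0) {
      flat <- matrix(dat, nrow = prod(dims), ncol = n_scans)
      for (mi in seq_along(masks)) {
        if (!truth$signal[mi]) next
        m <- masks[[mi]]
        if (!identical(dim(m$data), as.integer(dims)))
          stop("mask grid does not match config grid")
        co <- mask_coords(m)
        lin <- co[, 1] + dims[1] * (co[, 2] - 1L) + dims[1] * dims[2] * (co[, 3] - 1L)
        pat <- truth$patterns[[mi]]
        P <- matrix(sapply(ukeys, function(k) {
          if (k %in% names(pat)) pat[[k]]
          else {
            f <- as.numeric(sub("^F", "", k))
            f * pat$A + (1 - f) * pat$B
          }
        }), ncol = length(ukeys))
        # voxels x scans increment
        flat[lin, ] <- flat[lin, ] +
          config$pattern_amplitude * (P %*% t(R))
      }
      dat <- array(flat, dim = c(dims, n_scans))
    }
    bold4d(dat, tr_s = config$tr_s, voxel_size_mm = config$voxel_size_mm)
  })
}

#' Simulate one complete synthetic subject
#'
#' Generates subfield masks, the event schedule, psychometric behavior,
#' ground-truth patterns and the BOLD run for one subject, all
#' deterministically derived from the config seed and the subject index.
#'
#' @param config A [sim_config()].
#' @param subject Subject index (1-based).
#' @return List of class `subject_sim` with elements `masks`, `events`,
#'   `truth`, `bold`, `subject`.
#' @export
simulate_subject <- function(config, subject = 1L) {
  validate_sim_config(config)
  masks <- make_subfield_masks(config$grid_dims, config$target_counts,
                               seed = child_seed(config$seed, subject, 1L),
                               voxel_size_mm = config$voxel_size_mm)
  events <- make_event_schedule(config$n_repeats_per_stimulus,
                                config$stimulus_dur_s, config$confidence_dur_s,
                                config$rest_dur_s,
                                seed = child_seed(config$seed, subject, 2L))
  events <- simulate_behavior(events, slope = config$psychometric_slope,
                              no_decision_rate = config$no_decision_rate,
                              seed = child_seed(config$seed, subject, 3L))
  truth <- make_ground_truth(masks, events, config,
                             seed = child_seed(config$seed, subject, 4L))
  bold <- simulate_bold(events, masks, truth, config,
                        seed = child_seed(config$seed, subject, 5L))
  structure(list(masks = masks, events = events, truth = truth, bold = bold,
                 subject = subject),
            class = "subject_sim")
}
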
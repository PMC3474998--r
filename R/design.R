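#' Build a per-trial GLM design matrix
#'
#' Every trial is modelled as its own regressor: a boxcar of the stimulus
#' duration at the trial onset, convolved with the canonical HRF. The
#' convolution is carried out on a grid oversampled `oversample` times finer
#' than the TR and then sampled at scan acquisition times, so onsets need not
#' fall on TR multiples. Column order is fixed and documented: trial
#' regressors in event order (`trial_001`, ...), then any nuisance columns
#' (`nuisance_1`, ...), then a constant `intercept`.
#'
#' @param events Event table (only `onset_s` and the stimulus duration
#'   attribute/argument are used).
#' @param n_scans Number of acquired volumes.
#' @param tr_s Repetition time in seconds.
#' @param nuisance Optional numeric matrix with `n_scans` rows of regressors
#'   of no interest (e.g. movement parameters).
#' @param stimulus_dur_s Boxcar duration in seconds; defaults to the event
#'   table's `stimulus_dur_s` attribute or 2.5.
#' @param hrf [hrf_params()] for the convolution kernel.
#' @param oversample Temporal oversampling factor (default 16).
#' @return Numeric matrix `n_scans x (n_trials + n_nuisance + 1)` with an
#'   attribute `"task_cols"` marking the trial columns.
#' @export
build_design <- function(events, n_scans, tr_s, nuisance = NULL,
                         stimulus_dur_s = NULL, hrf = hrf_params(),
                         oversample = 16L) {
  stopifnot(n_scans >= 1L, tr_s > 0, oversample >= 1L)
  onsets <- events$onset_s
  if (is.null(stimulus_dur_s))
    stimulus_dur_s <- attr(events, "stimulus_dur_s") %||% 2.5
  if (anyDuplicated(onsets)) stop("overlapping identical onsets in event table")
  if (any(onsets < 0)) stop("negative onsets")
  total_s <- n_scans * tr_s
  if (any(onsets + stimulus_dur_s > total_s))
    stop(sprintf("events extend past the scan (duration %.1f s)", total_s))
  n_trials <- length(onsets)

  dt <- tr_s / oversample
  n_fine <- ceiling((total_s + hrf$length_s) / dt) + 1L
  t_fine <- (seq_len(n_fine) - 1) * dt
  kern <- hrf_eval(t_fine[t_fine <= hrf$length_s], hrf)
  kern <- kern / max(kern)
  scan_idx <- round((seq_len(n_scans) - 1) * tr_s / dt) + 1L

  # discrete convolution of a boxcar [a, b] with the kernel, evaluated via
  # the kernel's cumulative sum: conv[n] = S[n - a + 1] - S[n - b], with S
  # zero-padded; equivalent to full convolve-then-decimate but O(n) per trial
  S <- cumsum(kern)
  S_at <- function(i) {
    out <- numeric(length(i))
    out[i >= length(S)] <- S[length(S)]
    mid <- i >= 1L & i < length(S)
    out[mid] <- S[i[mid]]
    out
  }
  X <- matrix(0, nrow = n_scans, ncol = n_trials)
  for (i in seq_len(n_trials)) {
    a <- floor(onsets[i] / dt) + 1L
    b <- min(n_fine, ceiling((onsets[i] + stimulus_dur_s) / dt))
    X[, i] <- S_at(scan_idx - a + 1L) - S_at(scan_idx - b)
  }
  colnames(X) <- sprintf("trial_%03d", seq_len(n_trials))

  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_scans)
      stop("nuisance matrix must have n_scans rows")
    colnames(nuisance) <- sprintf("nuisance_%d", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
  }
  X <- cbind(X, intercept = 1)
  attr(X, "task_cols") <- seq_len(n_trials)
  X
}

`%||%` <- function(a, b) if (is.null(a)) b else a
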
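test_that("canonical HRF starts at zero, has unit peak near the peak delay", {
  h <- canonical_hrf(3.5)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  params <- hrf_params()
  t_at_max <- (which.max(h) - 1) * 3.5
  expect_lte(abs(t_at_max - params$peak_delay_s), 3.5)
  expect_error(canonical_hrf(0), "positive")
})

test_that("design matrix has one HRF-convolved column per trial plus intercept", {
  ev <- make_event_schedule(n_repeats = 40, seed = 1)
  n_scans <- ceiling((max(ev$onset_s) + 7.5 + 32) / 3.5)
  X <- build_design(ev, n_scans, 3.5)
  expect_equal(ncol(X), 361L)  # 360 task + intercept
  expect_true(all(X[, "intercept"] == 1))

  # single event at onset 0: column proportional to the convolved kernel shape
  one <- ev[1, ]; one$onset_s <- 0
  X1 <- build_design(one, 20, 3.5)
  expect_equal(unname(X1[1, 1]), 0)     # no response before the HRF rises
  expect_gt(max(X1[, 1]), 0.9)          # peak close to the unit-peak kernel
  expect_equal(which.max(X1[, 1]), 3L)  # peak lag ~6-7 s at TR 3.5

  nuis <- matrix(rnorm(20 * 2), 20)
  Xn <- build_design(one, 20, 3.5, nuisance = nuis)
  expect_equal(ncol(Xn), 4L)  # task + 2 nuisance + intercept

  dup <- rbind(one, one)
  expect_error(build_design(dup, 20, 3.5), "onsets|increasing|identical")
  late <- one; late$onset_s <- 1000
  expect_error(build_design(late, 20, 3.5), "past the scan")
})

test_that("sub-TR onsets reproduce the oversample-then-decimate convolution oracle", {
  ev <- make_event_schedule(n_repeats = 1, seed = 4)
  ev$onset_s <- ev$onset_s + 1.3   # not a TR multiple
  n_scans <- 40; tr <- 3.5
  X <- build_design(ev, n_scans, tr)
  # independent oracle: explicit boxcar on the 16x fine grid, full discrete
  # convolution (FFT), decimation at scan times
  hp <- hrf_params(); dt <- tr / 16
  n_fine <- ceiling((n_scans * tr + hp$length_s) / dt) + 1
  tf <- (seq_len(n_fine) - 1) * dt
  kern <- hippmvpa:::hrf_eval(tf[tf <= hp$length_s], hp)
  kern <- kern / max(kern)
  for (i in c(1L, 5L)) {
    box <- numeric(n_fine)
    box[(floor(ev$onset_s[i] / dt) + 1):ceiling((ev$onset_s[i] + 2.5) / dt)] <- 1
    conv <- stats::convolve(box, rev(kern), type = "open")[seq_len(n_fine)]
    oracle <- conv[round((seq_len(n_scans) - 1) * tr / dt) + 1]
    expect_equal(X[, i], oracle, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("Gaussian smoothing is identity at fwhm 0, flat on constants, mass-preserving", {
  set.seed(2)
  b <- bold4d(array(rnorm(10 * 10 * 6 * 3, 100), dim = c(10, 10, 6, 3)))
  expect_identical(smooth_gaussian(b, 0), b)
  s <- smooth_gaussian(b, 3)
  for (t in 1:3)
    expect_equal(sum(s$data[, , , t]), sum(b$data[, , , t]), tolerance = 1e-10)
  const <- bold4d(array(7, dim = c(8, 8, 6, 2)))
  expect_equal(smooth_gaussian(const, 3)$data, const$data, tolerance = 1e-12)
  expect_error(smooth_gaussian(b, -1), "non-negative")
})

test_that("impulse response equals the hand-computed discrete Gaussian kernel", {
  vol <- array(0, dim = c(11, 11, 11, 1))
  vol[6, 6, 6, 1] <- 1
  s <- smooth_gaussian(bold4d(vol), 3)
  # hand-built kernel: sigma = 3/(2 sqrt(2 ln 2))/1.5 voxels, truncated 3 sigma
  sigma <- 3 / (2 * sqrt(2 * log(2))) / 1.5
  r <- ceiling(3 * sigma)
  w <- exp(-((-r):r)^2 / (2 * sigma^2)); w <- w / sum(w)
  expect_equal(s$data[6, 6, 6, 1], w[r + 1]^3, tolerance = 1e-12)
  expect_equal(s$data[6, 7, 6, 1], w[r + 1]^2 * w[r + 2], tolerance = 1e-12)
})

test_that("beta-series OLS recovers exact coefficients and orthogonal residuals", {
  ev <- make_event_schedule(n_repeats = 1, seed = 9)
  n_scans <- 40
  X <- build_design(ev, n_scans, 3.5)
  # noiseless y = 3.7 * single task regressor (trial 3)
  y <- 3.7 * X[, 3]
  vol <- array(0, dim = c(2, 2, 2, n_scans))
  for (t in seq_len(n_scans)) vol[, , , t] <- y[t]
  bs <- fit_beta_series(bold4d(vol), X)
  expect_equal(unname(bs$betas[3, ]), rep(3.7, 8), tolerance = 1e-8)

  # zero BOLD -> zero betas
  bs0 <- fit_beta_series(bold4d(array(0, dim = c(2, 2, 2, n_scans))), X)
  expect_true(all(bs0$betas == 0))

  # constant shift absorbed by the intercept
  vol2 <- vol + 100
  bs2 <- fit_beta_series(bold4d(vol2), X)
  expect_equal(bs2$betas, bs$betas, tolerance = 1e-8)

  # residuals orthogonal to every design column at machine precision
  set.seed(5)
  voln <- vol + array(rnorm(length(vol)), dim = dim(vol))
  bsn <- fit_beta_series(bold4d(voln), X)
  resid <- attr(bsn, "residuals")
  ortho <- crossprod(X, resid)
  expect_lt(max(abs(ortho)), 1e-8 * max(abs(voln)))

  # rank deficiency is reported with the collinear columns named
  Xbad <- cbind(X, dup = X[, 2])
  attr(Xbad, "task_cols") <- attr(X, "task_cols")
  expect_error(fit_beta_series(bold4d(voln), Xbad), "rank deficient")
})

test_that("forward model then GLM recovers the embedded patterns (noiseless limit)", {
  cfg <- sim_config(n_subjects = 1, grid_dims = c(10, 10, 8),
                    n_repeats_per_stimulus = 3, pattern_amplitude = 1,
                    noise_sd = 1e-6, target_counts = c(ROI = 40),
                    signal_subfields = "ROI", seed = 21)
  sim <- simulate_subject(cfg, 1)
  X <- build_design(sim$events, dim(sim$bold$data)[4], cfg$tr_s)
  bs <- fit_beta_series(sim$bold, X, sim$masks$ROI_L)   # no smoothing
  keys <- hippmvpa:::trial_pattern_key(sim$events$morph_fraction,
                                       sim$truth$latent_state)
  pat <- sim$truth$patterns$ROI_L
  for (t in seq_len(nrow(bs$betas))) {
    k <- keys[t]
    truth <- if (k %in% names(pat)) pat[[k]] else {
      f <- as.numeric(sub("^F", "", k)); f * pat$A + (1 - f) * pat$B
    }
    cs <- sum(bs$betas[t, ] * truth) /
      sqrt(sum(bs$betas[t, ]^2) * sum(truth^2))
    expect_gt(cs, 0.99)
  }
})
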
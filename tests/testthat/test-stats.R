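test_that("one-sample t-test against chance matches hand arithmetic", {
  # mean 0.7, sd 0.1 -> t = 0.2 / (0.1/sqrt(3))
  r <- ttest_vs_chance(c(0.6, 0.7, 0.8), 0.5)
  expect_equal(r$t, 0.2 / (0.1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(r$df, 2L)
  expect_equal(r$p, 2 * pt(-abs(r$t), 2), tolerance = 1e-12)

  r0 <- ttest_vs_chance(c(0.5, 0.5, 0.5), 0.5)
  expect_equal(r0$t, 0); expect_equal(r0$p, 1)

  # location invariance: shifting data and chance together leaves t unchanged
  r_shift <- ttest_vs_chance(c(0.6, 0.7, 0.8) + 0.2, 0.7)
  expect_equal(r_shift$t, r$t, tolerance = 1e-10)

  expect_error(ttest_vs_chance(c(0.7, 0.7)), "zero variance")
  expect_error(ttest_vs_chance(0.6), "at least 2")
})

test_that("repeated-measures ANOVA equals the sums-of-squares oracle and aov", {
  # brute-force SS decomposition as independent oracle
  brute_rm <- function(tab) {
    n <- nrow(tab); r <- ncol(tab); g <- mean(tab)
    ssr <- n * sum((colMeans(tab) - g)^2)
    sss <- r * sum((rowMeans(tab) - g)^2)
    sse <- sum((tab - g)^2) - ssr - sss
    (ssr / (r - 1)) / (sse / ((r - 1) * (n - 1)))
  }
  set.seed(14)
  tab <- matrix(runif(16 * 4, 0.4, 0.9), 16, 4,
                dimnames = list(NULL, c("CA1", "CA3", "DG", "SUB")))
  r <- rm_anova(tab)
  expect_equal(r$F, brute_rm(tab), tolerance = 1e-10)
  expect_equal(r$df_between, 3L)
  expect_equal(r$df_error, 45L)

  # stats::aov with an Error(subject) stratum as a second, independent route
  long <- data.frame(acc = as.vector(tab),
                     region = factor(rep(colnames(tab), each = 16)),
                     subject = factor(rep(1:16, times = 4)))
  fit <- summary(stats::aov(acc ~ region + Error(subject / region), data = long))
  f_aov <- fit[["Error: subject:region"]][[1]]["region", "F value"]
  expect_equal(r$F, unname(f_aov), tolerance = 1e-8)

  # per-subject constant offsets are absorbed by the subject effect
  tab2 <- tab + matrix(rnorm(16), 16, 4)
  expect_equal(rm_anova(tab2)$F, brute_rm(tab2), tolerance = 1e-10)
  r2 <- rm_anova(sweep(tab, 1, seq_len(16) / 10, `+`))
  expect_equal(r2$F, r$F, tolerance = 1e-8)

  # no between-region variance -> F = 0
  same <- matrix(rep(runif(6), 3), 6, 3)
  expect_equal(rm_anova(same)$F, 0)

  # the stated degenerate toy: region B = A + 0.2 exactly -> zero error SS
  toy <- matrix(c(0.5, 0.6, 0.4, 0.7, 0.8, 0.6), 3, 2)
  expect_true(is.infinite(rm_anova(toy)$F))

  expect_error(rm_anova(matrix(c(1, NA, 2, 3), 2, 2)), "complete|missing")
})

test_that("paired t-tests reduce to one-sample tests on the differences", {
  set.seed(20)
  tab <- matrix(runif(8 * 2, 0.4, 0.9), 8, 2, dimnames = list(NULL, c("X", "Y")))
  pt_ <- paired_ttests(tab)
  d <- tab[, 1] - tab[, 2]
  ref <- ttest_vs_chance(d, 0)
  expect_equal(pt_$t, ref$t, tolerance = 1e-10)
  expect_equal(pt_$df, ref$df)
  expect_equal(pt_$p, ref$p, tolerance = 1e-12)

  # all six pairs by default for four regions
  tab4 <- matrix(runif(5 * 4), 5, 4, dimnames = list(NULL, c("CA1", "CA3", "DG", "SUB")))
  expect_equal(nrow(paired_ttests(tab4)), 6L)

  # identical columns: t = 0; exact constant offset: degenerate infinite t
  same <- cbind(A = tab[, 1], B = tab[, 1])
  expect_equal(paired_ttests(same)$t, 0)
  off <- cbind(A = tab[, 1], B = tab[, 1] + 0.1)
  expect_warning(res <- paired_ttests(off), "zero-variance")
  expect_true(is.infinite(res$t))
})

test_that("two-level repeated-measures F equals the squared paired t", {
  set.seed(25)
  for (i in 1:5) {
    L <- runif(10, 0.4, 0.9); R <- L + rnorm(10, 0, 0.05)
    f <- rm_anova(cbind(L, R))$F
    t2 <- paired_ttests(cbind(L = L, R = R))$t^2
    expect_equal(f, t2, tolerance = 1e-8)
  }
})

test_that("hemisphere check reports per-region tests and collapses by averaging", {
  set.seed(30)
  subs <- 1:6
  long <- expand.grid(subject = subs, subfield = c("CA1", "CA3"),
                      hemisphere = c("L", "R"), stringsAsFactors = FALSE)
  long$accuracy <- runif(nrow(long), 0.4, 0.9)
  out <- hemisphere_check_and_collapse(long)
  expect_equal(dim(out$collapsed), c(6L, 2L))
  # collapsed cell is the arithmetic mean of the two hemispheres
  l1 <- long$accuracy[long$subject == 1 & long$subfield == "CA1"]
  expect_equal(out$collapsed[1, "CA1"], mean(l1))
  expect_equal(nrow(out$hemisphere_tests), 2L)
  # F equals squared paired t on the same data
  wide <- cbind(
    L = long$accuracy[long$subfield == "CA1" & long$hemisphere == "L"],
    R = long$accuracy[long$subfield == "CA1" & long$hemisphere == "R"])
  expect_equal(out$hemisphere_tests$F[out$hemisphere_tests$subfield == "CA1"],
               paired_ttests(wide)$t^2, tolerance = 1e-8)
  # identical hemispheres: F = 0 and collapse returns the common values
  long$accuracy[long$hemisphere == "R"] <-
    long$accuracy[long$hemisphere == "L"]
  out2 <- hemisphere_check_and_collapse(long)
  expect_true(all(out2$hemisphere_tests$F == 0))
  expect_equal(unname(out2$collapsed[, "CA1"]),
               long$accuracy[long$subfield == "CA1" & long$hemisphere == "L"])
})

test_that("simple collapsed mean is the midpoint", {
  long <- data.frame(subject = c(1, 1), subfield = "CA1",
                     hemisphere = c("L", "R"), accuracy = c(0.6, 0.8))
  long2 <- rbind(long, transform(long, subject = 2))
  out <- hemisphere_check_and_collapse(long2)
  expect_equal(unname(out$collapsed[1, "CA1"]), 0.7)
})
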
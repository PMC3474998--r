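#' One-sample t-test of accuracies against chance
#'
#' Two-sided one-sample t-test of per-subject classifier accuracies against
#' the chance level (50% for two balanced classes), df = n - 1.
#'
#' @param accuracies Numeric vector of per-subject accuracies.
#' @param chance Chance level (default 0.5).
#' @return List with elements `t`, `df`, `p`.
#' @export
ttest_vs_chance <- function(accuracies, chance = 0.5) {
  stopifnot(is.numeric(accuracies))
  n <- length(accuracies)
  if (n < 2L) stop("at least 2 accuracy values required")
  if (sd(accuracies) == 0) {
    if (all(accuracies == chance))
      return(list(t = 0, df = n - 1L, p = 1))
    stop("degenerate case: zero variance in accuracies (all values identical, not at chance)")
  }
  ht <- t.test(accuracies, mu = chance)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' One-way repeated-measures ANOVA across regions
#'
#' Within-subject one-way ANOVA on a complete subjects x regions accuracy
#' table: `F = MS_regions / MS_(subject x region)` with degrees of freedom
#' `(r - 1, (r - 1)(n - 1))`. No sphericity correction is applied by
#' default; Greenhouse-Geisser correction of the p-value is available.
#'
#' @param table Numeric matrix, subjects x regions (complete, no `NA`).
#' @param gg Logical; apply the Greenhouse-Geisser epsilon to the p-value.
#' @return List with `F`, `df_between`, `df_error`, `p` (and `epsilon` when
#'   `gg = TRUE`).
#' @export
rm_anova <- function(table, gg = FALSE) {
  table <- as.matrix(table)
  if (anyNA(table)) stop("repeated-measures ANOVA requires a complete table (missing cells)")
  n <- nrow(table); r <- ncol(table)
  if (n < 2L || r < 2L) stop("need >= 2 subjects and >= 2 regions")
  grand <- mean(table)
  region_means <- colMeans(table)
  subject_means <- rowMeans(table)
  ss_region <- n * sum((region_means - grand)^2)
  ss_subject <- r * sum((subject_means - grand)^2)
  ss_total <- sum((table - grand)^2)
  ss_error <- ss_total - ss_region - ss_subject
  df_b <- r - 1L
  df_e <- (r - 1L) * (n - 1L)
  ms_region <- ss_region / df_b
  ms_error <- ss_error / df_e
  # error SS that is pure floating-point dust counts as zero (degenerate)
  f <- if (ms_error <= 1e-12 * max(ms_region, .Machine$double.xmin)) {
    if (ms_region == 0) 0 else Inf
  } else ms_region / ms_error
  out <- list(F = f, df_between = df_b, df_error = df_e,
              p = pf(f, df_b, df_e, lower.tail = FALSE))
  if (gg) {
    eps <- gg_epsilon(table)
    out$epsilon <- eps
    out$p <- pf(f, df_b * eps, df_e * eps, lower.tail = FALSE)
  }
  out
}

# Greenhouse-Geisser epsilon from the double-centred covariance matrix
gg_epsilon <- function(table) {
  S <- stats::cov(table)
  r <- ncol(S)
  Sc <- S - outer(rowMeans(S), rep(1, r)) - outer(rep(1, r), colMeans(S)) + mean(S)
  sum(diag(Sc))^2 / ((r - 1) * sum(Sc^2))
}

#' Paired t-tests between regions
#'
#' Two-sided paired t-tests for each requested region pair (all pairs by
#' default), df = n - 1 each. Zero-variance differences are reported as a
#' degenerate case: `t` is `Inf` (or 0 when the columns are identical) and
#' `p` is `NA` with a warning, rather than a fabricated p-value. No
#' multiple-comparison correction is applied, mirroring conventional
#' reporting of a small set of follow-up tests.
#'
#' @param table Numeric matrix, subjects x regions, with column names.
#' @param pairs Optional list of length-2 character vectors; default all
#'   unordered pairs of columns.
#' @return data.frame with columns `region_a`, `region_b`, `t`, `df`, `p`.
#' @export
paired_ttests <- function(table, pairs = NULL) {
  table <- as.matrix(table)
  if (is.null(colnames(table)))
    colnames(table) <- paste0("R", seq_len(ncol(table)))
  if (is.null(pairs)) {
    cn <- colnames(table)
    pairs <- utils::combn(cn, 2, simplify = FALSE)
  }
  res <- lapply(pairs, function(p) {
    d <- table[, p[1]] - table[, p[2]]
    n <- length(d)
    if (sd(d) == 0) {
      if (all(d == 0)) {
        tt <- 0; pv <- 1
      } else {
        warning(sprintf("zero-variance differences for %s vs %s: constant offset, t is infinite",
                        p[1], p[2]))
        tt <- sign(mean(d)) * Inf; pv <- NA_real_
      }
    } else {
      ht <- t.test(table[, p[1]], table[, p[2]], paired = TRUE)
      tt <- unname(ht$statistic); pv <- ht$p.value
    }
    data.frame(region_a = p[1], region_b = p[2], t = tt, df = n - 1L, p = pv,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Hemisphere comparison and collapse
#'
#' For each region, a two-level (left vs right) repeated-measures ANOVA on
#' the per-subject accuracies — numerically identical to the squared paired
#' t-test — then, regardless of the outcome, the per-subject mean of the two
#' hemispheres, reported alongside the test so the collapse is auditable.
#'
#' @param long data.frame with columns `subject`, `subfield`, `hemisphere`
#'   (`"L"`/`"R"`), `accuracy`; one row per cell.
#' @return List with `hemisphere_tests` (data.frame: subfield, F, df1, df2,
#'   p) and `collapsed` (subjects x subfields matrix of L/R means).
#' @export
hemisphere_check_and_collapse <- function(long) {
  need <- c("subject", "subfield", "hemisphere", "accuracy")
  if (!all(need %in% names(long)))
    stop("expected columns: ", paste(need, collapse = ", "))
  subs <- sort(unique(long$subject))
  regions <- unique(long$subfield)
  tests <- lapply(regions, function(rg) {
    sub <- long[long$subfield == rg, ]
    wide <- cbind(
      L = sub$accuracy[sub$hemisphere == "L"][match(subs, sub$subject[sub$hemisphere == "L"])],
      R = sub$accuracy[sub$hemisphere == "R"][match(subs, sub$subject[sub$hemisphere == "R"])]
    )
    if (anyNA(wide)) stop(sprintf("missing hemisphere for region %s", rg))
    a <- rm_anova(wide)
    data.frame(subfield = rg, F = a$F, df1 = a$df_between, df2 = a$df_error,
               p = a$p, stringsAsFactors = FALSE)
  })
  collapsed <- sapply(regions, function(rg) {
    sub <- long[long$subfield == rg, ]
    vapply(subs, function(s) mean(sub$accuracy[sub$subject == s]), 0)
  })
  collapsed <- matrix(collapsed, nrow = length(subs),
                      dimnames = list(subject = subs, subfield = regions))
  list(hemisphere_tests = do.call(rbind, tests), collapsed = collapsed)
}
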
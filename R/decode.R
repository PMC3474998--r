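#' Nested leave-one-trial-out decoding with fold-wise feature selection
#'
#' The two-step MVPA procedure: an outer leave-one-trial-out loop in which,
#' for every fold, (i) searchlight scores are computed on the n - 1 training
#' trials only, (ii) voxels are selected from those scores, (iii) a linear
#' SVM (fixed cost) is trained on the selected voxels of the training
#' trials, and (iv) the held-out trial is predicted. Feature selection never
#' sees the held-out trial, so the reported accuracy is free of selection
#' ("double-dipping") leakage.
#'
#' @param betas A [beta_series()] fit on the spec's restriction mask.
#' @param labels Binary labels, one per trial row (e.g. participants'
#'   choices).
#' @param spec A [searchlight_spec()].
#' @param svm An [svm_spec()].
#' @param rule Feature-selection rule, see [select_features()].
#' @param target_fraction ROI fraction for the `"union_top"` rule.
#' @param subject Optional subject identifier carried into the result.
#' @return A `decoding_result`: cross-validated `accuracy`, `n_test`,
#'   `mean_selected_voxels`, and per-fold records (selected voxel set,
#'   prediction, truth).
#' @export
loo_decode <- function(betas, labels, spec, svm = svm_spec(),
                       rule = c("union_top", "single_best"),
                       target_fraction = 0.6, subject = NA) {
  rule <- match.arg(rule)
  stopifnot(inherits(betas, "beta_series"), inherits(spec, "searchlight_spec"),
            inherits(svm, "svm_spec"))
  check_betas_match_mask(betas, spec)
  X <- betas$betas
  y <- labels_to_pm1(labels)
  if (length(y) != nrow(X)) stop("one label per trial row required")
  if (min(table(y)) < 2L)
    stop("each class needs at least 2 trials; with a single trial per class ",
         "the inner selection loop has nothing to cross-validate")
  nb <- build_neighborhoods(spec)
  coords1 <- mask_coords(spec$restriction_mask)
  n <- nrow(X)
  folds <- vector("list", n)
  correct <- logical(n)
  for (t in seq_len(n)) {
    tr <- setdiff(seq_len(n), t)
    ytr <- y[tr]
    if (min(table(ytr)) < 2L)
      stop("a class has a single trial in an outer training fold; more trials are needed")
    scores <- .searchlight_loo_scores(X[tr, , drop = FALSE], nb, ytr,
                                      svm$c, svm$tol, svm$max_iter)
    sel <- select_from_scores(as.numeric(scores), nb, coords1, rule,
                              target_fraction)
    Xtr <- X[tr, sel, drop = FALSE]
    K <- tcrossprod(Xtr)
    fit <- .svm_fit_gram(K, ytr, svm$c, svm$tol, svm$max_iter)
    f <- drop(X[t, sel, drop = FALSE] %*% t(Xtr) %*% (fit$alpha * ytr)) - fit$rho
    pred <- if (f >= 0) 1 else -1
    correct[t] <- pred == y[t]
    folds[[t]] <- list(selected = sel, prediction = pred, truth = y[t],
                       decision_value = f)
  }
  new_decoding_result(
    accuracy = mean(correct), n_test = n,
    folds = folds, labels_levels = attr(y, "levels"),
    mean_selected_voxels = mean(vapply(folds, function(f) length(f$selected), 0)),
    subject = subject, subfield = betas$roi_label,
    hemisphere = betas$hemisphere, analysis = "within",
    rule = rule, radius = spec$radius_voxels, c = svm$c)
}

#' Cross-condition decoding
#'
#' Feature selection and SVM training are performed once on the full
#' training condition; accuracy is then evaluated once on the disjoint test
#' condition (e.g. train on 100% scene trials labelled by choice, test on
#' 50% morph trials labelled by choice — the motor-confound control).
#'
#' @param train_betas,test_betas [beta_series()] objects on the same ROI.
#' @param train_labels,test_labels Binary labels for each condition.
#' @inheritParams loo_decode
#' @return A `decoding_result` with `n_test` the size of the test condition.
#' @export
cross_decode <- function(train_betas, train_labels, test_betas, test_labels,
                         spec, svm = svm_spec(),
                         rule = c("union_top", "single_best"),
                         target_fraction = 0.6, subject = NA) {
  rule <- match.arg(rule)
  stopifnot(inherits(train_betas, "beta_series"),
            inherits(test_betas, "beta_series"))
  check_betas_match_mask(train_betas, spec)
  if (!identical(dim(train_betas$voxel_coords), dim(test_betas$voxel_coords)) ||
      !all(train_betas$voxel_coords == test_betas$voxel_coords))
    stop("train and test beta series are on different voxel grids/ROIs")
  ytr <- labels_to_pm1(train_labels)
  lv <- attr(ytr, "levels")
  yte_chr <- as.character(test_labels)
  if (!all(yte_chr %in% lv))
    stop("test labels contain classes absent from training labels")
  yte <- ifelse(yte_chr == lv[1], 1, -1)
  if (min(table(ytr)) < 2L) stop("at least 2 training trials per class required")
  scores <- searchlight_scores(train_betas, train_labels, spec, svm)
  sel <- select_features(scores, spec, rule, target_fraction)
  Xtr <- train_betas$betas[, sel, drop = FALSE]
  K <- tcrossprod(Xtr)
  fit <- .svm_fit_gram(K, ytr, svm$c, svm$tol, svm$max_iter)
  f <- drop(test_betas$betas[, sel, drop = FALSE] %*% t(Xtr) %*% (fit$alpha * ytr)) - fit$rho
  pred <- ifelse(f >= 0, 1, -1)
  new_decoding_result(
    accuracy = mean(pred == yte), n_test = length(yte),
    folds = list(list(selected = sel, prediction = pred, truth = yte,
                      decision_value = f)),
    labels_levels = lv, mean_selected_voxels = length(sel),
    subject = subject, subfield = train_betas$roi_label,
    hemisphere = train_betas$hemisphere, analysis = "cross",
    rule = rule, radius = spec$radius_voxels, c = svm$c)
}

new_decoding_result <- function(...) {
  structure(list(...), class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %s%s%s: accuracy %.3f (n_test = %d, mean %.1f voxels selected)\n",
              if (is.na(x$subject)) "" else paste0("subject ", x$subject, " "),
              if (is.null(x$subfield)) "ROI" else x$subfield,
              if (is.null(x$hemisphere)) "" else paste0("-", x$hemisphere),
              x$accuracy, x$n_test, x$mean_selected_voxels))
  invisible(x)
}

#' @export
summary.decoding_result <- function(object, ...) {
  cat(sprintf("Decoding (%s condition), classes %s vs %s\n", object$analysis,
              object$labels_levels[1], object$labels_levels[2]))
  cat(sprintf("  searchlight radius %d, linear SVM C = %g, rule = %s\n",
              object$radius, object$c, object$rule))
  cat(sprintf("  accuracy: %.3f over %d test trials\n", object$accuracy,
              object$n_test))
  cat(sprintf("  mean selected voxels per fold: %.1f\n",
              object$mean_selected_voxels))
  invisible(object)
}
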
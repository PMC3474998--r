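#' Searchlight specification
#'
#' A searchlight is a small sphere centred in turn on every voxel of the
#' restriction mask; only voxels inside the mask are ever included, so the
#' effective sphere shape shrinks near ROI borders.
#'
#' @param restriction_mask A non-empty [roi_mask()] defining the search space.
#' @param radius_voxels Sphere radius in voxels (default 3, the conventional
#'   radius for hippocampal decoding).
#' @return Object of class `searchlight_spec`.
#' @export
searchlight_spec <- function(restriction_mask, radius_voxels = 3L) {
  stopifnot(inherits(restriction_mask, "roi_mask"),
            radius_voxels >= 1L)
  if (roi_voxel_count(restriction_mask) == 0L)
    stop("restriction mask is empty")
  structure(list(restriction_mask = restriction_mask,
                 radius_voxels = as.integer(radius_voxels)),
            class = "searchlight_spec")
}

#' Linear SVM specification
#'
#' Linear kernel only, with a fixed regularization hyperparameter (no
#' hyperparameter search); `c = 1` is the conventional fixed setting. The
#' dual optimizer tolerance is fixed for reproducible decisions.
#'
#' @param c Soft-margin cost (> 0), default 1.
#' @param tol KKT violation tolerance of the dual solver (default 1e-4).
#' @param max_iter Iteration cap of the dual solver.
#' @return Object of class `svm_spec`.
#' @export
svm_spec <- function(c = 1, tol = 1e-4, max_iter = 50000L) {
  stopifnot(c > 0, tol > 0, max_iter >= 1L)
  structure(list(c = c, tol = tol, max_iter = as.integer(max_iter)),
            class = "svm_spec")
}

#' Integer offsets of a discrete sphere
#'
#' All integer offset triples `(dx, dy, dz)` with
#' `dx^2 + dy^2 + dz^2 <= radius^2`, including the origin. Radius 3 gives
#' 123 offsets.
#'
#' @param radius Non-negative integer radius.
#' @return Integer matrix with 3 columns, ordered lexicographically.
#' @export
sphere_offsets <- function(radius) {
  if (!is.numeric(radius) || length(radius) != 1L || radius < 0)
    stop("radius must be a non-negative integer")
  radius <- as.integer(radius)
  g <- as.matrix(expand.grid(dz = -radius:radius, dy = -radius:radius,
                             dx = -radius:radius))[, 3:1, drop = FALSE]
  g <- g[rowSums(g^2) <= radius^2, , drop = FALSE]
  g[order(g[, 1], g[, 2], g[, 3]), , drop = FALSE]
}

#' Mask-restricted searchlight neighborhood of a voxel
#'
#' The sphere of [sphere_offsets()] translated to `center` and intersected
#' with the restriction mask (and the grid). The center must itself lie in
#' the mask.
#'
#' @param center Integer triple, 1-based grid coordinates.
#' @param spec A [searchlight_spec()].
#' @return Integer matrix of 1-based voxel coordinates (one row per voxel in
#'   the neighborhood, including the center).
#' @export
searchlight_neighborhood <- function(center, spec) {
  stopifnot(inherits(spec, "searchlight_spec"), length(center) == 3L)
  m <- spec$restriction_mask$data
  dims <- dim(m)
  center <- as.integer(center)
  if (any(center < 1L) || any(center > dims) ||
      m[center[1], center[2], center[3]] == 0L)
    stop("searchlight center is outside the restriction mask")
  pts <- sweep(sphere_offsets(spec$radius_voxels), 2, center, `+`)
  ok <- pts[, 1] >= 1L & pts[, 2] >= 1L & pts[, 3] >= 1L &
    pts[, 1] <= dims[1] & pts[, 2] <= dims[2] & pts[, 3] <= dims[3]
  pts <- pts[ok, , drop = FALSE]
  inside <- m[pts] != 0L
  pts[inside, , drop = FALSE]
}

# For every mask voxel (in mask_coords order, the column order of a masked
# beta series) the neighborhood as indices into that same ordering.
build_neighborhoods <- function(spec) {
  m <- spec$restriction_mask$data
  dims <- dim(m)
  coords <- mask_coords(spec$restriction_mask)
  lin <- coords[, 1] + dims[1] * (coords[, 2] - 1L) + dims[1] * dims[2] * (coords[, 3] - 1L)
  col_of <- integer(prod(dims))
  col_of[lin] <- seq_len(nrow(coords))
  offs <- sphere_offsets(spec$radius_voxels)
  lapply(seq_len(nrow(coords)), function(i) {
    pts <- sweep(offs, 2, coords[i, ], `+`)
    ok <- pts[, 1] >= 1L & pts[, 2] >= 1L & pts[, 3] >= 1L &
      pts[, 1] <= dims[1] & pts[, 2] <= dims[2] & pts[, 3] <= dims[3]
    pts <- pts[ok, , drop = FALSE]
    plin <- pts[, 1] + dims[1] * (pts[, 2] - 1L) + dims[1] * dims[2] * (pts[, 3] - 1L)
    sort(col_of[plin][m[plin] != 0L])
  })
}

# map 2-level labels to +1/-1; the first factor level (or alphabetically
# first value) codes +1
labels_to_pm1 <- function(labels) {
  lv <- if (is.factor(labels)) levels(droplevels(labels)) else sort(unique(as.character(labels)))
  if (length(lv) != 2L)
    stop(sprintf("binary labels required, got %d class(es): %s",
                 length(lv), paste(lv, collapse = ", ")))
  y <- ifelse(as.character(labels) == lv[1], 1, -1)
  attr(y, "levels") <- lv
  y
}

check_betas_match_mask <- function(betas, spec) {
  coords <- mask_coords(spec$restriction_mask) - 1L
  bc <- betas$voxel_coords
  if (nrow(bc) != nrow(coords) || !all(bc == coords))
    stop("beta series voxels do not match the restriction mask ",
         "(fit the beta series with this mask)")
  invisible(TRUE)
}

#' Searchlight information map over an ROI
#'
#' For every voxel of the restriction mask, the leave-one-out
#' cross-validated accuracy of a linear SVM trained on the features of the
#' voxel's searchlight neighborhood — computed strictly within the supplied
#' (training) trials. With n training trials each of the n inner folds
#' trains on n - 1 trials, i.e. k-fold with k equal to the number of trials.
#'
#' @param train_betas A [beta_series()] fit on the restriction mask.
#' @param train_labels Binary labels, one per trial row.
#' @param spec A [searchlight_spec()].
#' @param svm An [svm_spec()].
#' @return Numeric vector of per-center scores (one per mask voxel, in mask
#'   voxel order) with the 0-based center coordinates as attribute
#'   `"coords"`.
#' @export
searchlight_scores <- function(train_betas, train_labels, spec,
                               svm = svm_spec()) {
  stopifnot(inherits(train_betas, "beta_series"),
            inherits(spec, "searchlight_spec"), inherits(svm, "svm_spec"))
  check_betas_match_mask(train_betas, spec)
  y <- labels_to_pm1(train_labels)
  if (length(y) != nrow(train_betas$betas))
    stop("one label per trial row required")
  if (min(table(y)) < 2L)
    stop("at least 2 trials per class are required for searchlight scoring")
  nb <- build_neighborhoods(spec)
  scores <- .searchlight_loo_scores(train_betas$betas, nb, y, svm$c, svm$tol,
                                    svm$max_iter)
  scores <- as.numeric(scores)
  attr(scores, "coords") <- train_betas$voxel_coords
  scores
}

#' Select voxels from searchlight scores
#'
#' Default rule (`"union_top"`): rank searchlight centers by score (ties
#' broken lexicographically by center coordinate for determinism), then take
#' the union of the neighborhoods of the top-ranked centers, stopping at the
#' smallest number of centers whose union covers at least `target_fraction`
#' of the ROI. With the default fraction 0.6 a CA1-sized ROI (~267 voxels)
#' selects on the order of 160 voxels. The alternative `"single_best"` rule
#' returns exactly the best center's neighborhood.
#'
#' @param scores Numeric per-center scores from [searchlight_scores()].
#' @param spec The same [searchlight_spec()] used for scoring.
#' @param rule `"union_top"` or `"single_best"`.
#' @param target_fraction Fraction of the ROI the union must reach
#'   (default 0.6).
#' @return Sorted integer vector of selected voxel indices (columns of the
#'   masked beta series).
#' @export
select_features <- function(scores, spec, rule = c("union_top", "single_best"),
                            target_fraction = 0.6) {
  rule <- match.arg(rule)
  if (length(scores) == 0L) stop("empty score map")
  stopifnot(inherits(spec, "searchlight_spec"),
            target_fraction > 0, target_fraction <= 1)
  nb <- build_neighborhoods(spec)
  if (length(nb) != length(scores))
    stop("scores do not align with the restriction mask")
  coords <- mask_coords(spec$restriction_mask)
  select_from_scores(scores, nb, coords, rule, target_fraction)
}

# core of select_features with precomputed neighborhoods
select_from_scores <- function(scores, nb, coords, rule, target_fraction) {
  ord <- order(-scores, coords[, 1], coords[, 2], coords[, 3])
  if (rule == "single_best") return(sort(nb[[ord[1]]]))
  n_roi <- length(scores)
  target <- ceiling(target_fraction * n_roi)
  sel <- logical(n_roi)
  for (i in ord) {
    sel[nb[[i]]] <- TRUE
    if (sum(sel) >= target) break
  }
  which(sel)
}
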
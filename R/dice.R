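#' Dice overlap coefficient between two binary masks
#'
#' The volume of overlap divided by the mean volume of the two masks,
#' `|a & b| / ((|a| + |b|) / 2)`, algebraically identical to the classical
#' Dice (1945) coefficient `2|a & b| / (|a| + |b|)`. Used to quantify intra-
#' and inter-rater reliability of manual ROI segmentations.
#'
#' @param a,b [roi_mask()] objects (or 3D binary arrays) on the same grid.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  va <- as_mask_array(a); vb <- as_mask_array(b)
  if (!identical(dim(va), dim(vb)))
    stop(sprintf("mask grids differ: %s vs %s",
                 paste(dim(va), collapse = "x"), paste(dim(vb), collapse = "x")))
  na <- sum(va); nb <- sum(vb)
  if (na == 0L || nb == 0L)
    stop("dice() requires two non-empty masks")
  2 * sum(va & vb) / (na + nb)
}

#' Dice coefficient restricted to a run of consecutive slices
#'
#' Segmentation-reliability protocols compare raters on a small number of
#' consecutive slices through the body of the structure (conventionally
#' five). This restricts both masks to `n_slices` consecutive slices along
#' `axis` starting at `start` (1-based) and computes [dice()] on the
#' sub-volumes. Which slices constitute the "body" is an explicit input.
#'
#' @param a,b [roi_mask()] objects on the same grid.
#' @param axis `"x"`, `"y"` or `"z"`; the default `"y"` corresponds to
#'   stacking coronal slices along the anterior-posterior axis.
#' @param start First slice (1-based).
#' @param n_slices Number of consecutive slices (default 5).
#' @return Dice coefficient of the restricted masks.
#' @export
dice_on_slices <- function(a, b, axis = c("y", "x", "z"), start, n_slices = 5L) {
  axis <- match.arg(axis)
  va <- as_mask_array(a); vb <- as_mask_array(b)
  if (!identical(dim(va), dim(vb))) stop("mask grids differ")
  ax <- match(axis, c("x", "y", "z"))
  if (start < 1L || start + n_slices - 1L > dim(va)[ax])
    stop("slice range outside grid")
  sl <- start:(start + n_slices - 1L)
  sub <- function(v) switch(ax,
                            v[sl, , , drop = FALSE],
                            v[, sl, , drop = FALSE],
                            v[, , sl, drop = FALSE])
  sa <- sub(va); sb <- sub(vb)
  if (sum(sa) == 0L || sum(sb) == 0L)
    stop("slice range contains no mask voxels in one of the inputs")
  2 * sum(sa & sb) / (sum(sa) + sum(sb))
}

as_mask_array <- function(x) {
  if (inherits(x, "roi_mask")) x <- x$data
  if (length(dim(x)) != 3L) stop("expected a 3D mask")
  x != 0
}
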
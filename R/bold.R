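#' 4D BOLD container
#'
#' A 4D array (x, y, z, time) with acquisition metadata.
#'
#' @param data 4D numeric array.
#' @param tr_s Repetition time in seconds (default 3.5).
#' @param voxel_size_mm Isotropic voxel size in mm (default 1.5).
#' @return Object of class `bold4d`.
#' @export
bold4d <- function(data, tr_s = 3.5, voxel_size_mm = 1.5) {
  if (length(dim(data)) != 4L) stop("BOLD `data` must be a 4D array")
  stopifnot(tr_s > 0, voxel_size_mm > 0, dim(data)[4] >= 1L)
  if (!all(is.finite(data))) stop("BOLD data contain non-finite values")
  structure(list(data = data, tr_s = tr_s, voxel_size_mm = voxel_size_mm),
            class = "bold4d")
}

#' @export
print.bold4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold4d> %dx%dx%d grid, %d volumes, TR %.3g s, %.2g mm iso\n",
              d[1], d[2], d[3], d[4], x$tr_s, x$voxel_size_mm))
  invisible(x)
}

#' Spatial Gaussian smoothing of a BOLD series
#'
#' Convolves every volume with an isotropic 3D Gaussian of the given full
#' width at half maximum. The kernel standard deviation in voxel units is
#' `fwhm / (2 * sqrt(2 * log(2))) / voxel_size`; the discrete kernel is
#' truncated at 3 sigma and renormalized to unit mass, and boundaries are
#' handled by reflection (so a constant image stays constant and the image
#' sum is preserved). `fwhm_mm = 0` is the identity.
#'
#' @param bold A [bold4d()] object.
#' @param fwhm_mm Full width at half maximum in mm (>= 0); 3 mm is the
#'   conventional "minimal" smoothing for high-resolution ROI decoding.
#' @return A smoothed [bold4d()].
#' @export
smooth_gaussian <- function(bold, fwhm_mm = 3) {
  stopifnot(inherits(bold, "bold4d"))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm < 0)
    stop("fwhm_mm must be a non-negative scalar")
  if (fwhm_mm == 0) return(bold)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / bold$voxel_size_mm
  k <- gaussian_kernel_1d(sigma_vox)
  out <- bold$data
  for (axis in 1:3) out <- convolve_axis_reflect(out, k, axis)
  bold4d(out, tr_s = bold$tr_s, voxel_size_mm = bold$voxel_size_mm)
}

# discrete Gaussian kernel truncated at 3 sigma, unit mass
gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# 1D convolution along `axis` of a 3D or 4D array with reflective (half-sample
# symmetric, edge repeated) boundaries; this extension makes the filter mass-
# preserving, so the total image sum is unchanged by smoothing
convolve_axis_reflect <- function(arr, kernel, axis) {
  d <- dim(arr)
  n <- d[axis]
  r <- (length(kernel) - 1L) %/% 2L
  out <- array(0, dim = d)
  idx_all <- lapply(d, seq_len)
  for (j in seq_along(kernel)) {
    off <- j - r - 1L
    src <- seq_len(n) + off
    while (any(src < 1L | src > n)) {
      src <- ifelse(src < 1L, 1L - src, src)
      src <- ifelse(src > n, 2L * n + 1L - src, src)
    }
    idx <- idx_all
    idx[[axis]] <- src
    out <- out + kernel[j] * do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  }
  out
}
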
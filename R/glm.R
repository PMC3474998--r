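#' Per-trial beta series
#'
#' Trials x voxels matrix of GLM coefficients together with the voxel
#' coordinates it was estimated on and the trial rows it aligns to.
#'
#' @param betas Numeric matrix, trials x voxels.
#' @param voxel_coords Integer matrix (voxels x 3) of 0-based grid indices.
#' @param trial_index Integer vector aligning rows to event-table rows.
#' @param roi_label Optional subfield tag.
#' @param hemisphere Optional hemisphere tag.
#' @return Object of class `beta_series`.
#' @export
beta_series <- function(betas, voxel_coords, trial_index = seq_len(nrow(betas)),
                        roi_label = NULL, hemisphere = NULL) {
  betas <- as.matrix(betas)
  voxel_coords <- as.matrix(voxel_coords)
  stopifnot(ncol(voxel_coords) == 3L, nrow(voxel_coords) == ncol(betas),
            length(trial_index) == nrow(betas))
  structure(list(betas = betas, voxel_coords = voxel_coords,
                 trial_index = trial_index, roi_label = roi_label,
                 hemisphere = hemisphere),
            class = "beta_series")
}

#' @export
print.beta_series <- function(x, ...) {
  cat(sprintf("<beta_series> %d trials x %d voxels%s\n",
              nrow(x$betas), ncol(x$betas),
              if (is.null(x$roi_label)) "" else paste0(" [", x$roi_label, "]")))
  invisible(x)
}

#' Fit a per-trial beta series by ordinary least squares
#'
#' Fits the full design (trial regressors + nuisance + intercept) to every
#' voxel time series by OLS and returns the task-regressor coefficients
#' only, trial-aligned. With a mask, estimation is restricted to mask
#' voxels; otherwise all grid voxels are used.
#'
#' @param bold A [bold4d()] (typically after [smooth_gaussian()]).
#' @param design Design matrix from [build_design()].
#' @param mask Optional [roi_mask()] restricting the voxels.
#' @return A [beta_series()]. Residuals are available via
#'   `attr(, "residuals")` for diagnostic use.
#' @export
fit_beta_series <- function(bold, design, mask = NULL) {
  stopifnot(inherits(bold, "bold4d"))
  d <- dim(bold$data)
  if (nrow(design) != d[4])
    stop(sprintf("design has %d rows but BOLD has %d volumes", nrow(design), d[4]))
  qr_x <- qr(design)
  if (qr_x$rank < ncol(design)) {
    bad <- colnames(design)[qr_x$pivot[(qr_x$rank + 1L):ncol(design)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  if (is.null(mask)) {
    coords <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                                    z = seq_len(d[3])))
    Y <- matrix(bold$data, nrow = prod(d[1:3]), ncol = d[4])
    Y <- t(Y)
  } else {
    stopifnot(inherits(mask, "roi_mask"))
    if (!identical(dim(mask$data), d[1:3])) stop("mask grid does not match BOLD grid")
    coords <- mask_coords(mask)
    flat <- matrix(bold$data, nrow = prod(d[1:3]), ncol = d[4])
    lin <- coords[, 1] + d[1] * (coords[, 2] - 1L) + d[1] * d[2] * (coords[, 3] - 1L)
    Y <- t(flat[lin, , drop = FALSE])
  }
  coefs <- qr.coef(qr_x, Y)
  task <- attr(design, "task_cols") %||% seq_len(ncol(design) - 1L)
  betas <- coefs[task, , drop = FALSE]
  resid <- Y - design %*% coefs
  out <- beta_series(betas,
                     voxel_coords = coords - 1L,
                     trial_index = seq_along(task),
                     roi_label = if (!is.null(mask)) mask$subfield,
                     hemisphere = if (!is.null(mask)) mask$hemisphere)
  attr(out, "residuals") <- resid
  attr(out, "design") <- design
  out
}
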
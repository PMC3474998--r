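#' NIfTI-1 input/output for masks and BOLD series
#'
#' Masks are written as 0/1 integer volumes; BOLD as 4D floating point with
#' the TR in the time pixdim. Subfield/hemisphere labels travel in the file
#' name, not the header.
#'
#' @param mask A [roi_mask()].
#' @param bold A [bold4d()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @param subfield,hemisphere Labels to attach on read.
#' @return Writers return `path` invisibly; readers return the object.
#' @name nifti_io
NULL

#' @rdname nifti_io
#' @export
write_mask_nifti <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  img <- RNifti::asNifti(mask$data)
  RNifti::pixdim(img) <- rep(mask$voxel_size_mm, 3)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_mask_nifti <- function(path, subfield = "ROI", hemisphere = "L") {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1]
  roi_mask(array(as.integer(img != 0), dim = dim(img)),
           subfield = subfield, hemisphere = hemisphere, voxel_size_mm = vox)
}

#' @rdname nifti_io
#' @export
write_bold_nifti <- function(bold, path) {
  stopifnot(inherits(bold, "bold4d"))
  img <- RNifti::asNifti(bold$data)
  RNifti::pixdim(img) <- c(rep(bold$voxel_size_mm, 3), bold$tr_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_bold_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  bold4d(array(as.numeric(img), dim = dim(img)),
         tr_s = if (length(pd) >= 4) pd[4] else 1,
         voxel_size_mm = pd[1])
}

#' Write a beta series as 4D NIfTI plus a sidecar table
#'
#' The trial axis is stored as the 4th NIfTI dimension over the ROI bounding
#' box; a tab-delimited sidecar (same path with `.tsv` appended) records the
#' 0-based voxel coordinates so the trials x voxels matrix can be
#' reconstructed exactly.
#'
#' @param bs A [beta_series()].
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_beta_series <- function(bs, path) {
  stopifnot(inherits(bs, "beta_series"))
  co <- bs$voxel_coords + 1L
  dims <- apply(co, 2, max)
  vol <- array(0, dim = c(dims, nrow(bs$betas)))
  for (t in seq_len(nrow(bs$betas)))
    vol[cbind(co, t)] <- bs$betas[t, ]
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  write.table(data.frame(x = bs$voxel_coords[, 1], y = bs$voxel_coords[, 2],
                         z = bs$voxel_coords[, 3]),
              paste0(path, ".tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# structured ground-truth sidecar (JSON)
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(latent_state = truth$latent_state,
         signal = as.list(truth$signal),
         patterns = lapply(truth$patterns, lapply, as.numeric)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
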
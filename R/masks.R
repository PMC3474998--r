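#' Binary region-of-interest mask
#'
#' A 3D binary mask labelled with hippocampal subfield and hemisphere.
#' Voxels are on the functional grid; `voxel_size_mm` is the isotropic edge
#' length (1.5 mm by default, the resolution of high-resolution hippocampal
#' fMRI protocols).
#'
#' @param data 3D array of 0/1 (logical or numeric).
#' @param subfield One of `"CA1"`, `"CA3"`, `"DG"`, `"SUB"` (or another label).
#' @param hemisphere `"L"` or `"R"`.
#' @param voxel_size_mm Positive isotropic voxel size in mm.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(data, subfield = "ROI", hemisphere = "L",
                     voxel_size_mm = 1.5) {
  if (length(dim(data)) != 3L)
    stop("mask `data` must be a 3D array")
  d <- array(as.integer(data != 0), dim = dim(data))
  stopifnot(voxel_size_mm > 0)
  structure(list(data = d, subfield = subfield, hemisphere = hemisphere,
                 voxel_size_mm = voxel_size_mm),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s-%s: %d voxels on %s grid (%.2g mm iso)\n",
              x$subfield, x$hemisphere, sum(x$data),
              paste(dim(x$data), collapse = "x"), x$voxel_size_mm))
  invisible(x)
}

#' Number of nonzero voxels in a mask
#'
#' @param mask A [roi_mask()].
#' @return Integer voxel count.
#' @export
roi_voxel_count <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  sum(mask$data != 0L)
}

# coordinates (1-based matrix n x 3) of nonzero voxels, in column-major order
mask_coords <- function(mask) {
  which(mask$data != 0L, arr.ind = TRUE)
}

# default per-hemisphere voxel-count targets: group means of manually
# segmented subfields at 1.5 mm functional resolution, rounded
default_subfield_counts <- function() {
  c(CA1 = 267L, CA3 = 248L, DG = 183L, SUB = 111L)
}

# 6-connectivity test via breadth-first flood fill
mask_is_connected <- function(vol) {
  idx <- which(vol != 0L, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0L) return(FALSE)
  if (n == 1L) return(TRUE)
  dims <- dim(vol)
  lin <- function(co) co[, 1] + dims[1] * (co[, 2] - 1L) + dims[1] * dims[2] * (co[, 3] - 1L)
  inmask <- logical(prod(dims)); inmask[lin(idx)] <- TRUE
  seen <- logical(prod(dims))
  queue <- lin(idx[1, , drop = FALSE]); seen[queue] <- TRUE
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  count <- 0L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]; count <- count + 1L
    v0 <- v - 1L
    x <- v0 %% dims[1] + 1L
    y <- (v0 %/% dims[1]) %% dims[2] + 1L
    z <- v0 %/% (dims[1] * dims[2]) + 1L
    for (k in seq_len(6)) {
      nx <- x + offs[k, 1]; ny <- y + offs[k, 2]; nz <- z + offs[k, 3]
      if (nx < 1 || ny < 1 || nz < 1 || nx > dims[1] || ny > dims[2] || nz > dims[3]) next
      nv <- nx + dims[1] * (ny - 1L) + dims[1] * dims[2] * (nz - 1L)
      if (inmask[nv] && !seen[nv]) { seen[nv] <- TRUE; queue <- c(queue, nv) }
    }
  }
  count == n
}

# grow a connected random blob of `n_vox` voxels inside the box
# [lo, hi] (inclusive, 1-based per axis), avoiding voxels already taken
grow_blob <- function(dims, lo, hi, n_vox, taken) {
  box_cap <- prod(hi - lo + 1L)
  if (box_cap < n_vox) return(NULL)
  in_box <- function(x, y, z)
    x >= lo[1] && x <= hi[1] && y >= lo[2] && y <= hi[2] && z >= lo[3] && z <= hi[3]
  linidx <- function(x, y, z) x + dims[1] * (y - 1L) + dims[1] * dims[2] * (z - 1L)
  for (attempt in seq_len(25)) {
    start <- c(sample(lo[1]:hi[1], 1L), sample(lo[2]:hi[2], 1L), sample(lo[3]:hi[3], 1L))
    if (taken[linidx(start[1], start[2], start[3])]) next
    chosen <- integer(0)
    frontier <- matrix(start, nrow = 1)
    frontier_lin <- linidx(start[1], start[2], start[3])
    inset <- logical(prod(dims))
    offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
    while (length(chosen) < n_vox && nrow(frontier) > 0L) {
      pick <- sample.int(nrow(frontier), 1L)
      v <- frontier[pick, ]; vlin <- frontier_lin[pick]
      frontier <- frontier[-pick, , drop = FALSE]; frontier_lin <- frontier_lin[-pick]
      if (inset[vlin] || taken[vlin]) next
      inset[vlin] <- TRUE
      chosen <- c(chosen, vlin)
      for (k in seq_len(6)) {
        nx <- v[1] + offs[k, 1]; ny <- v[2] + offs[k, 2]; nz <- v[3] + offs[k, 3]
        if (!in_box(nx, ny, nz)) next
        nlin <- linidx(nx, ny, nz)
        if (!inset[nlin] && !taken[nlin]) {
          frontier <- rbind(frontier, c(nx, ny, nz))
          frontier_lin <- c(frontier_lin, nlin)
        }
      }
    }
    if (length(chosen) == n_vox) return(chosen)
  }
  NULL
}

#' Generate disjoint connected subfield masks for both hemispheres
#'
#' Grows eight random 6-connected blobs (four subfields x two hemispheres) by
#' stochastic region growing, each inside its own spatial compartment so the
#' masks are disjoint by construction. Real subfield anatomy is not emulated;
#' only the properties downstream code relies on are guaranteed: voxel counts
#' near the targets, disjointness, and connectedness. Per-mask counts are
#' jittered uniformly within `±jitter` of the target to mimic between-subject
#' volume variability.
#'
#' @param grid_dims Integer vector of 3 grid dimensions.
#' @param target_counts Named integer vector of per-hemisphere voxel-count
#'   targets; default [default_subfield_counts()] (CA1 267, CA3 248, DG 183,
#'   SUB 111).
#' @param seed Integer seed; identical seeds give identical masks.
#' @param jitter Fractional count jitter (default 0.05, always within the
#'   ±10% contract).
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @return List of eight [roi_mask()] objects named `<subfield>_<hemi>`.
#' @export
make_subfield_masks <- function(grid_dims, target_counts = default_subfield_counts(),
                                seed = NULL, jitter = 0.05, voxel_size_mm = 1.5) {
  stopifnot(length(grid_dims) == 3L, all(grid_dims >= 2L),
            all(target_counts >= 1L), jitter >= 0, jitter <= 0.1)
  grid_dims <- as.integer(grid_dims)
  subfields <- names(target_counts)
  if (is.null(subfields)) stop("target_counts must be named by subfield")
  with_seed(seed, {
    # hemispheres split along x; subfields in y/z quadrants of each hemisphere
    xmid <- grid_dims[1] %/% 2L
    ymid <- grid_dims[2] %/% 2L
    zmid <- grid_dims[3] %/% 2L
    hemi_x <- list(L = c(1L, xmid), R = c(xmid + 1L, grid_dims[1]))
    quads <- list(c(1L, 1L), c(1L, 2L), c(2L, 1L), c(2L, 2L))
    if (length(subfields) > 4L)
      stop("at most 4 subfields per hemisphere are supported")
    taken <- logical(prod(grid_dims))
    out <- list()
    for (h in c("L", "R")) {
      xr <- hemi_x[[h]]
      for (si in seq_along(subfields)) {
        q <- quads[[si]]
        lo <- c(xr[1],
                if (q[1] == 1L) 1L else ymid + 1L,
                if (q[2] == 1L) 1L else zmid + 1L)
        hi <- c(xr[2],
                if (q[1] == 1L) ymid else grid_dims[2],
                if (q[2] == 1L) zmid else grid_dims[3])
        target <- target_counts[[si]]
        n_vox <- max(1L, round(target * runif(1, 1 - jitter, 1 + jitter)))
        blob <- grow_blob(grid_dims, lo, hi, n_vox, taken)
        if (is.null(blob))
          stop(sprintf("mask placement failed: grid too small for %s_%s (target %d voxels in a %s box)",
                       subfields[si], h, n_vox, paste(hi - lo + 1L, collapse = "x")))
        taken[blob] <- TRUE
        vol <- array(0L, dim = grid_dims)
        vol[blob] <- 1L
        out[[paste0(subfields[si], "_", h)]] <-
          roi_mask(vol, subfield = subfields[si], hemisphere = h,
                   voxel_size_mm = voxel_size_mm)
      }
    }
    out
  })
}

#' Construct a mask pair with a prescribed Dice overlap
#'
#' Builds a second mask of the same volume as `base` whose Dice coefficient
#' with `base` hits `target_dice` to within 0.02, by retaining
#' `round(target_dice * v)` of the base voxels and replacing the rest with
#' voxels drawn from just outside the base. Used as a fixture for
#' segmentation-reliability computations.
#'
#' @param base A [roi_mask()].
#' @param target_dice Target Dice coefficient in \[0, 1\].
#' @param seed Integer seed.
#' @return List with elements `a` (the base) and `b` (the constructed mask).
#' @export
make_mask_pair <- function(base, target_dice, seed = NULL) {
  stopifnot(inherits(base, "roi_mask"),
            target_dice >= 0, target_dice <= 1)
  v <- roi_voxel_count(base)
  if (v == 0L) stop("base mask is empty")
  o <- round(target_dice * v)
  if (abs(o / v - target_dice) > 0.02)
    stop(sprintf("target Dice %.3f unattainable within 0.02 for a %d-voxel base (closest achievable %.3f)",
                 target_dice, v, o / v))
  with_seed(seed, {
    dims <- dim(base$data)
    inside <- which(base$data != 0L)
    keep <- sample(inside, o)
    outside <- setdiff(seq_len(prod(dims)), inside)
    if (length(outside) < v - o)
      stop("grid too small to place the non-overlapping portion")
    swap <- sample(outside, v - o)
    vol <- array(0L, dim = dims)
    vol[c(keep, swap)] <- 1L
    b <- roi_mask(vol, subfield = base$subfield, hemisphere = base$hemisphere,
                  voxel_size_mm = base$voxel_size_mm)
    list(a = base, b = b)
  })
}
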
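#' Sphere region of interest around a voxel
#'
#' Returns every voxel whose centre-to-centre Euclidean distance from the
#' given centre voxel is at most `radius_mm`. With the study geometry
#' (15-mm radius, 3-mm isotropic voxels) this is the 5-voxel-radius sphere of
#' 515 voxels used around each localizer peak. Spheres that meet the grid
#' boundary are clipped with a warning.
#'
#' @param center Integer 3-vector, 1-based voxel indices of the centre.
#' @param radius_mm Sphere radius in millimetres.
#' @param voxel_mm Isotropic voxel edge in millimetres.
#' @param grid_dims Integer 3-vector of grid dimensions.
#' @return An object of class `roi_mask`: a list with `voxels` (n x 3 integer
#'   matrix of voxel indices), `center`, `radius_mm` and `source`.
#' @examples
#' nrow(sphere_roi(c(12, 12, 8), 15, 3, c(24, 24, 16))$voxels)  # 515
#' @export
sphere_roi <- function(center, radius_mm = 15, voxel_mm = 3,
                       grid_dims = c(24L, 24L, 16L)) {
  center <- as.integer(round(center))
  if (length(center) != 3L || any(center < 1) || any(center > grid_dims))
    stop("sphere centre outside the grid")
  if (radius_mm < 0) stop("radius_mm must be non-negative")
  r_vox <- radius_mm / voxel_mm
  rng <- floor(r_vox)
  offs <- as.matrix(expand.grid(dx = -rng:rng, dy = -rng:rng, dz = -rng:rng))
  offs <- offs[rowSums(offs^2) <= r_vox^2 + 1e-9, , drop = FALSE]
  vox <- sweep(offs, 2, center, "+")
  inside <- vox[, 1] >= 1 & vox[, 1] <= grid_dims[1] &
    vox[, 2] >= 1 & vox[, 2] <= grid_dims[2] &
    vox[, 3] >= 1 & vox[, 3] <= grid_dims[3]
  if (!all(inside)) {
    warning("sphere clipped at the grid boundary")
    vox <- vox[inside, , drop = FALSE]
  }
  vox <- vox[order(vox[, 3], vox[, 2], vox[, 1]), , drop = FALSE]
  dimnames(vox) <- list(NULL, c("x", "y", "z"))
  structure(list(voxels = matrix(as.integer(vox), ncol = 3,
                                 dimnames = list(NULL, c("x", "y", "z"))),
                 center = center, radius_mm = radius_mm,
                 source = "localizer-peak"),
            class = "roi_mask")
}

#' Load a region of interest from a NIfTI mask
#'
#' Nonzero voxels of the mask become the ROI. Non-binary masks are accepted
#' with a warning; any nonzero value is treated as inclusion.
#'
#' @param path Path to a 3D NIfTI mask.
#' @param grid_dims Expected grid dimensions (checked against the mask).
#' @return A `roi_mask` with `source = "loaded-mask"`.
#' @export
load_mask <- function(path, grid_dims = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop(sprintf("expected a 3D mask, got %d dimensions", length(dim(arr))))
  if (!is.null(grid_dims) && !identical(as.integer(dim(arr)),
                                        as.integer(grid_dims)))
    stop(sprintf("mask grid %s does not match expected grid %s",
                 paste(dim(arr), collapse = "x"),
                 paste(grid_dims, collapse = "x")))
  vals <- unique(as.vector(arr))
  if (!all(vals %in% c(0, 1)))
    warning("non-binary mask: nonzero voxels treated as inclusion")
  idx <- which(arr != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask contains no nonzero voxels (empty ROI)")
  idx <- idx[order(idx[, 3], idx[, 2], idx[, 1]), , drop = FALSE]
  structure(list(voxels = matrix(as.integer(idx), ncol = 3,
                                 dimnames = list(NULL, c("x", "y", "z"))),
                 center = as.integer(round(colMeans(idx))),
                 radius_mm = NA_real_, source = "loaded-mask"),
            class = "roi_mask")
}

#' Write an ROI as a binary NIfTI mask
#'
#' @param roi A `roi_mask`.
#' @param grid_dims Grid dimensions of the output volume.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_mm Isotropic voxel size recorded in the header.
#' @return `path`, invisibly.
#' @export
write_mask <- function(roi, grid_dims, path, voxel_mm = 3) {
  arr <- array(0, dim = grid_dims)
  arr[roi$voxels] <- 1
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(voxel_mm, 3)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

roi_linear_index <- function(roi, grid_dims) {
  v <- roi$voxels
  as.integer(v[, 1] + (v[, 2] - 1L) * grid_dims[1] +
               (v[, 3] - 1L) * grid_dims[1] * grid_dims[2])
}
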
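#' Spatial Gaussian smoothing
#'
#' Separable Gaussian smoothing of a 3D volume or 4D time series with a
#' kernel of the given full width at half maximum, `sigma = fwhm /
#' (2 sqrt(2 ln 2))` per axis in voxel units. The kernel is truncated at
#' 4 sigma and renormalised (including at image boundaries), so constant
#' images are unchanged. `fwhm_mm = 0` is the identity.
#'
#' @param image 3D array, or 4D array smoothed volume-by-volume.
#' @param fwhm_mm Full width at half maximum in millimetres (>= 0).
#' @param voxel_mm Isotropic voxel edge in millimetres.
#' @return Smoothed array of the same dimensions.
#' @export
smooth_gaussian <- function(image, fwhm_mm, voxel_mm = 3) {
  if (fwhm_mm < 0) stop("fwhm_mm must be non-negative")
  if (fwhm_mm == 0) return(image)
  nd <- length(dim(image))
  if (!nd %in% c(3L, 4L)) stop("image must be a 3D or 4D array")
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  dims <- dim(image)
  bands <- lapply(dims[1:3], function(n) smoothing_band(n, sigma))
  if (nd == 3L) return(smooth_volume(image, bands))
  out <- image
  for (t in seq_len(dims[4])) {
    out[, , , t] <- smooth_volume(array(image[, , , t], dims[1:3]), bands)
  }
  out
}

# n x n convolution matrix for a truncated, row-renormalised Gaussian.
smoothing_band <- function(n, sigma) {
  h <- max(1L, ceiling(4 * sigma))
  kern <- exp(-((-h:h)^2) / (2 * sigma^2))
  band <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- pmax(1L, i - h):pmin(n, i + h)
    w <- kern[j - i + h + 1L]
    band[i, j] <- w / sum(w)
  }
  band
}

smooth_volume <- function(vol, bands) {
  d <- dim(vol)
  # axis 1
  m <- bands[[1]] %*% matrix(vol, d[1], d[2] * d[3])
  vol <- array(m, d)
  # axis 2
  vol <- aperm(vol, c(2, 1, 3))
  m <- bands[[2]] %*% matrix(vol, d[2], d[1] * d[3])
  vol <- aperm(array(m, c(d[2], d[1], d[3])), c(2, 1, 3))
  # axis 3
  vol <- aperm(vol, c(3, 1, 2))
  m <- bands[[3]] %*% matrix(vol, d[3], d[1] * d[2])
  aperm(array(m, c(d[3], d[1], d[2])), c(2, 3, 1))
}
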
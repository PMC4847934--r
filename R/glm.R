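#' Voxelwise ordinary-least-squares GLM with a contrast
#'
#' Fits `Y = X beta + eps` independently per voxel by OLS and evaluates a
#' contrast: `t = c' beta_hat / sqrt(sigma2_hat c' (X'X)^-1 c)` with
#' `sigma2_hat = RSS / (n - p)`.
#'
#' @param y `n_volumes x n_voxels` matrix of voxel time series (or a 4D
#'   array, which is reshaped with voxels in array order).
#' @param design A `design_matrix` from [make_design()]. Must be full column
#'   rank; collinear columns are named in the error.
#' @param contrast Contrast vector of length `n_regressors` (see
#'   [contrast_vector()]).
#' @return List with `beta_contrast` and `t`, each of length `n_voxels` (or
#'   3D arrays when `y` was 4D), and `dof = n - p`.
#' @export
fit_glm <- function(y, design, contrast) {
  x <- design$matrix
  dims3 <- NULL
  if (is.array(y) && length(dim(y)) == 4L) {
    dims3 <- dim(y)[1:3]
    y <- t(matrix(y, prod(dims3), dim(y)[4]))
  }
  y <- as.matrix(y)
  n <- nrow(x); p <- ncol(x)
  if (nrow(y) != n)
    stop(sprintf("y has %d rows but the design has %d", nrow(y), n))
  if (length(contrast) != p)
    stop("contrast length does not match the number of regressors")
  qx <- qr(x)
  if (qx$rank < p) {
    bad <- design$contrast_names[qx$pivot[(qx$rank + 1):p]]
    stop(sprintf("design is rank deficient; collinear column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  beta <- qr.coef(qx, y)                       # p x V
  res <- y - x %*% beta
  rss <- colSums(res^2)
  dof <- n - p
  sigma2 <- rss / dof
  xtx_inv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot)]
  cvar <- as.numeric(t(contrast) %*% xtx_inv %*% contrast)
  bc <- as.numeric(crossprod(contrast, beta))
  tval <- bc / sqrt(sigma2 * cvar)
  if (!is.null(dims3)) {
    bc <- array(bc, dims3)
    tval <- array(tval, dims3)
  }
  list(beta_contrast = bc, t = tval, dof = dof)
}

#' Second-level one-sample t-test across subjects
#'
#' Random-effects group analysis: a one-sample t-statistic per voxel over the
#' subjects' first-level contrast maps, with `dof = n_subjects - 1`.
#' Zero-variance voxels cannot support a t-statistic; they are flagged and
#' excluded from the analysis mask (their t is set to `Inf` with the sign of
#' the mean when the mean is nonzero, `NaN` otherwise).
#'
#' @param contrast_maps List of per-subject 3D arrays on identical grids
#'   (at least 2 subjects).
#' @return An object of class `stat_map`: list with `tmap` (3D array),
#'   `dof`, `mask` (logical 3D array of analysable voxels) and `n_in_mask`.
#' @export
group_ttest <- function(contrast_maps) {
  if (length(contrast_maps) < 2L)
    stop("group_ttest needs at least 2 subjects")
  dims <- dim(contrast_maps[[1]])
  for (m in contrast_maps)
    if (!identical(dim(m), dims)) stop("subject maps are on different grids")
  n <- length(contrast_maps)
  flat <- vapply(contrast_maps, as.vector, numeric(prod(dims)))
  mu <- rowMeans(flat)
  sdv <- sqrt(rowSums((flat - mu)^2) / (n - 1))
  tval <- mu / (sdv / sqrt(n))
  zero_var <- sdv == 0
  tval[zero_var] <- sign(mu[zero_var]) * Inf   # NaN where mean is also 0
  if (any(zero_var))
    warning(sprintf("%d zero-variance voxel(s) flagged and excluded from the mask",
                    sum(zero_var)))
  mask <- !zero_var
  structure(list(tmap = array(tval, dims), dof = n - 1L,
                 mask = array(mask, dims), n_in_mask = sum(mask)),
            class = "stat_map")
}
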
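test_that("Gaussian smoothing preserves constants and narrows to the kernel width", {
  img <- array(7, c(12, 12, 8))
  expect_equal(smooth_gaussian(img, 8, 3), img)
  expect_identical(smooth_gaussian(img, 0, 3), img)
  expect_error(smooth_gaussian(img, -1, 3), "non-negative")

  # unit impulse: half-max diameter ~ fwhm in voxel units (8 mm / 3 mm)
  imp <- array(0, c(25, 25, 25))
  imp[13, 13, 13] <- 1
  sm <- smooth_gaussian(imp, 8, 3)
  prof <- sm[, 13, 13]
  half <- max(prof) / 2
  above <- which(prof >= half)
  # linear interpolation of the crossing points
  lo <- min(above); hi <- max(above)
  xl <- lo - 1 + (half - prof[lo - 1]) / (prof[lo] - prof[lo - 1])
  xr <- hi + (prof[hi] - half) / (prof[hi] - prof[hi + 1])
  expect_lt(abs((xr - xl) - 8 / 3), 0.35)
  # symmetry under axis permutation
  expect_equal(sm[, 13, 13], sm[13, , 13])
  expect_equal(sm[, 13, 13], sm[13, 13, ])
})

test_that("GLM recovers noiseless coefficients exactly and matches the normal equations", {
  acq <- acq_params()
  sched <- build_schedule(1, acq)
  des <- make_design(sched, acq, NULL)
  x <- des$matrix
  set.seed(1)
  beta_true <- rnorm(ncol(x))
  y <- as.matrix(x %*% beta_true)
  ctr <- contrast_vector(des, "encoding")
  fit <- fit_glm(y, des, ctr)
  expect_equal(unname(fit$beta_contrast), sum(ctr * beta_true),
               tolerance = 1e-10)

  # small noisy instances vs an independent normal-equation solve
  for (rep in 1:5) {
    n <- 20; p <- 4
    xs <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    ys <- matrix(rnorm(n * 3), n)
    dsmall <- structure(list(matrix = xs,
                             contrast_names = paste0("c", 1:p)),
                        class = "design_matrix")
    fit2 <- fit_glm(ys, dsmall, c(0, 1, 0, 0))
    beta_ne <- solve(t(xs) %*% xs, t(xs) %*% ys)
    expect_lt(max(abs(fit2$beta_contrast - beta_ne[2, ])), 1e-8)
    # t statistic against the closed form
    rss <- colSums((ys - xs %*% beta_ne)^2)
    cvar <- solve(t(xs) %*% xs)[2, 2]
    t_ne <- beta_ne[2, ] / sqrt(rss / (n - p) * cvar)
    expect_lt(max(abs(fit2$t - t_ne)), 1e-8)
  }
})

test_that("a contrast orthogonal to the signal has null-centred t values", {
  set.seed(3)
  n <- 60
  xs <- cbind(1, rnorm(n), rnorm(n))
  dsmall <- structure(list(matrix = xs, contrast_names = c("a", "b", "c")),
                      class = "design_matrix")
  ys <- matrix(2 * xs[, 2], n, 200) + matrix(rnorm(n * 200), n)
  fit <- fit_glm(ys, dsmall, c(0, 0, 1))   # contrast on the silent column
  expect_lt(abs(mean(fit$t)), 3 / sqrt(200))
})

test_that("rank-deficient designs are reported with the collinear columns", {
  xs <- cbind(1, 1:10, 2 * (1:10))
  d <- structure(list(matrix = xs,
                      contrast_names = c("intercept", "ramp", "ramp2")),
                 class = "design_matrix")
  expect_error(fit_glm(matrix(rnorm(10)), d, c(0, 1, 0)), "ramp")
})

test_that("group t-test has n-1 dof and flags zero-variance voxels", {
  maps <- lapply(1:35, function(i) array(rnorm(27), c(3, 3, 3)))
  sm <- group_ttest(maps)
  expect_equal(sm$dof, 34L)
  expect_equal(sm$n_in_mask, 27L)
  expect_error(group_ttest(maps[1]), "2 subjects")

  # identical nonzero maps: flagged, excluded from mask
  same <- lapply(1:5, function(i) array(1, c(2, 2, 2)))
  expect_warning(sm0 <- group_ttest(same), "zero-variance")
  expect_equal(sm0$n_in_mask, 0L)
  expect_true(all(is.infinite(sm0$tmap)))

  # sign-symmetric maps cancel
  m <- array(rnorm(8), c(2, 2, 2))
  sym <- list(m, -m, m, -m)
  expect_equal(max(abs(group_ttest(sym)$tmap)), 0)
})

test_that("cluster thresholding applies the Bonferroni and extent rules", {
  dims <- c(12, 12, 8)
  n_sub <- 16
  blob <- function(size3) {
    arr <- array(0, dims)
    arr[3:(2 + size3[1]), 3:(2 + size3[2]), 3:(2 + size3[3])] <- 10
    arr
  }
  mk_statmap <- function(signal) {
    maps <- lapply(1:n_sub, function(i) signal + array(rnorm(prod(dims)),
                                                       dims))
    group_ttest(maps)
  }
  set.seed(4)
  # null map: no clusters
  expect_length(threshold_clusters(mk_statmap(array(0, dims))), 0L)
  # 30-voxel slab survives (k > 20) with the peak inside the slab
  cl <- threshold_clusters(mk_statmap(blob(c(5, 3, 2))))
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$size_k, 30L)
  expect_true(all(cl[[1]]$peak_voxel >= 3 & cl[[1]]$peak_voxel <= 7))
  # 12-voxel slab is removed by the extent filter
  expect_length(threshold_clusters(mk_statmap(blob(c(3, 2, 2)))), 0L)
  # raising alpha never shrinks the suprathreshold set
  sm <- mk_statmap(blob(c(5, 3, 2)))
  n_sup <- function(alpha) {
    thr <- qt(1 - alpha / sm$n_in_mask, sm$dof)
    sum(sm$tmap > thr)
  }
  counts <- vapply(c(0.001, 0.01, 0.05, 0.2), n_sup, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("connected components separate distinct blobs under 26-connectivity", {
  mask <- array(FALSE, c(8, 8, 4))
  mask[1:2, 1:2, 1:2] <- TRUE          # blob A: 8 voxels
  mask[5:8, 5:8, 3:4] <- TRUE          # blob B: 32 voxels
  mask[3, 3, 2] <- TRUE                # touches A diagonally (26-conn)
  comp26 <- reactivatr:::connected_components(mask, 26L)
  expect_length(comp26, 2L)
  expect_setequal(vapply(comp26, nrow, integer(1)), c(9L, 32L))
  comp6 <- reactivatr:::connected_components(mask, 6L)
  expect_length(comp6, 3L)
})

test_that("sphere ROI voxel counts match brute-force lattice enumeration", {
  grid <- c(24, 24, 16)
  expect_equal(nrow(sphere_roi(c(12, 12, 8), 0, 3, grid)$voxels), 1L)
  expect_equal(nrow(sphere_roi(c(12, 12, 8), 3, 3, grid)$voxels), 7L)
  # the study geometry: 15-mm radius at 3-mm voxels = 5-voxel radius
  expect_equal(nrow(sphere_roi(c(12, 12, 8), 15, 3, grid)$voxels),
               sphere_count_oracle(5))
  expect_equal(sphere_count_oracle(5), 515L)
  # other radii against the oracle
  for (r in c(1, 2, 4)) {
    expect_equal(nrow(sphere_roi(c(12, 12, 8), r * 3, 3, grid)$voxels),
                 sphere_count_oracle(r))
  }
  # symmetry about the centre
  roi <- sphere_roi(c(12, 12, 8), 15, 3, grid)
  offs <- sweep(roi$voxels, 2, c(12, 12, 8))
  expect_setequal(paste(offs[, 1], offs[, 2], offs[, 3]),
                  paste(-offs[, 1], -offs[, 2], -offs[, 3]))
  expect_setequal(paste(offs[, 1], offs[, 2], offs[, 3]),
                  paste(offs[, 2], offs[, 3], offs[, 1]))
  # boundary clipping warns; outside centre errors
  expect_warning(clipped <- sphere_roi(c(2, 12, 8), 15, 3, grid), "clipped")
  expect_lt(nrow(clipped$voxels), 515L)
  expect_error(sphere_roi(c(0, 5, 5), 15, 3, grid), "grid")
})

test_that("masks round-trip through NIfTI and reject degenerate inputs", {
  grid <- c(10, 10, 6)
  roi <- sphere_roi(c(5, 5, 3), 6, 3, grid)
  path <- tempfile(fileext = ".nii.gz")
  write_mask(roi, grid, path)
  back <- load_mask(path, grid)
  expect_equal(back$voxels, roi$voxels)
  expect_equal(back$source, "loaded-mask")
  expect_error(load_mask(path, c(8, 8, 8)), "does not match")

  zero <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, grid)), zero)
  expect_error(load_mask(zero), "empty")
  nb <- tempfile(fileext = ".nii.gz")
  arr <- array(0, grid); arr[2:3, 2, 2] <- 2.5
  RNifti::writeNifti(RNifti::asNifti(arr), nb, datatype = "double")
  expect_warning(nbroi <- load_mask(nb), "non-binary")
  expect_equal(nrow(nbroi$voxels), 2L)
})
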
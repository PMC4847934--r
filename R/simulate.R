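# Forward BOLD model: baseline + HRF-convolved planted signals + drift + noise.
# The cluster signal carries the univariate encoding activation for the
# localizer; the pattern sphere carries the multivariate signal for MVPA.

# Per-voxel condition amplitudes for an arbitrary voxel set (n x 3 matrix).
# Returns list(enc, vd): amplitude of the encoding-locked and
# distractor-vocabulary-locked responses at each voxel.
signal_amplitudes <- function(config, voxels, pattern_vector) {
  dims <- config$acquisition$grid_dims
  n <- nrow(voxels)
  lin <- voxels[, 1] + (voxels[, 2] - 1L) * dims[1] +
    (voxels[, 3] - 1L) * dims[1] * dims[2]
  enc <- numeric(n)
  for (cl in config$planted_clusters) {
    d2 <- (voxels[, 1] - cl$center[1])^2 + (voxels[, 2] - cl$center[2])^2 +
      (voxels[, 3] - cl$center[3])^2
    enc[d2 <= cl$radius^2 + 1e-9] <- config$beta_enc * cl$amplitude
  }
  vd <- numeric(n)
  roi <- pattern_roi(config)
  plin <- roi_linear_index(roi, dims)
  hit <- match(lin, plin)
  has <- !is.na(hit)
  vd[has] <- config$a_voc * pattern_vector[hit[has]]
  enc[has] <- enc[has] + config$rho * config$a_voc * pattern_vector[hit[has]]
  list(enc = enc, vd = vd)
}

#' Sphere carrying the planted multivariate pattern
#'
#' @param config A [sim_config()].
#' @return The `roi_mask` over which the pattern vector is defined.
#' @export
pattern_roi <- function(config) {
  sphere_roi(config$pattern_center, config$pattern_radius_mm,
             config$acquisition$voxel_mm, config$acquisition$grid_dims)
}

# Draw a zero-spatial-mean, unit-norm pattern vector over n voxels.
draw_pattern_vector <- function(n) {
  p <- stats::rnorm(n)
  p <- p - mean(p)
  p / sqrt(sum(p^2))
}

resolve_pattern_vector <- function(config) {
  n <- nrow(pattern_roi(config)$voxels)
  if (is.null(config$pattern_vector)) return(draw_pattern_vector(n))
  p <- config$pattern_vector
  if (length(p) != n)
    stop(sprintf("pattern_vector has length %d but the pattern sphere has %d voxels",
                 length(p), n))
  nrm <- sqrt(sum(p^2))
  if (abs(nrm - 1) > 1e-6) stop("pattern_vector must have unit Euclidean norm")
  p
}

# Gaussian noise, optionally AR(1)-filtered along time, as a T x V matrix.
# Innovations are scaled by sqrt(1 - phi^2) so the stationary marginal SD is
# noise_sd regardless of phi.
noise_matrix <- function(n_t, n_v, noise_sd, ar1_phi) {
  if (noise_sd == 0) return(matrix(0, n_t, n_v))
  if (ar1_phi == 0) return(matrix(stats::rnorm(n_t * n_v, sd = noise_sd),
                                  n_t, n_v))
  innov_sd <- noise_sd * sqrt(1 - ar1_phi^2)
  e <- matrix(stats::rnorm(n_t * n_v, sd = innov_sd), n_t, n_v)
  x <- e
  x[1, ] <- stats::rnorm(n_v, sd = noise_sd)   # stationary start
  for (t in 2:n_t) x[t, ] <- ar1_phi * x[t - 1, ] + e[t, ]
  x
}

# Time series for a given voxel set: T x V matrix of BOLD values.
simulate_timeseries <- function(config, schedule, voxels, pattern_vector) {
  acq <- config$acquisition
  n_t <- acq$n_volumes
  enc_ev <- schedule[schedule$trial_type == "encoding", ]
  vd_ev <- schedule[schedule$trial_type == "vocab_distractor", ]
  x_enc <- if (nrow(enc_ev)) hrf_regressor(enc_ev$onset_s, enc_ev$duration_s,
                                           acq) else numeric(n_t)
  x_vd <- if (nrow(vd_ev)) hrf_regressor(vd_ev$onset_s, vd_ev$duration_s,
                                         acq) else numeric(n_t)
  amp <- signal_amplitudes(config, voxels, pattern_vector)
  sig <- config$baseline +
    outer(x_enc, amp$enc) + outer(x_vd, amp$vd) +
    config$drift_slope * (seq_len(n_t) - 1)
  sig + noise_matrix(n_t, nrow(voxels), config$noise_sd, config$ar1_phi)
}

# Six motion regressors: white noise smoothed with a moving-average window.
simulate_motion <- function(n_t, scale = 0.2, width = 11L) {
  kern <- rep(1 / width, width)
  m <- sapply(seq_len(6), function(i) {
    x <- stats::filter(stats::rnorm(n_t + width, sd = scale), kern,
                       sides = 2)
    as.numeric(x[seq_len(n_t) + (width %/% 2)])
  })
  colnames(m) <- c("trans_x", "trans_y", "trans_z",
                   "rot_x", "rot_y", "rot_z")
  m
}

#' Simulate one synthetic subject's functional run
#'
#' Generates the 4D BOLD volume, the event table, motion regressors,
#' behavioural responses, and a record of the planted ground truth, for the
#' forward model documented in [sim_config()].
#'
#' @param config A [sim_config()]. Out-of-grid planted voxels are a
#'   configuration error.
#' @param schedule A schedule from [build_schedule()]; defaults to the order
#'   given by `config$order_id` (order 1 if `NA`).
#' @param reseed If `TRUE` (default) the RNG is seeded from `config$seed`, so
#'   identical configurations reproduce bit-identical subjects. Internal
#'   cohort calls pass `FALSE` and draw from the running RNG stream.
#' @return An object of class `synthetic_subject`: list with `image`
#'   (4D array x,y,z,t), `events`, `motion`, `behavior`, and `truth` (the
#'   configuration actually used, including the realised pattern vector).
#' @export
simulate_bold <- function(config, schedule = NULL, reseed = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (reseed) set.seed(config$seed)
  if (is.null(schedule)) {
    ord <- if (is.na(config$order_id)) 1 else config$order_id
    schedule <- build_schedule(ord, config$acquisition)
  }
  acq <- config$acquisition
  dims <- acq$grid_dims
  pattern_vector <- resolve_pattern_vector(config)
  all_vox <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                                   z = seq_len(dims[3])))
  mat <- simulate_timeseries(config, schedule, all_vox, pattern_vector)
  img <- array(t(mat), dim = c(dims, acq$n_volumes))
  motion <- simulate_motion(acq$n_volumes)
  behavior <- simulate_behavior(config, reseed = FALSE)
  truth <- config
  truth$pattern_vector <- pattern_vector
  structure(list(image = img, events = schedule, motion = motion,
                 behavior = behavior, truth = truth),
            class = "synthetic_subject")
}

#' Simulate only an ROI's voxel time series
#'
#' Fast path for replicate studies: generates the `volumes x voxels` matrix
#' for the given ROI under exactly the same generative law as extracting
#' those voxels from [simulate_bold()] output (the noise is voxelwise
#' independent, so restricting the simulation to the ROI leaves the joint
#' distribution of the ROI time series unchanged).
#'
#' @param config A [sim_config()].
#' @param schedule A schedule from [build_schedule()].
#' @param roi A `roi_mask`; defaults to the planted pattern sphere.
#' @param reseed As in [simulate_bold()].
#' @return List with `mat` (`n_volumes x n_voxels`), `events`, `behavior`,
#'   and `pattern_vector`.
#' @export
simulate_roi_session <- function(config, schedule = NULL,
                                 roi = pattern_roi(config), reseed = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (reseed) set.seed(config$seed)
  if (is.null(schedule)) {
    ord <- if (is.na(config$order_id)) 1 else config$order_id
    schedule <- build_schedule(ord, config$acquisition)
  }
  pattern_vector <- resolve_pattern_vector(config)
  mat <- simulate_timeseries(config, schedule, roi$voxels, pattern_vector)
  behavior <- simulate_behavior(config, reseed = FALSE)
  list(mat = mat, events = schedule, behavior = behavior,
       pattern_vector = pattern_vector)
}

#' Simulate one subject's behavioural record
#'
#' Probe scores are Binomial(16, p) per probe period; vocabulary scores are
#' Binomial(15, p) per block; mean reaction times are Gaussian with the
#' configured between-subject mean and SD, truncated below at 0.5 s.
#'
#' @param config A [sim_config()].
#' @param reseed If `TRUE`, seed the RNG from `config$seed` first.
#' @return One-row data.frame with probe, vocabulary and reaction-time
#'   fields.
#' @export
simulate_behavior <- function(config, reseed = TRUE) {
  if (reseed) set.seed(config$seed)
  rt <- function(ms) max(0.5, stats::rnorm(1, ms[1], ms[2]))
  data.frame(
    probe_correct_distractor_1 = stats::rbinom(1, 16, config$p_distractor),
    probe_correct_distractor_2 = stats::rbinom(1, 16, config$p_distractor),
    probe_correct_immediate = stats::rbinom(1, 16, config$p_immediate),
    vocab_correct_distractor_1 = stats::rbinom(1, 15, config$p_vocab),
    vocab_correct_distractor_2 = stats::rbinom(1, 15, config$p_vocab),
    vocab_correct_independent_1 = stats::rbinom(1, 15, config$p_vocab),
    vocab_correct_independent_2 = stats::rbinom(1, 15, config$p_vocab),
    rt_mean_distractor_s = rt(config$rt_distractor_s),
    rt_mean_independent_s = rt(config$rt_independent_s))
}

#' Simulate a cohort of subjects
#'
#' Seeds the RNG once from `config$seed` and draws subjects sequentially.
#' When `config$order_id` is `NA`, counterbalance orders alternate 1, 2, 1,
#' 2, ... across subjects.
#'
#' @param config A [sim_config()].
#' @param roi_only If `TRUE`, generate only the pattern-sphere time series
#'   per subject (fast path, [simulate_roi_session()]); otherwise full 4D
#'   volumes ([simulate_bold()]).
#' @return List of subjects (one per `config$n_subjects`).
#' @export
simulate_cohort <- function(config, roi_only = FALSE) {
  set.seed(config$seed)
  lapply(seq_len(config$n_subjects), function(i) {
    ord <- if (is.na(config$order_id)) ((i - 1L) %% 2L) + 1L else
      config$order_id
    sched <- build_schedule(ord, config$acquisition)
    if (roi_only) simulate_roi_session(config, sched, reseed = FALSE)
    else simulate_bold(config, sched, reseed = FALSE)
  })
}
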
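#' Simulation configuration
#'
#' Collects every parameter of the synthetic-session generator: acquisition
#' geometry, counterbalance order, univariate encoding activation planted in
#' designated clusters, the multivariate pattern planted in a voxel set, the
#' reactivation strength `rho`, the noise model, and behavioural response
#' probabilities.
#'
#' The generative model for voxel `v` at volume time `t` is
#' \deqn{y(v,t) = baseline + \beta_{enc} 1_{cluster}(v) X_{enc}(t) +
#'   a_{voc} p_v X_{vd}(t) + \rho\, a_{voc} p_v X_{enc}(t) +
#'   drift \cdot (vol - 1) + \epsilon(v,t)}
#' where `X_enc` and `X_vd` are the HRF-convolved boxcars of the encoding and
#' distractor-vocabulary epochs (plateau-normalised to 1), `p` is the
#' unit-norm pattern vector over `pattern_voxels`, and `eps` is Gaussian noise
#' with standard deviation `noise_sd`, optionally AR(1)-filtered with
#' coefficient `ar1_phi` (innovations scaled so the stationary marginal SD
#' stays `noise_sd`). With `rho = 0` encoding volumes carry no planted
#' pattern.
#'
#' @param acquisition An [acq_params()] object.
#' @param order_id Counterbalance order 1 or 2, or `NA` to alternate across
#'   subjects within a cohort.
#' @param baseline Baseline signal level (arbitrary units).
#' @param beta_enc Univariate encoding amplitude planted in the clusters.
#' @param planted_clusters List of clusters, each `list(center =, radius =,
#'   amplitude =)` with `center` a 3-vector of 1-based voxel indices,
#'   `radius` in voxels, and `amplitude` a multiplier on `beta_enc`.
#' @param pattern_center,pattern_radius_mm Centre (1-based voxel indices) and
#'   radius of the sphere carrying the multivariate pattern. The default
#'   centre is distinct from the planted univariate clusters: the pattern is
#'   zero-mean across voxels, so the region carries distributed information
#'   without univariate activation (and, conversely, univariate activation
#'   inside a decoding ROI acts as a per-subject symmetric confound on the
#'   cross-decoding test - see the vignette).
#' @param pattern_vector Optional unit-norm vector over the pattern voxels;
#'   `NULL` draws a fresh zero-spatial-mean unit-norm vector per subject.
#' @param a_voc Pattern amplitude during distractor-condition vocabulary
#'   blocks (absent during independent vocabulary blocks).
#' @param rho Reactivation strength in `[0, 1]`: the pattern amplitude during
#'   encoding blocks is `rho * a_voc`.
#' @param noise_sd Gaussian noise standard deviation.
#' @param ar1_phi AR(1) coefficient in `[0, 1)`; 0 gives white noise.
#' @param drift_slope Linear drift in arbitrary units per volume.
#' @param seed RNG seed for [simulate_cohort()].
#' @param n_subjects Cohort size.
#' @param p_distractor,p_immediate Per-trial probe accuracy in the
#'   distractor-task and immediate-recall conditions (16 probe trials each).
#' @param p_vocab Per-trial vocabulary accuracy (15 trials per block).
#' @param rt_distractor_s,rt_independent_s Mean reaction time (s) and
#'   between-subject SD, as `c(mean, sd)`, for the two vocabulary task types.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(acquisition = acq_params(),
                       order_id = NA,
                       baseline = 100,
                       beta_enc = 5,
                       planted_clusters = default_clusters(acquisition),
                       pattern_center = as.integer(
                         round(acquisition$grid_dims / 2)),
                       pattern_radius_mm = 15,
                       pattern_vector = NULL,
                       a_voc = 1,
                       rho = 0.6,
                       noise_sd = 1,
                       ar1_phi = 0,
                       drift_slope = 0,
                       seed = 1L,
                       n_subjects = 35L,
                       p_distractor = 8.73 / 16,
                       p_immediate = 7.94 / 16,
                       p_vocab = 7.41 / 15,
                       rt_distractor_s = c(4.25, 0.68),
                       rt_independent_s = c(4.16, 0.57)) {
  stopifnot(rho >= 0, rho <= 1, noise_sd >= 0, ar1_phi >= 0, ar1_phi < 1,
            a_voc >= 0, n_subjects >= 1)
  probs <- c(p_distractor, p_immediate, p_vocab)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  dims <- acquisition$grid_dims
  for (cl in planted_clusters) {
    if (any(cl$center < 1) || any(cl$center > dims))
      stop("planted cluster centre outside the grid")
    if (any(cl$center - ceiling(cl$radius) < 1) ||
        any(cl$center + ceiling(cl$radius) > dims))
      stop("planted cluster extends outside the grid")
  }
  if (any(pattern_center < 1) || any(pattern_center > dims))
    stop("pattern_center outside the grid")
  cfg <- list(acquisition = acquisition, order_id = order_id,
              baseline = baseline, beta_enc = beta_enc,
              planted_clusters = planted_clusters,
              pattern_center = as.integer(pattern_center),
              pattern_radius_mm = pattern_radius_mm,
              pattern_vector = pattern_vector, a_voc = a_voc, rho = rho,
              noise_sd = noise_sd, ar1_phi = ar1_phi,
              drift_slope = drift_slope, seed = as.integer(seed),
              n_subjects = as.integer(n_subjects),
              p_distractor = p_distractor, p_immediate = p_immediate,
              p_vocab = p_vocab, rt_distractor_s = rt_distractor_s,
              rt_independent_s = rt_independent_s)
  structure(cfg, class = "sim_config")
}

#' Default planted activation clusters
#'
#' Four well-separated spherical clusters of radius 2 voxels, emulating the
#' four encoding-related regions a group localizer is expected to recover.
#' None of them overlaps the default pattern sphere, which carries the
#' multivariate signal without univariate activation.
#'
#' Centres sit at the quarter points of the x/y axes and mid-grid in z
#' (6,6,8 / 18,6,8 / 6,18,8 / 18,18,8 on the default 24 x 24 x 16 grid),
#' clamped so each sphere fits inside the grid.
#'
#' @param acquisition An [acq_params()] object.
#' @return List of cluster specifications.
#' @export
default_clusters <- function(acquisition = acq_params()) {
  d <- acquisition$grid_dims
  radius <- 2
  clamp <- function(v, dim) pmin(pmax(v, radius + 1L), dim - radius)
  lo <- clamp(as.integer(round(d[1:2] * 0.25)), d[1:2])
  hi <- clamp(as.integer(round(d[1:2] * 0.75)), d[1:2])
  z <- clamp(as.integer(round(d[3] / 2)), d[3])
  centers <- list(c(lo[1], lo[2], z), c(hi[1], lo[2], z),
                  c(lo[1], hi[2], z), c(hi[1], hi[2], z))
  lapply(centers, function(ctr) list(center = ctr, radius = radius,
                                     amplitude = 1))
}
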
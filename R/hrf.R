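#' Canonical double-gamma hemodynamic response function
#'
#' The BOLD impulse response modelled as the difference of two gamma
#' densities, `h(t) = g(t; 6, 1) - g(t; 16, 1) / 6` (shapes 6 and 16, unit
#' scales, undershoot ratio 1/6). The response peaks near 5 s and undershoots
#' between roughly 12 and 24 s.
#'
#' @param t_grid Non-negative times in seconds.
#' @return `h(t)` evaluated on `t_grid`.
#' @examples
#' canonical_hrf(0)                       # 0
#' tg <- seq(0, 32, by = 0.01)
#' tg[which.max(canonical_hrf(tg))]       # ~5 s peak
#' @export
canonical_hrf <- function(t_grid) {
  if (any(t_grid < 0)) stop("t_grid must be non-negative")
  stats::dgamma(t_grid, shape = 6, rate = 1) -
    stats::dgamma(t_grid, shape = 16, rate = 1) / 6
}

#' Convolve block epochs with the canonical HRF
#'
#' Builds the expected BOLD time course for a set of epochs: a boxcar at high
#' temporal resolution is convolved with [canonical_hrf()] and sampled at the
#' volume acquisition times. The result is normalised by the integral of the
#' HRF so that a sustained epoch plateaus at the boxcar amplitude, making
#' planted amplitudes directly interpretable in signal units.
#'
#' @param onsets,durations Epoch onsets and durations in seconds.
#' @param acquisition An [acq_params()] object.
#' @param dt Oversampling resolution in seconds.
#' @return Numeric vector of length `n_volumes`.
#' @keywords internal
hrf_regressor <- function(onsets, durations, acquisition, dt = 0.1) {
  stopifnot(length(onsets) == length(durations))
  key <- paste(c(onsets, durations, acquisition$tr_s, acquisition$n_volumes,
                 dt), collapse = ",")
  hit <- .hrf_cache[[key]]
  if (!is.null(hit)) return(hit)
  run_len <- run_duration_s(acquisition)
  n_hi <- ceiling(run_len / dt) + 1L
  t_hi <- (seq_len(n_hi) - 1) * dt
  box <- numeric(n_hi)
  for (i in seq_along(onsets)) {
    on <- t_hi >= onsets[i] & t_hi < onsets[i] + durations[i]
    box[on] <- box[on] + 1
  }
  kern <- canonical_hrf(seq(0, 32, by = dt))
  kern <- kern / sum(kern)                 # sustained plateau == amplitude 1
  conv <- stats::convolve(box, rev(kern), type = "open")[seq_len(n_hi)]
  out <- stats::approx(t_hi, conv, xout = volume_times(acquisition),
                       rule = 2)$y
  .hrf_cache[[key]] <- out
  out
}

# memoisation for repeated schedules (cohort simulation, replicate studies)
.hrf_cache <- new.env(parent = emptyenv())
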
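#' Acquisition parameters for a functional run
#'
#' Describes the scanner geometry and timing of one simulated functional run:
#' the repetition time (TR), the number of whole-brain volumes, the isotropic
#' voxel size, and the grid dimensions. Defaults reproduce a 528-volume,
#' 1320-second run at TR 2.5 s with 3-mm isotropic voxels on a desk-scale
#' 24 x 24 x 16 grid (configurable up to full EPI matrix sizes such as
#' 64 x 64 x 42).
#'
#' @param tr_s Seconds per volume (TR). Must be positive.
#' @param n_volumes Number of volumes in the run.
#' @param voxel_mm Isotropic voxel edge length in millimetres.
#' @param grid_dims Integer vector of length 3: voxels along x, y, z.
#' @return An object of class `acq_params`.
#' @examples
#' acq <- acq_params()
#' acq$n_volumes * acq$tr_s  # nominal run duration in seconds
#' @export
acq_params <- function(tr_s = 2.5, n_volumes = 528L, voxel_mm = 3,
                       grid_dims = c(24L, 24L, 16L)) {
  stopifnot(is.numeric(tr_s), length(tr_s) == 1L, tr_s > 0)
  stopifnot(is.numeric(n_volumes), length(n_volumes) == 1L, n_volumes >= 1)
  stopifnot(is.numeric(voxel_mm), length(voxel_mm) == 1L, voxel_mm > 0)
  if (length(grid_dims) != 3L || any(grid_dims < 1))
    stop("grid_dims must be 3 integers >= 1")
  structure(
    list(tr_s = as.numeric(tr_s), n_volumes = as.integer(n_volumes),
         voxel_mm = as.numeric(voxel_mm), grid_dims = as.integer(grid_dims)),
    class = "acq_params")
}

#' Volume acquisition start times
#'
#' @param acquisition An [acq_params()] object.
#' @return Numeric vector of length `n_volumes`: the acquisition start time of
#'   each volume in seconds from run onset (volume v starts at `(v - 1) * TR`).
#' @export
volume_times <- function(acquisition) {
  (seq_len(acquisition$n_volumes) - 1) * acquisition$tr_s
}

run_duration_s <- function(acquisition) {
  acquisition$n_volumes * acquisition$tr_s
}
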
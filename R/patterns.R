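#' Extract per-block ROI activity patterns
#'
#' For each event whose `trial_type` is in `labels_wanted`, collects the raw
#' (unsmoothed, non-deconvolved) ROI voxel values of the volumes whose
#' acquisition start time falls in `[onset + lag_exclude_s, onset +
#' duration)`. The default 10-s exclusion discards the first 4 volumes of a
#' 48-volume (120-s, TR 2.5 s) block to account for hemodynamic lag, leaving
#' 44 volumes per block.
#'
#' @param image Either a 4D array (x, y, z, t) or an `n_volumes x n_voxels`
#'   matrix already restricted to the ROI (in which case `roi` is only used
#'   for its name).
#' @param events A `session_schedule` / events data.frame.
#' @param roi A `roi_mask`; must be non-empty.
#' @param labels_wanted Trial types to extract (e.g.
#'   `c("vocab_distractor", "vocab_independent")`).
#' @param lag_exclude_s Seconds excluded from each block onset (>= 0).
#' @param acquisition An [acq_params()] object (for volume timing).
#' @return List of `pattern_block` objects: each a list with `matrix`
#'   (retained volumes x ROI voxels), `label`, `block_id`, `onset_s`, and
#'   `volume_index` (1-based volume position within the block, counted from
#'   the block onset).
#' @export
extract_block_patterns <- function(image, events, roi, labels_wanted,
                                   lag_exclude_s = 10,
                                   acquisition = acq_params()) {
  if (lag_exclude_s < 0) stop("lag_exclude_s must be non-negative")
  if (is.null(roi$voxels) || nrow(roi$voxels) == 0L) stop("empty ROI")
  if (is.array(image) && length(dim(image)) == 4L) {
    dims <- dim(image)[1:3]
    flat <- t(matrix(image, prod(dims), dim(image)[4]))
    mat <- flat[, roi_linear_index(roi, dims), drop = FALSE]
  } else {
    mat <- as.matrix(image)
    if (ncol(mat) != nrow(roi$voxels))
      stop("matrix columns do not match the ROI voxel count")
  }
  times <- volume_times(acquisition)
  if (nrow(mat) != length(times))
    stop(sprintf("image has %d volumes but acquisition specifies %d",
                 nrow(mat), length(times)))
  sel <- events[events$trial_type %in% labels_wanted, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(sel))) {
    onset <- sel$onset_s[i]; dur <- sel$duration_s[i]
    keep <- which(times >= onset + lag_exclude_s & times < onset + dur)
    if (!length(keep))
      stop(sprintf("block %s (%s) retains no volumes after %g-s lag exclusion",
                   sel$block_id[i], sel$trial_type[i], lag_exclude_s))
    out[[length(out) + 1L]] <- structure(
      list(matrix = mat[keep, , drop = FALSE],
           label = sel$trial_type[i],
           block_id = sel$block_id[i],
           onset_s = onset,
           volume_index = as.integer(floor((times[keep] - onset) /
                                             acquisition$tr_s)) + 1L),
      class = "pattern_block")
  }
  out
}

#' Double mean-centering of a pattern matrix
#'
#' Centers a `volumes x voxels` matrix around its means both within voxels
#' (subtract each column's mean across volumes) and across voxels (then
#' subtract each row's mean across columns). After this sequence all row and
#' column means are zero, and the operation is idempotent.
#'
#' @param m Numeric matrix with at least one row and column.
#' @return Centered matrix of the same dimensions.
#' @examples
#' double_center(matrix(c(1, 3, 2, 5), 2, 2))
#' @export
double_center <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty matrix")
  m <- sweep(m, 2, colMeans(m))
  sweep(m, 1, rowMeans(m))
}

#' Center patterns across voxels only
#'
#' Subtracts each volume's spatial mean, removing spatially uniform
#' components (baseline level, scanner drift, global activation shifts)
#' while leaving each volume's within-pattern structure - including any
#' sustained task-wide component of the pattern - intact. Used for
#' cross-decoded test sets, where within-voxel (temporal) centering would
#' remove the sustained signal under test (see the package vignette).
#'
#' @param m Numeric matrix (volumes x voxels).
#' @return Row-centered matrix.
#' @export
center_across_voxels <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty matrix")
  sweep(m, 1, rowMeans(m))
}

#' Assemble block-wise cross-validation folds
#'
#' With exactly two blocks per class, training uses one block of each class
#' and testing the remaining blocks; all 2 x 2 train-block combinations are
#' emitted. With the study geometry (44 retained volumes per block) each
#' fold has 44 x 2 = 88 training and 88 testing patterns.
#'
#' @param blocks List of `pattern_block` objects: exactly 2 blocks per class
#'   and equal row counts throughout.
#' @return List of folds, each `list(train, test)` where both elements are
#'   lists of `pattern_block`s (one per class in `train`, the held-out
#'   blocks in `test`).
#' @export
assemble_folds <- function(blocks) {
  labels <- vapply(blocks, `[[`, character(1), "label")
  classes <- sort(unique(labels))
  if (length(classes) != 2L)
    stop(sprintf("expected exactly 2 classes, got: %s",
                 paste(classes, collapse = ", ")))
  rows <- vapply(blocks, function(b) nrow(b$matrix), integer(1))
  if (length(unique(rows)) != 1L)
    stop(sprintf("blocks have unequal row counts: %s",
                 paste(rows, collapse = ", ")))
  by_class <- split(seq_along(blocks), labels)
  if (any(vapply(by_class, length, integer(1)) != 2L))
    stop("expected exactly 2 blocks per class")
  folds <- list()
  for (i in 1:2) for (j in 1:2) {
    tr <- c(by_class[[1]][i], by_class[[2]][j])
    te <- setdiff(seq_along(blocks), tr)
    folds[[length(folds) + 1L]] <- list(train = blocks[tr],
                                        test = blocks[te])
  }
  folds
}

# rbind the matrices of a list of pattern blocks; returns list(x, labels,
# block_id, volume_index) with one entry per row.
stack_blocks <- function(blocks) {
  x <- do.call(rbind, lapply(blocks, `[[`, "matrix"))
  labels <- unlist(lapply(blocks, function(b) rep(b$label, nrow(b$matrix))))
  bid <- unlist(lapply(blocks, function(b) rep(b$block_id, nrow(b$matrix))))
  vidx <- unlist(lapply(blocks, `[[`, "volume_index"))
  list(x = x, labels = labels, block_id = bid, volume_index = vidx)
}
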
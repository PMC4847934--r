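#' Write a synthetic subject's session to disk
#'
#' Emits one 4D NIfTI-1 volume (`bold.nii.gz`, isotropic affine, float64 so
#' the round trip is lossless), a BIDS-style events TSV (`events.tsv` with
#' columns onset, duration, trial_type, block_id, condition_tag), a
#' motion-regressor TSV, a behaviour TSV, and a ground-truth JSON.
#'
#' @param subject A `synthetic_subject` from [simulate_bold()].
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of the written file paths, invisibly.
#' @export
write_session <- function(subject, out_dir) {
  stopifnot(inherits(subject, "synthetic_subject"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create '%s'", out_dir))
  acq <- subject$truth$acquisition

  nii_path <- file.path(out_dir, "bold.nii.gz")
  img <- RNifti::asNifti(subject$image)
  RNifti::pixdim(img) <- c(rep(acq$voxel_mm, 3), acq$tr_s)
  RNifti::writeNifti(img, nii_path, datatype = "double")

  ev <- subject$events
  ev_out <- data.frame(onset = ev$onset_s, duration = ev$duration_s,
                       trial_type = ev$trial_type, block_id = ev$block_id,
                       condition_tag = ev$condition_tag)
  ev_path <- file.path(out_dir, "events.tsv")
  write_tsv(ev_out, ev_path)

  mo_path <- file.path(out_dir, "motion.tsv")
  write_tsv(as.data.frame(subject$motion), mo_path)

  be_path <- file.path(out_dir, "behavior.tsv")
  write_tsv(subject$behavior, be_path)

  tr_path <- file.path(out_dir, "truth.json")
  truth <- subject$truth
  truth$acquisition <- unclass(truth$acquisition)
  jsonlite::write_json(unclass(truth), tr_path, auto_unbox = TRUE,
                       digits = NA, null = "null")

  invisible(c(bold = nii_path, events = ev_path, motion = mo_path,
              behavior = be_path, truth = tr_path))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("'%s' is missing required column(s): %s", path,
                 paste(missing, collapse = ", ")))
}

#' Read an events table
#'
#' @param path Path to a tab-separated events file with columns `onset`,
#'   `duration`, `trial_type` (and optionally `block_id`, `condition_tag`).
#' @return A `session_schedule` data.frame.
#' @export
read_events <- function(path) {
  df <- read_tsv(path)
  require_columns(df, c("onset", "duration", "trial_type"), path)
  out <- data.frame(onset_s = as.numeric(df$onset),
                    duration_s = as.numeric(df$duration),
                    trial_type = as.character(df$trial_type))
  out$block_id <- if ("block_id" %in% names(df)) as.integer(df$block_id) else
    seq_len(nrow(df))
  out$condition_tag <- if ("condition_tag" %in% names(df))
    as.character(df$condition_tag) else NA_character_
  if (any(!is.finite(out$onset_s)) || any(!is.finite(out$duration_s)))
    stop(sprintf("'%s' contains non-numeric onset/duration values", path))
  if (any(out$duration_s <= 0) || any(out$onset_s < 0))
    stop(sprintf("'%s': onsets must be >= 0 and durations > 0", path))
  out <- out[order(out$onset_s), ]
  rownames(out) <- NULL
  class(out) <- c("session_schedule", "data.frame")
  out
}

#' Read a 4D functional image
#'
#' @param path Path to a NIfTI-1 file; must be 4D with finite values.
#' @return A 4D array (x, y, z, t).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 4L)
    stop(sprintf("'%s': expected a 4D image, got %d dimension(s)", path,
                 length(dim(arr))))
  if (!all(is.finite(arr)))
    stop(sprintf("'%s' contains non-finite voxel values", path))
  arr
}

#' Read a behavioural response table
#'
#' @param path Path to a tab-separated behaviour file (one row per subject or
#'   a single-subject row) with the probe, vocabulary and reaction-time
#'   columns written by [write_session()].
#' @return A data.frame.
#' @export
read_behavior <- function(path) {
  df <- read_tsv(path)
  require_columns(df, c("probe_correct_distractor_1",
                        "probe_correct_distractor_2",
                        "probe_correct_immediate",
                        "vocab_correct_distractor_1",
                        "vocab_correct_distractor_2",
                        "vocab_correct_independent_1",
                        "vocab_correct_independent_2",
                        "rt_mean_distractor_s", "rt_mean_independent_s"),
                  path)
  df
}

#' Read a motion-regressor table
#'
#' @param path Path to a 6-column tab-separated motion file.
#' @return A numeric matrix with 6 columns.
#' @export
read_motion <- function(path) {
  df <- read_tsv(path)
  if (ncol(df) != 6L)
    stop(sprintf("'%s': expected 6 motion columns, got %d", path, ncol(df)))
  as.matrix(df)
}
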
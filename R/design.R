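MODELED_TRIAL_TYPES <- c("encoding", "vocab_distractor", "vocab_independent",
                         "probe", "instruction", "bonus", "trivia")

#' Build a first-level GLM design matrix
#'
#' One column per task condition present in the events (each condition's
#' epochs form a boxcar convolved with the canonical HRF and sampled at
#' volume acquisition times), plus six motion regressors and an intercept.
#' Fixation is not modelled and serves as the implicit baseline. Events with
#' an unknown `trial_type` are excluded with a warning.
#'
#' @param events A `session_schedule` / events data.frame.
#' @param acquisition An [acq_params()] object.
#' @param motion `n_volumes x 6` matrix of motion regressors, or `NULL` to
#'   omit motion columns.
#' @return An object of class `design_matrix`: list with `matrix`
#'   (`n_volumes x n_regressors`), `conditions` (modelled condition names)
#'   and `contrast_names` (all column labels).
#' @export
make_design <- function(events, acquisition = acq_params(), motion = NULL) {
  n_t <- acquisition$n_volumes
  known <- events$trial_type %in% c(MODELED_TRIAL_TYPES, "fixation")
  if (!all(known)) {
    warning(sprintf("excluding events with unknown trial_type: %s",
                    paste(unique(events$trial_type[!known]), collapse = ", ")))
    events <- events[known, , drop = FALSE]
  }
  if (any(events$onset_s + events$duration_s >
          run_duration_s(acquisition) + 1e-9))
    stop("events extend beyond the run")
  conds <- intersect(MODELED_TRIAL_TYPES, unique(events$trial_type))
  cols <- lapply(conds, function(cond) {
    ev <- events[events$trial_type == cond, ]
    hrf_regressor(ev$onset_s, ev$duration_s, acquisition)
  })
  x <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(0), nrow = n_t, ncol = 0)
  colnames(x) <- conds
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n_t)
      stop(sprintf("motion has %d rows but the run has %d volumes",
                   nrow(motion), n_t))
    colnames(motion) <- paste0("motion_", seq_len(ncol(motion)))
    x <- cbind(x, motion)
  }
  x <- cbind(x, intercept = rep(1, n_t))
  structure(list(matrix = x, conditions = conds,
                 contrast_names = colnames(x)),
            class = "design_matrix")
}

#' Contrast vector selecting one or more conditions
#'
#' @param design A `design_matrix`.
#' @param conditions Condition column names given weight 1 (all other
#'   columns 0).
#' @return Numeric contrast vector aligned with the design columns.
#' @export
contrast_vector <- function(design, conditions = "encoding") {
  missing <- setdiff(conditions, design$contrast_names)
  if (length(missing))
    stop(sprintf("contrast names not in the design: %s",
                 paste(missing, collapse = ", ")))
  as.numeric(design$contrast_names %in% conditions)
}
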
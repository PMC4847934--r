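#' Build the block schedule for one counterbalance order
#'
#' Reconstructs the within-run task sequence of the paired-associates session.
#' The run contains two distractor-task conditions, two independent vocabulary
#' tasks, one immediate-recall condition and one trivia block, in one of two
#' counterbalanced orders:
#'
#' * order 1: distractor, independent-vocab, immediate-recall, trivia,
#'   independent-vocab, distractor
#' * order 2: independent-vocab, distractor, immediate-recall, trivia,
#'   distractor, independent-vocab
#'
#' Each distractor-task condition expands to instruction (5 s), encoding
#' (120 s), instruction (5 s), distractor vocabulary (120 s), instruction
#' (5 s), probe (80 s), bonus screen (5 s). The immediate-recall condition is
#' the same without the vocabulary segment. An independent vocabulary task is
#' instruction (5 s) plus vocabulary (120 s); trivia is a single 60-s block.
#' A 15-s fixation precedes every task, and the run ends with a trailing
#' fixation padded so that the schedule occupies exactly
#' `n_volumes * tr_s` seconds (the itemised segments sum to slightly less
#' than the nominal run length, and the remainder is assigned to the final
#' fixation).
#'
#' All blocks are half-open intervals `[onset, onset + duration)`; blocks are
#' non-overlapping and sorted by onset.
#'
#' @param order_id 1 or 2, the counterbalance order.
#' @param acquisition An [acq_params()] object.
#' @return A `session_schedule`: a data.frame with columns `onset_s`,
#'   `duration_s`, `trial_type` (one of instruction, encoding,
#'   vocab_distractor, vocab_independent, probe, bonus, trivia, fixation),
#'   `block_id` and `condition_tag`.
#' @examples
#' sched <- build_schedule(1)
#' subset(sched, trial_type == "encoding")$duration_s  # 120 120 120
#' @export
build_schedule <- function(order_id, acquisition = acq_params()) {
  if (!is.numeric(order_id) || length(order_id) != 1L || !order_id %in% c(1, 2))
    stop("order_id must be 1 or 2")

  task_seq <- if (order_id == 1) {
    c("distractor", "independent", "immediate", "trivia", "independent",
      "distractor")
  } else {
    c("independent", "distractor", "immediate", "trivia", "distractor",
      "independent")
  }

  # per-task segment expansions: trial_type / duration
  expand_task <- function(task, tag) {
    seg <- switch(task,
      distractor = data.frame(
        trial_type = c("instruction", "encoding", "instruction",
                       "vocab_distractor", "instruction", "probe", "bonus"),
        duration_s = c(5, 120, 5, 120, 5, 80, 5)),
      immediate = data.frame(
        trial_type = c("instruction", "encoding", "instruction", "probe",
                       "bonus"),
        duration_s = c(5, 120, 5, 80, 5)),
      independent = data.frame(
        trial_type = c("instruction", "vocab_independent"),
        duration_s = c(5, 120)),
      trivia = data.frame(trial_type = "trivia", duration_s = 60))
    seg$condition_tag <- tag
    seg
  }

  # condition tags number repeated tasks by occurrence order
  counters <- c(distractor = 0L, independent = 0L)
  rows <- list()
  for (task in task_seq) {
    rows[[length(rows) + 1L]] <- data.frame(
      trial_type = "fixation", duration_s = 15, condition_tag = "fixation")
    tag <- switch(task,
      distractor = {
        counters["distractor"] <- counters["distractor"] + 1L
        paste0("distractor-task-", counters[["distractor"]])
      },
      independent = {
        counters["independent"] <- counters["independent"] + 1L
        paste0("independent-vocab-", counters[["independent"]])
      },
      immediate = "immediate-recall",
      trivia = "trivia")
    rows[[length(rows) + 1L]] <- expand_task(task, tag)
  }

  sched <- do.call(rbind, rows)
  sched$onset_s <- cumsum(c(0, sched$duration_s[-nrow(sched)]))
  itemised_end <- sched$onset_s[nrow(sched)] + sched$duration_s[nrow(sched)]

  run_len <- run_duration_s(acquisition)
  trailing <- run_len - itemised_end
  if (trailing < 0)
    stop(sprintf("schedule (%g s) exceeds the run length (%g s)",
                 itemised_end, run_len))
  # trailing fixation absorbs the remainder so blocks tile the run exactly
  if (trailing > 0)
    sched <- rbind(sched, data.frame(
      trial_type = "fixation", duration_s = trailing,
      condition_tag = "fixation", onset_s = itemised_end))

  sched$block_id <- seq_len(nrow(sched))
  sched <- sched[, c("onset_s", "duration_s", "trial_type", "block_id",
                     "condition_tag")]
  rownames(sched) <- NULL
  class(sched) <- c("session_schedule", "data.frame")
  sched
}
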
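#' Train a linear support vector machine
#'
#' Soft-margin linear SVM (hinge loss at fixed cost `cost_C`, no feature
#' scaling) via libsvm. The fitted model is reduced to an explicit weight
#' vector and bias so that decisions are transparent and reproducible:
#' `decision(x) = w . x + b`, positive values meaning the positive class.
#'
#' @param x Training matrix (patterns x features).
#' @param labels Character/factor labels; both classes must be present.
#' @param cost_C Regularisation constant (default 1).
#' @param positive_class Label treated as the positive decision side
#'   (default `"vocab_distractor"`; otherwise the first sorted label).
#' @return An object of class `linear_classifier`: list with `weights`,
#'   `bias`, `positive_class`, `negative_class`, `cost_C`.
#' @export
train_linear <- function(x, labels, cost_C = 1,
                         positive_class = NULL) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L)
    stop(sprintf("training needs exactly 2 classes, got %d",
                 length(classes)))
  if (length(labels) != nrow(x))
    stop("labels length does not match the number of training patterns")
  if (is.null(positive_class))
    positive_class <- if ("vocab_distractor" %in% classes)
      "vocab_distractor" else classes[1]
  if (!positive_class %in% classes) stop("positive_class not in labels")
  negative_class <- setdiff(classes, positive_class)
  # libsvm orients its decision toward the class of the first training row;
  # put the positive class first so the orientation is fixed
  ord <- order(labels != positive_class)
  x <- x[ord, , drop = FALSE]
  labels <- labels[ord]
  y <- factor(labels, levels = c(positive_class, negative_class))
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost_C, scale = FALSE)
  w <- as.numeric(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  structure(list(weights = w, bias = b, positive_class = positive_class,
                 negative_class = negative_class, cost_C = cost_C),
            class = "linear_classifier")
}

#' Decision values of a linear classifier
#'
#' @param model A `linear_classifier`.
#' @param x Matrix of patterns (rows) with matching feature count.
#' @param use_bias If `FALSE`, the decision threshold is placed at the
#'   origin (`w . x` only); used by the baseline-referenced cross-decoding
#'   test.
#' @return Numeric decision values.
#' @export
decision_values <- function(model, x, use_bias = TRUE) {
  x <- as.matrix(x)
  if (ncol(x) != length(model$weights))
    stop(sprintf("patterns have %d features but the model has %d",
                 ncol(x), length(model$weights)))
  as.numeric(x %*% model$weights) + if (use_bias) model$bias else 0
}

#' Predict class labels
#'
#' A pattern is assigned the positive class iff its decision value is
#' strictly positive; exact ties go to the negative class.
#'
#' @inheritParams decision_values
#' @return Character vector of labels.
#' @export
predict_linear <- function(model, x, use_bias = TRUE) {
  dec <- decision_values(model, x, use_bias)
  ifelse(dec > 0, model$positive_class, model$negative_class)
}

#' Score one fold as signal-detection sensitivity (d-prime)
#'
#' Hit rate and false-alarm rate are computed against the positive class and
#' clipped to `[1/(2N), 1 - 1/(2N)]` (N the per-class test count) so that
#' perfect rates stay finite; `d' = qnorm(HR) - qnorm(FA)`.
#'
#' @param predicted,truth Equal-length label vectors; both truth classes
#'   must be present.
#' @param positive_class The signal class.
#' @return An object of class `fold_result`: list with `hits`, `misses`,
#'   `false_alarms`, `correct_rejections`, `hit_rate`, `fa_rate`, `dprime`.
#' @export
fold_dprime <- function(predicted, truth, positive_class) {
  if (length(predicted) != length(truth))
    stop("predicted and truth have different lengths")
  is_pos <- truth == positive_class
  if (!any(is_pos) || all(is_pos))
    stop("both truth classes must be present in the fold")
  hits <- sum(predicted[is_pos] == positive_class)
  misses <- sum(is_pos) - hits
  fa <- sum(predicted[!is_pos] == positive_class)
  cr <- sum(!is_pos) - fa
  clip <- function(rate, n) pmin(pmax(rate, 1 / (2 * n)), 1 - 1 / (2 * n))
  hr <- clip(hits / sum(is_pos), sum(is_pos))
  far <- clip(fa / sum(!is_pos), sum(!is_pos))
  structure(list(hits = hits, misses = misses, false_alarms = fa,
                 correct_rejections = cr, hit_rate = hr, fa_rate = far,
                 dprime = stats::qnorm(hr) - stats::qnorm(far)),
            class = "fold_result")
}

#' Within-vocabulary discrimination for one subject and ROI
#'
#' The four vocabulary blocks (two distractor-condition, two independent)
#' are pooled and double-centered per ROI, split into all four
#' one-block-per-class train/test folds, and each fold is classified with a
#' linear SVM and scored as d-prime. The subject's score is the mean over
#' folds.
#'
#' @param vocab_blocks List of 4 `pattern_block`s (2 per class).
#' @param cost_C SVM cost.
#' @return List with `dprime_mean`, `fold_results`, and `n_folds`.
#' @export
subject_dprime <- function(vocab_blocks, cost_C = 1) {
  blocks <- center_block_pool(vocab_blocks)
  folds <- assemble_folds(blocks)
  fold_results <- lapply(folds, function(fold) {
    tr <- stack_blocks(fold$train)
    te <- stack_blocks(fold$test)
    if (any(duplicated(rbind(tr$x, te$x))))
      stop("identical patterns on both sides of a fold (leakage)")
    model <- train_linear(tr$x, tr$labels, cost_C)
    pred <- predict_linear(model, te$x)
    fold_dprime(pred, te$labels, model$positive_class)
  })
  dp <- vapply(fold_results, `[[`, numeric(1), "dprime")
  list(dprime_mean = mean(dp), fold_results = fold_results,
       n_folds = length(fold_results))
}

# Double-center the pooled rows of a block list and write the centered rows
# back into the blocks (pooled-within-analysis centering: train and test
# share one affine shift).
center_block_pool <- function(blocks) {
  st <- stack_blocks(blocks)
  xc <- double_center(st$x)
  offset <- 0L
  for (i in seq_along(blocks)) {
    n <- nrow(blocks[[i]]$matrix)
    blocks[[i]]$matrix <- xc[offset + seq_len(n), , drop = FALSE]
    offset <- offset + n
  }
  blocks
}

#' Cross-decode encoding volumes with a vocabulary-trained classifier
#'
#' A single linear SVM is trained on the pooled, double-centered vocabulary
#' patterns (two blocks per class) to discriminate distractor-condition from
#' independent vocabulary activity. Every retained encoding volume is then
#' classified, and the fraction labelled as the distractor-condition class
#' is the subject's reactivation score.
#'
#' Encoding test patterns are centered across voxels only
#' ([center_across_voxels()]), and with `threshold = "baseline"` (default)
#' the decision threshold sits at the fixation-baseline origin along the
#' learned discriminant axis: the test asks on which side of baseline each
#' encoding volume falls. Under the no-reactivation null the encoding
#' patterns have no component along the discriminant and the expected
#' proportion is exactly the 50% chance level; temporal centering of the
#' test set would instead remove the sustained component under test (see the
#' vignette). `threshold = "trained"` retains the fitted SVM bias.
#'
#' @param vocab_blocks List of 4 vocabulary `pattern_block`s (2 per class).
#' @param encoding_blocks List of >= 1 encoding `pattern_block`s.
#' @param cost_C SVM cost.
#' @param threshold `"baseline"` or `"trained"`.
#' @return An object of class `subject_decoding`: list with
#'   `encoding_distractor_proportion`, `per_volume_labels` (binary, in
#'   acquisition order), `volume_index` (within-encoding-block volume
#'   numbers), `block_id`, and `model`.
#' @export
cross_decode <- function(vocab_blocks, encoding_blocks, cost_C = 1,
                         threshold = c("baseline", "trained")) {
  threshold <- match.arg(threshold)
  if (!length(encoding_blocks)) stop("no encoding blocks to classify")
  raw <- stack_blocks(vocab_blocks)
  if (length(unique(raw$labels)) != 2L)
    stop("both vocabulary classes must be present")
  col_means <- colMeans(raw$x)
  xtr <- sweep(sweep(raw$x, 2, col_means), 1,
               rowMeans(sweep(raw$x, 2, col_means)))
  model <- train_linear(xtr, raw$labels, cost_C)
  te <- stack_blocks(encoding_blocks)
  xe <- if (threshold == "trained") {
    # project the test set into the training frame so the fitted bias is
    # the between-class midpoint
    center_across_voxels(sweep(te$x, 2, col_means))
  } else {
    center_across_voxels(te$x)
  }
  pred <- predict_linear(model, xe, use_bias = (threshold == "trained"))
  lab <- as.integer(pred == model$positive_class)
  structure(list(
    encoding_distractor_proportion = mean(lab),
    per_volume_labels = lab,
    volume_index = te$volume_index,
    block_id = te$block_id,
    model = model,
    threshold = threshold), class = "subject_decoding")
}

#' Across-subject classification proportion per encoding volume
#'
#' For each within-encoding-block volume number, the proportion of
#' encoding observations (pooled over subjects and, within subject, over
#' encoding blocks) classified as the distractor-condition vocabulary task.
#'
#' @param decodings List of `subject_decoding` objects sharing the same
#'   encoding volume indexing.
#' @return List with `volume_index` (sorted unique volume numbers) and
#'   `proportion` (same length).
#' @export
proximity_series <- function(decodings) {
  idx_list <- lapply(decodings, `[[`, "volume_index")
  ref <- sort(unique(idx_list[[1]]))
  for (ix in idx_list)
    if (!identical(sort(unique(ix)), ref))
      stop("subjects have inconsistent encoding volume indexing")
  all_idx <- unlist(idx_list)
  all_lab <- unlist(lapply(decodings, `[[`, "per_volume_labels"))
  prop <- tapply(all_lab, all_idx, mean)
  list(volume_index = as.integer(names(prop)),
       proportion = as.numeric(prop))
}

#' Per-subject series of classification proportions by encoding volume
#'
#' @param decodings List of `subject_decoding` objects.
#' @return Matrix (subjects x volume numbers) of within-subject proportions.
#' @export
subject_volume_series <- function(decodings) {
  ref <- sort(unique(decodings[[1]]$volume_index))
  t(vapply(decodings, function(d) {
    as.numeric(tapply(d$per_volume_labels, d$volume_index, mean))
  }, numeric(length(ref))))
}
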
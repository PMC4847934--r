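test_that("linear SVM solves symmetric and separable toy problems", {
  # symmetric 1-D pair: boundary at 0, weight positive toward class A
  x <- matrix(c(1, -1), ncol = 1)
  m <- train_linear(x, c("A", "B"), cost_C = 100, positive_class = "A")
  expect_equal(m$bias, 0, tolerance = 1e-6)
  expect_gt(m$weights, 0)
  expect_equal(predict_linear(m, matrix(c(2, -2), ncol = 1)), c("A", "B"))

  # separable 4-point 2-D set: zero training error
  x4 <- rbind(c(0, 2), c(1, 3), c(0, -2), c(1, -3))
  y4 <- c("A", "A", "B", "B")
  m4 <- train_linear(x4, y4, cost_C = 10, positive_class = "A")
  expect_equal(predict_linear(m4, x4), y4)

  expect_error(train_linear(x4, rep("A", 4)), "2 classes")
  expect_error(predict_linear(m4, matrix(0, 1, 3)), "features")
})

test_that("SVM margin matches the exact QP oracle on 6-point instances", {
  insts <- list(
    list(x = rbind(c(1, 0), c(2, 1), c(2, -1),
                   c(-1, 0), c(-2, 1), c(-2, -1)),
         y = c(1, 1, 1, -1, -1, -1)),
    list(x = rbind(c(1.5, 0.5), c(2, 2), c(3, -1),
                   c(-0.5, 0.2), c(-2, 1), c(-1, -2)),
         y = c(1, 1, 1, -1, -1, -1)))
  for (inst in insts) {
    oracle <- qp_svm_oracle(inst$x, inst$y)
    lab <- ifelse(inst$y > 0, "pos", "neg")
    m <- train_linear(inst$x, lab, cost_C = 1e4, positive_class = "pos")
    margin_svm <- 2 / sqrt(sum(m$weights^2))
    expect_equal(margin_svm, oracle$margin, tolerance = 1e-6)
    expect_equal(m$weights / sqrt(sum(m$weights^2)),
                 oracle$w / sqrt(sum(oracle$w^2)), tolerance = 1e-5)
  }
})

test_that("prediction ties go to the negative class and negation flips labels", {
  m <- structure(list(weights = c(1, -1), bias = 0, positive_class = "pos",
                      negative_class = "neg", cost_C = 1),
                 class = "linear_classifier")
  expect_equal(predict_linear(m, matrix(c(1, 1), 1)), "neg")   # exact tie
  x <- matrix(rnorm(20), 10, 2)
  m2 <- m; m2$weights <- -m$weights
  p1 <- predict_linear(m, x)
  p2 <- predict_linear(m2, x)
  expect_true(all((p1 == "pos") == (p2 == "neg")))
})

test_that("classifier refits are bit-identical on identical inputs", {
  set.seed(21)
  x <- matrix(rnorm(60 * 8), 60, 8)
  y <- rep(c("vocab_distractor", "vocab_independent"), each = 30)
  m1 <- train_linear(x, y)
  m2 <- train_linear(x, y)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$bias, m2$bias)
})

test_that("d-prime scoring matches the inverse-normal oracle with clipping", {
  mk_labels <- function(hits, fas) {
    truth <- rep(c("pos", "neg"), each = 44)
    pred <- c(rep("pos", hits), rep("neg", 44 - hits),
              rep("pos", fas), rep("neg", 44 - fas))
    list(pred = pred, truth = truth)
  }
  # chance
  z <- mk_labels(22, 22)
  expect_equal(fold_dprime(z$pred, z$truth, "pos")$dprime, 0)
  # HR .75 / FA .25 -> 2 * qnorm(.75)
  z2 <- mk_labels(33, 11)
  expect_equal(fold_dprime(z2$pred, z2$truth, "pos")$dprime,
               2 * qnorm(0.75), tolerance = 1e-12)
  expect_equal(2 * qnorm(0.75), 1.349, tolerance = 1e-3)
  # perfect fold is clipped to 1/(2N)
  z3 <- mk_labels(44, 0)
  expect_equal(fold_dprime(z3$pred, z3$truth, "pos")$dprime,
               2 * qnorm(87 / 88), tolerance = 1e-12)
  # antisymmetry under label swap
  z4 <- mk_labels(30, 10)
  d1 <- fold_dprime(z4$pred, z4$truth, "pos")$dprime
  flipped <- ifelse(z4$pred == "pos", "neg", "pos")
  d2 <- fold_dprime(flipped, z4$truth, "pos")$dprime
  expect_equal(d1, -d2)
  expect_error(fold_dprime(rep("pos", 4), rep("pos", 4), "pos"),
               "both truth classes")
})

test_that("subject d-prime is centred at zero under label shuffling and high under planted signal", {
  nvox <- 24
  mk_block <- function(label, id, shift = 0) structure(
    list(matrix = matrix(rnorm(44 * nvox), 44, nvox) + shift,
         label = label, block_id = id, onset_s = id, volume_index = 5:48),
    class = "pattern_block")
  set.seed(31)
  # null: labels carry no information
  null_dp <- replicate(40, {
    blocks <- list(mk_block("vocab_distractor", 1),
                   mk_block("vocab_distractor", 2),
                   mk_block("vocab_independent", 3),
                   mk_block("vocab_independent", 4))
    subject_dprime(blocks)$dprime_mean
  })
  expect_lt(abs(mean(null_dp)), 3 * sd(null_dp) / sqrt(length(null_dp)))
  # strong planted zero-spatial-mean pattern (uniform shifts are removed by
  # the across-voxel centering, so the pattern must be distributed)
  pat <- rnorm(nvox); pat <- (pat - mean(pat)) / sqrt(sum(pat^2))
  shift_mat <- 3 * matrix(pat, 44, nvox, byrow = TRUE)
  strong <- replicate(10, {
    blocks <- list(mk_block("vocab_distractor", 1, shift_mat),
                   mk_block("vocab_distractor", 2, shift_mat),
                   mk_block("vocab_independent", 3),
                   mk_block("vocab_independent", 4))
    subject_dprime(blocks)$dprime_mean
  })
  expect_true(all(strong > 1))
})

test_that("cross-decoding proportions behave at the degenerate extremes", {
  set.seed(41)
  nvox <- 24
  mk_block <- function(label, id, shift = 0) structure(
    list(matrix = matrix(rnorm(44 * nvox, sd = 0.05), 44, nvox) + shift,
         label = label, block_id = id, onset_s = id, volume_index = 5:48),
    class = "pattern_block")
  pat <- rnorm(nvox); pat <- (pat - mean(pat)) / sqrt(sum(pat^2))
  shift_mat <- matrix(pat, 44, nvox, byrow = TRUE)
  vocab <- list(mk_block("vocab_distractor", 1, shift_mat),
                mk_block("vocab_distractor", 2, shift_mat),
                mk_block("vocab_independent", 3),
                mk_block("vocab_independent", 4))
  # encoding duplicated from a distractor block -> proportion 1 under both
  # threshold placements
  enc_d <- vocab[[1]]; enc_d$label <- "encoding"; enc_d$block_id <- 9L
  expect_equal(cross_decode(vocab,
                            list(enc_d))$encoding_distractor_proportion, 1)
  expect_equal(cross_decode(vocab, list(enc_d),
                            threshold = "trained")$encoding_distractor_proportion,
               1)
  # an independent-duplicate test set lies on the baseline side of the
  # trained midpoint, but at the baseline origin itself it splits ~50/50
  enc_i <- vocab[[3]]; enc_i$label <- "encoding"; enc_i$block_id <- 9L
  expect_equal(cross_decode(vocab, list(enc_i),
                            threshold = "trained")$encoding_distractor_proportion,
               0)
  base_i <- cross_decode(vocab, list(enc_i))$encoding_distractor_proportion
  expect_gt(base_i, 0.2); expect_lt(base_i, 0.8)
  expect_error(cross_decode(vocab, list()), "no encoding blocks")
})

test_that("proximity series aggregates per-volume labels across subjects", {
  mk_dec <- function(labels) structure(
    list(encoding_distractor_proportion = mean(labels),
         per_volume_labels = labels, volume_index = rep(5:8, 2),
         block_id = rep(1:2, each = 4)), class = "subject_decoding")
  all_one <- lapply(1:3, function(i) mk_dec(rep(1L, 8)))
  ps <- proximity_series(all_one)
  expect_equal(ps$proportion, rep(1, 4))
  expect_equal(ps$volume_index, 5:8)
  one <- proximity_series(list(mk_dec(c(1, 0, 1, 0, 1, 0, 0, 0))))
  expect_true(all(one$proportion %in% c(0, 0.5, 1)))
  # coin-flip labels concentrate near 0.5
  set.seed(2)
  many <- lapply(1:200, function(i) mk_dec(rbinom(8, 1, 0.5)))
  psm <- proximity_series(many)
  expect_lt(max(abs(psm$proportion - 0.5)), 0.15)
  bad <- mk_dec(rep(1L, 8)); bad$volume_index <- rep(9:12, 2)
  expect_error(proximity_series(list(all_one[[1]], bad)), "inconsistent")
})
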
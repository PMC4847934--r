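test_that("Wilcoxon signed-rank exact p-values match full enumeration", {
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3))$p_value, 0.125)
  expect_equal(wilcoxon_signed_rank(c(-1, -2, -3))$p_value, 1)
  set.seed(12)
  for (n in 3:10) {
    vals <- round(rnorm(n), 1)          # occasional ties and zeros
    vals <- vals[vals != 0]
    if (length(vals) < 2) next
    res <- wilcoxon_signed_rank(vals)
    expect_equal(res$p_value, wilcoxon_enum_p(vals), info = paste("n =", n))
    expect_equal(res$method, "exact")
    # against stats::wilcox.test where no ties interfere
    if (!any(duplicated(abs(vals)))) {
      ref <- stats::wilcox.test(vals, mu = 0, alternative = "greater",
                                exact = TRUE)
      expect_equal(res$p_value, ref$p.value)
    }
  }
  expect_error(wilcoxon_signed_rank(c(0, 0)), "zero")
})

test_that("Wilcoxon normal approximation is continuity- and tie-corrected", {
  set.seed(13)
  vals <- rnorm(40, mean = 0.3)
  res <- wilcoxon_signed_rank(vals)
  expect_equal(res$method, "normal")
  ref <- stats::wilcox.test(vals, mu = 0, alternative = "greater",
                            exact = FALSE, correct = TRUE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  # Z and p are consistent
  expect_equal(res$p_value, pnorm(res$statistic_z, lower.tail = FALSE))
  # symmetric data in large samples sit near p = 0.5
  sym <- c(rnorm(30), -rnorm(30))
  expect_gt(wilcoxon_signed_rank(sym)$p_value, 0.1)
})

test_that("chance level arithmetic", {
  expect_equal(chance_correct(16, 3), 16 / 3)
  expect_equal(chance_correct(16, 3), 5.333, tolerance = 1e-3)
  expect_equal(chance_correct(0, 3), 0)
  expect_equal(chance_correct(10, 1), 10)
  expect_error(chance_correct(10, 0), "alternatives")
})

test_that("paired t-test matches the closed form", {
  a <- c(2, 3, 4); b <- c(1, 1, 1)      # d = 1, 2, 3
  res <- paired_ttest(a, b)
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$dof, 2)
  expect_equal(res$p, 2 * pt(2 * sqrt(3), 2, lower.tail = FALSE))
  # n = 35 cohorts carry 34 dof
  set.seed(14)
  res35 <- paired_ttest(rnorm(35), rnorm(35))
  expect_equal(res35$dof, 34)
  expect_error(paired_ttest(1:5, 1:5 + 1), "zero-variance")
  expect_error(paired_ttest(1:4, 1:5), "lengths")
})

test_that("proximity correlation test evaluates the one-tailed p formula", {
  x <- 1:20
  up <- proximity_test(x, 0.1 * x)
  expect_equal(up$r, 1)
  expect_lt(up$p_one_tailed_positive, 1e-10)
  down <- proximity_test(x, -0.05 * x)
  expect_equal(down$r, -1)
  expect_gt(down$p_one_tailed_positive, 1 - 1e-10)
  # r = -0.31 at dof 33: p ~ 0.965 by the t-CDF formula
  tval <- -0.31 * sqrt(33 / (1 - 0.31^2))
  expect_equal(pt(tval, 33, lower.tail = FALSE), 0.9645, tolerance = 1e-3)
  # and the same through the function on data constructed to give that r
  set.seed(15)
  xx <- seq_len(35)
  yy <- -0.31 * scale(xx)[, 1] +
    sqrt(1 - 0.31^2) * scale(resid(lm(rnorm(35) ~ xx)))[, 1]
  res <- proximity_test(xx, yy)
  expect_equal(res$dof, 33)
  expect_equal(res$r, -0.31, tolerance = 1e-10)
  expect_equal(res$p_one_tailed_positive, pt(tval, 33, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_error(proximity_test(1:2, 1:2), "3 points")
  expect_error(proximity_test(1:5, rep(1, 5)), "zero variance")
})

test_that("behavioural comparison recovers condition means and tests", {
  set.seed(16)
  n <- 35
  beh <- data.frame(
    probe_correct_distractor_1 = rbinom(n, 16, 8.73 / 16),
    probe_correct_distractor_2 = rbinom(n, 16, 8.73 / 16),
    probe_correct_immediate = rbinom(n, 16, 7.94 / 16),
    vocab_correct_distractor_1 = rbinom(n, 15, 7.41 / 15),
    vocab_correct_distractor_2 = rbinom(n, 15, 7.41 / 15),
    vocab_correct_independent_1 = rbinom(n, 15, 7.41 / 15),
    vocab_correct_independent_2 = rbinom(n, 15, 7.41 / 15),
    rt_mean_distractor_s = rnorm(n, 4.25, 0.68),
    rt_mean_independent_s = rnorm(n, 4.16, 0.57))
  res <- behavioral_compare(beh)
  expect_equal(nrow(res$rows), 3L)
  expect_equal(res$chance_pairs, 16 / 3)
  expect_true(all(res$rows$dof == n - 1))
  probe <- res$rows[res$rows$comparison == "probe_distractor_vs_immediate", ]
  expect_lt(abs(probe$mean_a - 8.73), 1)
  expect_lt(abs(probe$mean_b - 7.94), 1)
  expect_error(behavioral_compare(beh[, -3]), "missing")
})

test_that("probe comparison p-values are uniform under a true null", {
  set.seed(17)
  ps <- replicate(200, {
    n <- 20
    beh <- data.frame(
      probe_correct_distractor_1 = rbinom(n, 16, 0.5),
      probe_correct_distractor_2 = rbinom(n, 16, 0.5),
      probe_correct_immediate = rbinom(n, 16, 0.5))
    paired_ttest((beh[[1]] + beh[[2]]) / 2, beh[[3]])$p
  })
  expect_gt(mean(ps <= 0.05), 0.01)
  expect_lt(mean(ps <= 0.05), 0.11)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.001)
})
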
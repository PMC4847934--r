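#' One-sample Wilcoxon signed-rank test
#'
#' Tests whether `values` are shifted away from `mu0`. Zero differences are
#' dropped (classical convention); ranks of absolute differences use
#' midranks for ties. For `n_effective <= 12` the p-value is exact, by full
#' enumeration of all `2^n` sign assignments of the observed ranks;
#' otherwise a normal approximation with tie correction and continuity
#' correction is used. The normal-approximation `Z` is reported in both
#' cases for comparability.
#'
#' @param values Numeric vector.
#' @param mu0 Null location (default 0; use 0.5 for chance-level
#'   proportions).
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @param exact_max Largest `n_effective` for which the exact enumeration is
#'   used (default 12).
#' @return An object of class `group_result`: list with `statistic_z`,
#'   `p_value`, `w_statistic`, `n_effective`, `method` (`"exact"` or
#'   `"normal"`), `alternative`, `mu0`.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3))$p_value  # exact 1/8
#' @export
wilcoxon_signed_rank <- function(values, mu0 = 0,
                                 alternative = c("greater", "less",
                                                 "two.sided"),
                                 exact_max = 12L) {
  alternative <- match.arg(alternative)
  d <- values - mu0
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero")
  r <- rank(abs(d))
  w <- sum(r[d > 0])

  # normal approximation with tie and continuity correction (always
  # computed: Z is the reported comparability statistic)
  mu_w <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  cc <- switch(alternative, greater = -0.5, less = 0.5,
               two.sided = -0.5 * sign(w - mu_w))
  z <- (w - mu_w + cc) / sqrt(sigma2)

  if (n <= exact_max) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    wdist <- as.numeric(signs %*% r)
    p <- switch(alternative,
      greater = mean(wdist >= w),
      less = mean(wdist <= w),
      two.sided = min(1, 2 * min(mean(wdist >= w), mean(wdist <= w))))
    method <- "exact"
  } else {
    p <- switch(alternative,
      greater = stats::pnorm(z, lower.tail = FALSE),
      less = stats::pnorm(z),
      two.sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
    method <- "normal"
  }
  structure(list(statistic_z = z, p_value = p, w_statistic = w,
                 n_effective = n, method = method,
                 alternative = alternative, mu0 = mu0),
            class = "group_result")
}

#' Expected correct responses under guessing
#'
#' @param n_trials Number of forced-choice trials.
#' @param n_alternatives Alternatives per trial (>= 1).
#' @return `n_trials / n_alternatives` (e.g. 16 probe trials with 3
#'   alternatives give 16/3 = 5.33 pairs).
#' @export
chance_correct <- function(n_trials, n_alternatives) {
  if (n_alternatives < 1) stop("n_alternatives must be >= 1")
  n_trials / n_alternatives
}

#' Paired-samples t-test
#'
#' @param a,b Equal-length numeric vectors (n >= 2) of paired observations.
#' @param two_tailed If `FALSE`, one-tailed p for `mean(a - b) > 0`.
#' @return List with `t`, `dof = n - 1`, `p`, `mean_diff`.
#' @export
paired_ttest <- function(a, b, two_tailed = TRUE) {
  if (length(a) != length(b)) stop("a and b have different lengths")
  n <- length(a)
  if (n < 2L) stop("need at least 2 pairs")
  d <- a - b
  if (stats::sd(d) == 0) stop("zero-variance differences")
  tt <- stats::t.test(a, b, paired = TRUE,
                      alternative = if (two_tailed) "two.sided" else
                        "greater")
  list(t = unname(tt$statistic), dof = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(d))
}

#' Temporal-proximity control correlation
#'
#' Pearson correlation between the classification proportion and the
#' encoding volume number, with a one-tailed p-value for a positive
#' correlation: `t = r sqrt(dof / (1 - r^2))`, `dof = n - 2`,
#' `p = P(T_dof >= t)`. A temporal-proximity account of cross-decoding
#' predicts `r > 0` (classification as distractor increases towards the end
#' of encoding); a non-significant or negative r disfavours it.
#'
#' @param volume_index Volume numbers (>= 3 points).
#' @param proportions Classification proportions, same length.
#' @return An object of class `proximity_result`: list with `r`, `dof`,
#'   `p_one_tailed_positive`, `n_points`.
#' @export
proximity_test <- function(volume_index, proportions) {
  if (length(volume_index) != length(proportions))
    stop("inconsistent lengths")
  n <- length(volume_index)
  if (n < 3L) stop("need at least 3 points")
  if (stats::sd(volume_index) == 0 || stats::sd(proportions) == 0)
    stop("zero variance in the correlation inputs")
  r <- stats::cor(volume_index, proportions)
  dof <- n - 2L
  tval <- r * sqrt(dof / (1 - r^2))
  structure(list(r = r, dof = dof,
                 p_one_tailed_positive = stats::pt(tval, dof,
                                                   lower.tail = FALSE),
                 n_points = n),
            class = "proximity_result")
}

#' Per-subject temporal-proximity test
#'
#' Alternative mode: each subject's own correlation between classification
#' and volume number is Fisher-z transformed and the transformed values are
#' submitted to a one-sample t-test against 0 (one-tailed, positive). Its
#' degrees of freedom are `n_subjects - 1`. Subjects with zero variance in
#' either vector are dropped.
#'
#' @param series Matrix (subjects x volume numbers) from
#'   [subject_volume_series()].
#' @param volume_index Volume numbers (columns of `series`).
#' @return List with `mean_r`, `t`, `dof`, `p_one_tailed_positive`,
#'   `n_subjects_used`.
#' @export
proximity_subject_test <- function(series, volume_index) {
  rs <- apply(series, 1, function(y) {
    if (stats::sd(y) == 0) return(NA_real_)
    stats::cor(volume_index, y)
  })
  rs <- rs[!is.na(rs)]
  if (length(rs) < 2L) stop("fewer than 2 subjects with usable series")
  fz <- atanh(pmin(pmax(rs, -1 + 1e-12), 1 - 1e-12))
  tt <- stats::t.test(fz, mu = 0, alternative = "greater")
  list(mean_r = mean(rs), t = unname(tt$statistic),
       dof = unname(tt$parameter), p_one_tailed_positive = tt$p.value,
       n_subjects_used = length(rs))
}

#' Behavioural comparisons for a cohort
#'
#' Per subject, the distractor-condition probe score is the mean of the two
#' distractor-task probe periods; the vocabulary scores and reaction times
#' are per-condition means of their two blocks. Three two-tailed paired
#' t-tests are reported: probe recall (distractor vs immediate), vocabulary
#' accuracy (distractor vs independent), and vocabulary reaction time. The
#' probe chance level, 16 trials at 3 alternatives, is attached.
#'
#' @param behavior data.frame with one row per subject (columns as written
#'   by [write_session()]).
#' @return List with `rows` (a data.frame, one row per comparison:
#'   mean/sd per condition, t, dof, p) and `chance_pairs`.
#' @export
behavioral_compare <- function(behavior) {
  need <- c("probe_correct_distractor_1", "probe_correct_distractor_2",
            "probe_correct_immediate", "vocab_correct_distractor_1",
            "vocab_correct_distractor_2", "vocab_correct_independent_1",
            "vocab_correct_independent_2", "rt_mean_distractor_s",
            "rt_mean_independent_s")
  missing <- setdiff(need, names(behavior))
  if (length(missing))
    stop(sprintf("behavior table is missing: %s",
                 paste(missing, collapse = ", ")))
  probe_d <- (behavior$probe_correct_distractor_1 +
                behavior$probe_correct_distractor_2) / 2
  probe_i <- behavior$probe_correct_immediate
  voc_d <- (behavior$vocab_correct_distractor_1 +
              behavior$vocab_correct_distractor_2) / 2
  voc_i <- (behavior$vocab_correct_independent_1 +
              behavior$vocab_correct_independent_2) / 2
  rt_d <- behavior$rt_mean_distractor_s
  rt_i <- behavior$rt_mean_independent_s
  row_for <- function(name, a, b) {
    tt <- paired_ttest(a, b, two_tailed = TRUE)
    data.frame(comparison = name, mean_a = mean(a), sd_a = stats::sd(a),
               mean_b = mean(b), sd_b = stats::sd(b), t = tt$t,
               dof = tt$dof, p = tt$p)
  }
  rows <- rbind(
    row_for("probe_distractor_vs_immediate", probe_d, probe_i),
    row_for("vocab_accuracy_distractor_vs_independent", voc_d, voc_i),
    row_for("vocab_rt_distractor_vs_independent", rt_d, rt_i))
  list(rows = rows, chance_pairs = chance_correct(16, 3))
}
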
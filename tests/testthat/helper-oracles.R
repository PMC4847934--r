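# Independent oracles and small fixtures used across the suite.

# Small-grid acquisition for fast full-volume tests.
tiny_acq <- function(grid = c(10L, 10L, 6L)) acq_params(grid_dims = grid)

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(
    acquisition = tiny_acq(),
    planted_clusters = list(list(center = c(3, 3, 3), radius = 1,
                                 amplitude = 1)),
    pattern_center = c(7L, 7L, 3L), pattern_radius_mm = 6,
    n_subjects = 1L, seed = 1L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Exact max-margin solver for tiny separable 2-class problems: enumerates
# active sets of the hard-margin dual KKT system (interior support vectors
# only, valid for large C on separable data) and returns the best feasible
# stationary point. Independent of libsvm.
qp_svm_oracle <- function(x, y) {
  x <- as.matrix(x)
  y <- as.numeric(y)              # +1 / -1
  n <- nrow(x)
  q <- (y %*% t(y)) * (x %*% t(x))
  best <- NULL
  for (mask in 1:(2^n - 1)) {
    s <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(unique(y[s])) < 2) next
    # solve: Q_ss a + mu y_s = 1, y_s' a = 0
    k <- length(s)
    a_full <- rep(0, n)
    m <- rbind(cbind(q[s, s, drop = FALSE], y[s]), c(y[s], 0))
    rhs <- c(rep(1, k), 0)
    sol <- tryCatch(solve(m, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    a <- sol[seq_len(k)]
    if (any(a < -1e-10)) next
    a_full[s] <- pmax(a, 0)
    # KKT: margins of non-support points must be >= 1
    w <- colSums(a_full * y * x)
    b <- mean(y[s] - x[s, , drop = FALSE] %*% w)
    marg <- y * (x %*% w + b)
    if (any(marg < 1 - 1e-8)) next
    obj <- sum(a_full) - 0.5 * t(a_full) %*% q %*% a_full
    if (is.null(best) || obj > best$obj + 1e-12)
      best <- list(w = w, b = as.numeric(b), obj = as.numeric(obj),
                   margin = 2 / sqrt(sum(w^2)))
  }
  best
}

# Full 2^n enumeration of the one-sample signed-rank null distribution.
wilcoxon_enum_p <- function(values, mu0 = 0, alternative = "greater") {
  d <- values - mu0
  d <- d[d != 0]
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  wdist <- as.numeric(signs %*% r)
  switch(alternative,
         greater = mean(wdist >= w_obs),
         less = mean(wdist <= w_obs))
}

# Brute-force count of lattice points within a sphere of radius r voxels.
sphere_count_oracle <- function(r_vox) {
  rng <- ceiling(r_vox)
  g <- expand.grid(i = -rng:rng, j = -rng:rng, k = -rng:rng)
  sum(g$i^2 + g$j^2 + g$k^2 <= r_vox^2 + 1e-9)
}
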
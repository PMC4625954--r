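# Independent oracles and shared fixtures for the test suite.

# Exhaustive enumeration of all admissible DTW paths (depth-first with
# cost pruning; exact for the minimum because step costs are >= 0).
# Completely independent of the dynamic-programming implementation.
dtw_oracle <- function(y1, y2, boundary = "partial") {
  m <- length(y1)
  n <- length(y2)
  starts <- if (boundary == "fixed") list(c(1, 1)) else
    unique(c(lapply(seq_len(n), function(j) c(1, j)),
             lapply(seq_len(m), function(i) c(i, 1))))
  is_end <- switch(boundary,
    partial = function(i, j) i == m || j == n,
    fixed   = function(i, j) i == m && j == n,
    printed = function(i, j) i == n || j == n)
  best <- Inf
  rec <- function(i, j, acc) {
    acc <- acc + (y1[i] - y2[j])^2
    if (acc >= best) return(invisible(NULL))
    if (is_end(i, j)) best <<- acc
    if (i < m) rec(i + 1, j, acc)
    if (j < n) rec(i, j + 1, acc)
    if (i < m && j < n) rec(i + 1, j + 1, acc)
  }
  for (s in starts) rec(s[1], s[2], 0)
  best
}

# Log partial likelihood (Breslow; valid with no tied event times) for a
# single covariate Cox model, maximized by golden-section search.
cox_oracle_coef <- function(time, event, x) {
  ll <- function(b) {
    s <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      s <- s + b * x[i] - log(sum(exp(b * x[risk])))
    }
    s
  }
  stats::optimize(ll, c(-10, 10), maximum = TRUE, tol = 1e-10)$maximum
}

# Adjusted Rand index from the contingency table (closed form).
adjusted_rand <- function(a, b) {
  ct <- table(a, b)
  n <- sum(ct)
  sum_ij <- sum(choose(ct, 2))
  sum_a <- sum(choose(rowSums(ct), 2))
  sum_b <- sum(choose(colSums(ct), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# random signature with betas on a 0.1 grid, lengths in len_range
random_grid_signature <- function(len_range = c(1, 6)) {
  len <- sample(seq.int(len_range[1], len_range[2]), 1)
  sample(seq(0, 1, by = 0.1), len, replace = TRUE)
}

# shared fixture cache: heavier cohorts built once per test run
.fixture_env <- new.env(parent = emptyenv())
fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# small matched cohort used across module tests
small_cohort <- function() {
  fixture("small_cohort", simulate_cohort(
    sim_config(n_cgi = 40, n_samples_normal = 30, n_samples_cancer = 60,
               seed = 42)))
}

small_profiles <- function(condition = "cancer") {
  key <- paste0("small_profiles_", condition)
  fixture(key, {
    coh <- small_cohort()
    betas <- if (condition == "cancer") coh$betas_cancer else coh$betas_normal
    build_profiles(betas, coh$manifest)
  })
}
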
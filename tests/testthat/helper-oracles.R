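# Shared fixtures and independent brute-force oracles.

# Reduced grid for fast end-to-end runs: 5 frequencies (one octave apart),
# full level ladder, halved sampling rate.
tiny_grid <- function() {
  stimulus_grid(f_min = 2000, f_max = 32000, steps_per_octave = 1)
}

tiny_config <- function(n_5ch = 1, n_6ch = 1, ...) {
  cohort_config(n_5ch = n_5ch, n_6ch = n_6ch, grid = tiny_grid(), ...)
}

# Oracle: threshold by linear scan over all levels.
brute_threshold <- function(p2p, baseline, levels) {
  criterion <- pmax(2 * baseline, 0.1)
  if (length(criterion) == 1) criterion <- rep(criterion, length(levels))
  for (i in seq_along(levels))
    if (p2p[i] >= criterion[i])
      return(list(threshold = levels[i], censored = FALSE))
  list(threshold = max(levels) + diff(levels[1:2]), censored = TRUE)
}

# Oracle: exact signed-rank p by enumeration of all 2^n sign patterns.
enum_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  list(statistic = v_obs, p_value = min(1, 2 * min(p_le, p_ge)))
}

# Oracle: exact Mann-Whitney p by enumeration of all group assignments.
enum_mann_whitney <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n <- length(a)
  w_obs <- sum(r[seq_len(n)])
  u_obs <- w_obs - n * (n + 1) / 2
  combs <- utils::combn(length(pooled), n)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]))
  u_all <- w_all - n * (n + 1) / 2
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  list(statistic = u_obs, p_value = min(1, 2 * min(p_le, p_ge)))
}

# Oracle: OLS via the normal equations.
normal_eq_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  yhat <- X %*% beta
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2], r_squared = 1 - ss_res / ss_tot)
}
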
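# Independent oracles used across test files. These deliberately avoid the
# package's own computational paths.

# Cluster-robust sandwich variance by explicit matrix arithmetic:
# (X'X)^-1 [sum_g s_g s_g'] (X'X)^-1 * [G/(G-1)] * [(N-1)/(N-k)],
# s_g the within-cluster sum of score vectors X_i * e_i.
brute_sandwich <- function(y, x, cluster_ids) {
  X <- cbind(1, x)
  n <- length(y)
  k <- ncol(X)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  e <- as.vector(y - X %*% beta)
  groups <- split(seq_len(n), cluster_ids)
  G <- length(groups)
  meat <- matrix(0, k, k)
  for (idx in groups) {
    s <- colSums(X[idx, , drop = FALSE] * e[idx])
    meat <- meat + s %o% s
  }
  bread <- solve(t(X) %*% X)
  c_adj <- (G / (G - 1)) * ((n - 1) / (n - k))
  list(beta = as.vector(beta), vcov = bread %*% meat %*% bread * c_adj)
}

# Hand evaluation of the type-7 interpolation rule at h = (n-1) p + 1.
hand_quantile <- function(values, p) {
  s <- sort(values)
  n <- length(s)
  sapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  })
}

# Central-moment skewness/kurtosis by direct arithmetic.
hand_moments <- function(values) {
  m <- mean(values)
  m2 <- mean((values - m)^2)
  m3 <- mean((values - m)^3)
  m4 <- mean((values - m)^4)
  c(skewness = m3 / m2^1.5, kurtosis_excess = m4 / m2^2 - 3)
}

# Two-tailed z-test power by direct normal-CDF arithmetic.
hand_meta_power <- function(delta, se, alpha = 0.05) {
  zc <- qnorm(1 - alpha / 2)
  1 - pnorm(zc - delta / se) + pnorm(-zc - delta / se)
}

# Strict monotonicity check that tolerates saturation of the power
# function at 1 in double precision.
is_power_monotone <- function(p) {
  all(diff(p) >= -1e-12) &&
    all(diff(p)[p[-length(p)] < 1 - 1e-9] > 0)
}

# Small well-formed effects table used by several IO tests.
tiny_effects <- function() {
  effect_records(
    es_value = c(0.4, -1.1, 0.9),
    es_metric = c("cohens_d", "hedges_g", "cohens_d"),
    meta_id = c("M1", "M1", "M2"),
    ci_lower = c(0.1, -1.6, NA), ci_upper = c(0.7, -0.6, NA),
    n_treatment = c(12L, 20L, NA), n_control = c(11L, 18L, NA),
    year = c(2005L, 2012L, 1998L),
    vessel_bed = c("macro", "micro", "unknown"),
    modality = c("ultrasound", "laser_doppler", "unknown"),
    bio_category = c("exercise", "pathophysiology", "unknown"))
}
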
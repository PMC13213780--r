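# Shared fixtures, built in code.

default_dataset <- function(seed = 1, ...) {
  simulate_peppers(synthetic_config(...), seed = seed)
}

# Brute-force two-sample KS statistic: scan |ECDF_a - ECDF_b| at all points.
brute_ks_d <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(vapply(pts, function(t) {
    abs(mean(a <= t) - mean(b <= t))
  }, numeric(1)))
}

# Brute-force KMO from explicit pairwise partial correlations: q_ij is the
# correlation of residuals of x_i and x_j after regressing each on all
# other variables.
brute_kmo <- function(X) {
  p <- ncol(X)
  R <- cor(X)
  q <- matrix(0, p, p)
  for (i in 1:(p - 1)) for (j in (i + 1):p) {
    others <- setdiff(1:p, c(i, j))
    ri <- if (length(others)) resid(lm(X[, i] ~ X[, others])) else X[, i]
    rj <- if (length(others)) resid(lm(X[, j] ~ X[, others])) else X[, j]
    q[i, j] <- cor(ri, rj)
  }
  off <- upper.tri(R)
  sum(R[off]^2) / (sum(R[off]^2) + sum(q[off]^2))
}

# Quick fusion-free training configuration for tests that only need a
# converged small network, not peak accuracy.
test_cfg <- function(seed = 1, epochs = 900, patience = 150,
                     min_epochs = 250) {
  train_config(epochs = epochs, patience = patience,
               min_epochs = min_epochs, seed = seed)
}
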
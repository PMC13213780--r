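# Exact (O(n^2)) t-distributed stochastic neighbor embedding, sufficient for
# panels of a few hundred samples.  Deterministic given a seed.

tsne_embed <- function(X, dims = 2, perplexity = 15, max_iter = 500,
                       eta = 200, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 5) abort("need at least 5 samples for t-SNE")
  if (perplexity >= (n - 1) / 3) perplexity <- max(2, floor((n - 1) / 3))
  D2 <- as.matrix(dist(X))^2

  # per-point precision by bisection to match the target perplexity
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      s <- sum(p)
      if (s == 0) { p <- rep(1 / length(di), length(di)); break }
      H <- log(s) + beta * sum(di * p) / s
      diff <- H - logU
      if (abs(diff) < 1e-5) break
      if (diff > 0) {
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    P[i, -i] <- p / sum(p)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  set.seed(seed)
  Y <- matrix(rnorm(n * dims, 0, 1e-4), n, dims)
  dY <- matrix(0, n, dims)
  gains <- matrix(1, n, dims)
  momentum <- 0.5
  Pe <- P * 12                              # early exaggeration
  for (it in seq_len(max_iter)) {
    if (it == 101) Pe <- P
    if (it == 251) momentum <- 0.8
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y), "-")
  }
  Y
}
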
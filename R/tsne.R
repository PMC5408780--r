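# Compact exact t-SNE (O(n^2)), sufficient for embedding a few hundred
# spatial-max-reduced feature vectors.  Perplexity calibration by binary
# search on the per-point Gaussian bandwidth; early exaggeration and
# momentum follow the reference implementation's schedule.

tsne_p_matrix <- function(X, perplexity) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betamin <- -Inf; betamax <- Inf
    Di <- D[i, -i]
    for (tries in 1:50) {
      ex <- exp(-Di * beta)
      sumP <- sum(ex)
      if (sumP == 0) sumP <- .Machine$double.xmin
      H <- log(sumP) + beta * sum(Di * ex) / sumP
      diff <- H - logU
      if (abs(diff) < 1e-5) break
      if (diff > 0) {
        betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else {
        betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
    }
    Pi <- exp(-Di * beta)
    Pi <- Pi / max(sum(Pi), .Machine$double.xmin)
    P[i, -i] <- Pi
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

tsne_embed <- function(X, perplexity = 15, n_iter = 400, seed = 1L) {
  n <- nrow(X)
  if (n < 4) stop_locnet("data", "too few samples for embedding (%d)", n)
  perplexity <- min(perplexity, (n - 1) / 3)
  P <- tsne_p_matrix(X, perplexity)
  with_seed(seed, {
    Y <- matrix(rnorm(n * 2, 0, 1e-4), n, 2)
    dY <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    momentum <- 0.5
    eta <- 100
    P4 <- P * 4                      # early exaggeration
    for (it in seq_len(n_iter)) {
      Puse <- if (it <= 100) P4 else P
      sumY <- rowSums(Y^2)
      num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (Puse - Q) * num
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      dY <- momentum * dY - eta * gains * grad
      Y <- Y + dY
      Y <- sweep(Y, 2, colMeans(Y))
      if (it == 100) momentum <- 0.8
    }
    Y
  })
}
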
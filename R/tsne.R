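# Exact (quadratic-cost) t-SNE. Suitable for the cohort sizes this package
# targets (a few thousand points); no Barnes-Hut approximation.

# Conditional probabilities with per-point precision found by binary search
# so every row has the target perplexity.
tsne_p_matrix <- function(D2, perplexity, tol = 1e-5) {
  n <- nrow(D2)
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { H <- 0; p <- w } else {
        p <- w / sw
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(H - logU) < tol) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

# Gradient-descent t-SNE with early exaggeration and momentum switching.
tsne_embed <- function(X, perplexity = 30, max_iter = 300, lr = 100,
                       seed = 1L, pca_dims = 50) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n - 1 < 3 * perplexity) {
    stop("t-SNE needs n >= 3 * perplexity + 1 = ", 3 * perplexity + 1,
         " points (got ", n, ")")
  }
  with_seed(seed, {
    if (ncol(X) > pca_dims) {
      X <- stats::prcomp(X, rank. = pca_dims)$x
    }
    D2 <- as.matrix(stats::dist(X))^2
    P <- tsne_p_matrix(D2, perplexity)
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    dY <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    exag_until <- max(20, round(max_iter / 4))
    for (iter in seq_len(max_iter)) {
      Pe <- if (iter <= exag_until) P * 12 else P
      num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (Pe - Q) * num
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      momentum <- if (iter <= 50) 0.5 else 0.8
      gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      dY <- momentum * dY - lr * gains * grad
      Y <- Y + dY
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}
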
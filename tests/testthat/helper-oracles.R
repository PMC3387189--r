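# Independent test oracles, kept free of the implementation paths they check.

# Brute-force maximum-likelihood sigma scan over every SDEM column, written
# directly from the definition (normal-CDF mass on [U - a, U + a], indicator
# for degenerate cells, first maximum wins).
brute_infer_sigma <- function(U, k, sdem, alpha = 0.1) {
  k <- min(k, sdem$n_max)
  best_j <- NA_integer_
  best_L <- -Inf
  for (j in seq_along(sdem$sigma_grid)) {
    m <- sdem$mean[k, j]
    s <- sdem$sd[k, j]
    L <- if (s < 1e-9) {
      as.numeric(abs(U - m) <= alpha)
    } else {
      pnorm((U + alpha - m) / s) - pnorm((U - alpha - m) / s)
    }
    if (L > best_L) {
      best_L <- L
      best_j <- j
    }
  }
  c(sigma_hat = sdem$sigma_grid[best_j], likelihood = best_L)
}

# Plug-in entropy by direct evaluation over an explicit bin table.
brute_histogram_entropy <- function(offsets) {
  p <- as.vector(table(offsets)) / length(offsets)
  -sum(p * log(p))
}
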
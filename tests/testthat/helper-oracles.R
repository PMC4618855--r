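# Brute-force affinity oracle: plain double loops, per-row bisection on
# the precision following the same documented search rule as the
# implementation (start 1, double/halve to bracket, then bisect).
oracle_affinities <- function(X, perplexity) {
  n <- nrow(X)
  D2 <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    D2[i, j] <- max(sum((X[i, ] - X[j, ])^2), 1e-12)
  Pc <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    for (iter in 1:64) {
      p <- numeric(n)
      m <- min(D2[i, -i])
      for (j in seq_len(n)) if (j != i)
        p[j] <- exp(-beta * (D2[i, j] - m))
      p <- p / sum(p)
      H <- 0
      for (j in seq_len(n)) if (p[j] > 0) H <- H - p[j] * log(p[j])
      if (abs(exp(H) - perplexity) <= 1e-12) break
      if (exp(H) > perplexity) {
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    Pc[i, ] <- p
  }
  (Pc + t(Pc)) / (2 * n)
}

oracle_kl <- function(P, Y) {
  n <- nrow(Y)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    W[i, j] <- 1 / (1 + max(sum((Y[i, ] - Y[j, ])^2), 1e-12))
  Q <- W / sum(W)
  kl <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (P[i, j] > 0) kl <- kl + P[i, j] * log(P[i, j] / Q[i, j])
  kl
}
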
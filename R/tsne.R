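# Exact t-distributed stochastic neighbour embedding to 2-D.
#
# n here is a few thousand at most, so the O(n^2) exact algorithm is used
# throughout; no Barnes-Hut or interpolation approximations.

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the previous RNG state, so
#' that seeded internals never perturb the caller's random stream.
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(seed)
  code
}

# Squared Euclidean distance matrix with an off-diagonal floor so that
# duplicated points cannot produce infinite precisions or divisions by 0.
.sq_dist <- function(X, floor = 1e-12) {
  s <- rowSums(X^2)
  D2 <- outer(s, s, "+") - 2 * tcrossprod(X)
  D2[D2 < floor] <- floor
  diag(D2) <- 0
  D2
}

#' Input-space affinities for t-SNE
#'
#' Builds the symmetric joint probabilities `p_ij` over pairs of points:
#' per-row Gaussian conditionals whose bandwidth is calibrated by binary
#' search so that the conditional distribution's perplexity (`2^H`, a
#' smooth effective-neighbour count) matches the target, then symmetrised
#' as `(p_{j|i} + p_{i|j}) / (2n)`.
#'
#' @param X Numeric matrix (n x d), n >= 3.
#' @param perplexity Target perplexity, in (1, n).
#' @param tol Tolerance on the achieved perplexity (default `1e-4`).
#' @param max_iter Maximum binary-search iterations per point.
#' @return List with `P` (n x n symmetric, zero diagonal, sums to 1),
#'   `sigmas` (per-point Gaussian bandwidths) and `perplexity`.
#' @export
tsne_affinities <- function(X, perplexity, tol = 1e-4, max_iter = 64L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  if (perplexity <= 1 || perplexity >= n)
    stop("perplexity must be in (1, n); got ", perplexity, " with n = ", n,
         call. = FALSE)
  D2 <- .sq_dist(X)
  Pc <- matrix(0, n, n)
  betas <- numeric(n)            # beta = 1 / (2 sigma^2)
  for (i in seq_len(n)) {
    d2 <- D2[i, -i]
    beta <- 1; lo <- -Inf; hi <- Inf
    for (iter in seq_len(max_iter)) {
      w <- exp(-beta * (d2 - min(d2)))
      p <- w / sum(w)
      H <- -sum(p[p > 0] * log(p[p > 0]))     # entropy in nats
      achieved <- exp(H)
      # iterate to machine convergence (well inside `tol`)
      if (abs(achieved - perplexity) <= 1e-12) break
      if (achieved > perplexity) {            # too flat: raise precision
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    betas[i] <- beta
    Pc[i, -i] <- p
  }
  P <- (Pc + t(Pc)) / (2 * n)
  list(P = P, sigmas = sqrt(1 / (2 * betas)), perplexity = perplexity)
}

# Low-dimensional similarities: Student-t kernel with one degree of
# freedom, normalised over off-diagonal pairs. Returns W (unnormalised)
# and Q.
.tsne_q <- function(Y) {
  W <- 1 / (1 + .sq_dist(Y))
  diag(W) <- 0
  list(W = W, Q = W / sum(W))
}

#' Kullback-Leibler divergence of a t-SNE embedding
#'
#' The information lost when the Student-t similarities of the 2-D layout
#' `Y` stand in for the input-space affinities `P`:
#' `sum over p_ij > 0 of p_ij log(p_ij / q_ij)`. Non-negative by Gibbs'
#' inequality; zero only when the two distributions coincide.
#'
#' @param P Symmetric joint affinity matrix (see [tsne_affinities()]).
#' @param Y Numeric matrix (n x 2) of embedding coordinates.
#' @return Non-negative scalar.
#' @export
tsne_kl <- function(P, Y) {
  if (!all(is.finite(Y))) stop("non-finite embedding coordinates",
                               call. = FALSE)
  Q <- .tsne_q(as.matrix(Y))$Q
  sel <- P > 0
  sum(P[sel] * log(P[sel] / pmax(Q[sel], .Machine$double.xmin)))
}

#' Exact t-SNE embedding to two dimensions
#'
#' Minimises the KL divergence between input-space Gaussian affinities and
#' 2-D Student-t similarities by gradient descent with momentum, adaptive
#' per-coordinate gains, and early exaggeration. Deterministic given
#' `seed`.
#'
#' Optimiser defaults follow the original algorithm's conventions:
#' 1000 iterations, learning rate 200, momentum 0.5 switching to 0.8 at
#' iteration 250, affinities multiplied by 4 for the first 100 iterations,
#' and initial coordinates drawn from N(0, 1e-4).
#'
#' @param X Numeric matrix (n x d), n >= 5 (rows are observations).
#' @param perplexity Target perplexity (default 30).
#' @param seed Integer seed for the random initialisation.
#' @param iters Gradient-descent iterations.
#' @param learning_rate Step size.
#' @param momentum,final_momentum,momentum_switch Momentum schedule.
#' @param exaggeration,exaggeration_iters Early-exaggeration factor and
#'   duration.
#' @return Object of class `tsne_embedding`: list with `Y` (n x 2),
#'   `kl_final`, `kl_initial` (both on the unexaggerated affinities),
#'   `perplexity`, `seed`, `iters`.
#' @examples
#' X <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 8), 20))
#' emb <- tsne(X, perplexity = 10, seed = 1, iters = 300)
#' emb$kl_final <= emb$kl_initial
#' @export
tsne <- function(X, perplexity = 30, seed = 1L, iters = 1000L,
                 learning_rate = 200, momentum = 0.5,
                 final_momentum = 0.8, momentum_switch = 250L,
                 exaggeration = 4, exaggeration_iters = 100L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 5L) stop("need at least 5 points", call. = FALSE)
  aff <- tsne_affinities(X, perplexity)
  P <- aff$P

  Y <- with_seed(seed, matrix(stats::rnorm(n * 2L, sd = 1e-2), n, 2L))
  kl_initial <- tsne_kl(P, Y)

  dY <- matrix(0, n, 2L)
  gains <- matrix(1, n, 2L)
  for (t in seq_len(iters)) {
    Pt <- if (t <= exaggeration_iters) P * exaggeration else P
    q <- .tsne_q(Y)
    L <- (Pt - q$Q) * q$W   # exaggeration overweights attractive forces
    grad <- 4 * (rowSums(L) * Y - L %*% Y)
    if (!all(is.finite(grad)))
      stop("non-finite gradient at iteration ", t, call. = FALSE)
    mom <- if (t < momentum_switch) momentum else final_momentum
    same <- sign(grad) == sign(dY)
    gains <- ifelse(same, gains * 0.8, gains + 0.2)
    gains[gains < 0.01] <- 0.01
    dY <- mom * dY - learning_rate * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  structure(
    list(Y = Y, kl_final = tsne_kl(P, Y), kl_initial = kl_initial,
         perplexity = perplexity, seed = as.integer(seed),
         iters = as.integer(iters), sigmas = aff$sigmas),
    class = "tsne_embedding")
}

#' @export
print.tsne_embedding <- function(x, ...) {
  cat("t-SNE embedding: ", nrow(x$Y), " points, perplexity ",
      x$perplexity, ", seed ", x$seed, "\n",
      "  KL divergence ", format(x$kl_initial, digits = 4), " -> ",
      format(x$kl_final, digits = 4), " after ", x$iters,
      " iterations\n", sep = "")
  invisible(x)
}

#' @export
plot.tsne_embedding <- function(x, col = 1, pch = 16, ...) {
  graphics::plot(x$Y, col = col, pch = pch, xlab = "t-SNE 1",
                 ylab = "t-SNE 2",
                 main = paste0("t-SNE (perplexity ", x$perplexity, ")"),
                 ...)
  invisible(x)
}

#' Perplexity sweep with a cluster-count selection rule
#'
#' Typical perplexities lie between 5 and 50. The sweep embeds the data at
#' each candidate value, clusters every embedding, and keeps the
#' perplexity at which the clustering identifies the largest number of
#' components — the value that best spreads and separates the
#' observations. Ties are broken toward the smallest perplexity.
#'
#' @param X Numeric matrix (n x d).
#' @param values Candidate perplexities (default 5 to 50 in steps of 5);
#'   values >= n are dropped with a warning.
#' @param cluster_fn Function mapping an embedding's `n x 2` coordinate
#'   matrix to a fitted object with a component count `$G` (default:
#'   [gmm_select()] with its defaults).
#' @param seed Seed passed to every [tsne()] call.
#' @param ... Further arguments passed to [tsne()].
#' @return List with `perplexity` (chosen value), `embedding` (its
#'   [tsne()] result), `G` (named integer vector of component counts per
#'   candidate) and `models` (the fitted clusterings).
#' @export
perplexity_sweep <- function(X, values = seq(5, 50, by = 5),
                             cluster_fn = NULL, seed = 1L, ...) {
  X <- as.matrix(X)
  ok <- values > 1 & values < nrow(X)
  if (!any(ok)) stop("no admissible perplexity value", call. = FALSE)
  if (!all(ok)) {
    warning("dropping perplexity value(s) >= n: ",
            paste(values[!ok], collapse = ", "))
    values <- values[ok]
  }
  if (is.null(cluster_fn))
    cluster_fn <- function(Y) gmm_select(Y, seed = seed)
  embeddings <- vector("list", length(values))
  models <- vector("list", length(values))
  G <- rep(NA_integer_, length(values))
  names(G) <- values
  for (i in seq_along(values)) {
    emb <- tsne(X, perplexity = values[i], seed = seed, ...)
    fit <- tryCatch(cluster_fn(emb$Y), error = function(e) NULL)
    embeddings[[i]] <- emb
    models[[i]] <- fit
    if (!is.null(fit)) G[i] <- fit$G
  }
  if (all(is.na(G))) stop("clustering failed at every perplexity",
                          call. = FALSE)
  best <- which(G == max(G, na.rm = TRUE))[1L]   # ties: smallest value
  list(perplexity = values[best], embedding = embeddings[[best]],
       G = G, models = models)
}
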
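# Gaussian mixture modelling under the ten constrained covariance
# parameterisations obtained from the eigenvalue decomposition
#   Sigma_k = lambda_k D_k A_k D_k'
# (lambda volume, A shape with det A = 1, D orientation). The family code
# letters state whether volume, shape and orientation are Equal across
# components, Variable, or the Identity (spherical / coordinate axes).

.gmm_family_codes <- c("EII", "VII", "EEI", "VEI", "EVI",
                       "VVI", "EEE", "EEV", "VEV", "VVV")

#' The ten covariance families
#'
#' @return Data frame with one row per family: `code`, `distribution`
#'   (spherical / diagonal / ellipsoidal), `volume`, `shape`,
#'   `orientation`.
#' @export
gmm_families <- function() {
  data.frame(
    code = .gmm_family_codes,
    distribution = c("spherical", "spherical", "diagonal", "diagonal",
                     "diagonal", "diagonal", "ellipsoidal", "ellipsoidal",
                     "ellipsoidal", "ellipsoidal"),
    volume = c("equal", "variable", "equal", "variable", "equal",
               "variable", "equal", "equal", "variable", "variable"),
    shape = c("equal", "equal", "equal", "equal", "variable", "variable",
              "equal", "equal", "equal", "variable"),
    orientation = c("none", "none", "coordinate axes", "coordinate axes",
                    "coordinate axes", "coordinate axes", "equal",
                    "variable", "variable", "variable"),
    stringsAsFactors = FALSE
  )
}

#' Free parameter count of a constrained Gaussian mixture
#'
#' `(G - 1)` mixing weights, `G * d` means, plus the covariance
#' parameters implied by the family's volume/shape/orientation
#' constraints.
#'
#' @param family Family code (one of `r paste(.gmm_family_codes)`).
#' @param G Number of components.
#' @param d Dimensionality.
#' @return Integer parameter count.
#' @examples
#' gmm_n_params("EII", G = 2, d = 2)   # 1 + 4 + 1 = 6
#' @export
gmm_n_params <- function(family, G, d) {
  family <- match.arg(family, .gmm_family_codes)
  cov_pars <- switch(family,
    EII = 1,
    VII = G,
    EEI = d,
    VEI = G + (d - 1),
    EVI = 1 + G * (d - 1),
    VVI = G * d,
    EEE = d * (d + 1) / 2,
    EEV = G * d * (d - 1) / 2 + (d - 1) + 1,
    VEV = G * d * (d - 1) / 2 + (d - 1) + G,
    VVV = G * d * (d + 1) / 2)
  as.integer((G - 1) + G * d + cov_pars)
}

#' Bayesian Information Criterion of a fitted mixture
#'
#' `BIC = 2 * loglik - n_params * log(n)`; larger is better under this
#' sign convention.
#'
#' @param loglik Maximised log-likelihood.
#' @param n_params Free parameter count (see [gmm_n_params()]).
#' @param n Sample size.
#' @return Scalar BIC.
#' @export
gmm_bic <- function(loglik, n_params, n) 2 * loglik - n_params * log(n)

# log N(x; mu, Sigma) for all rows of X; Sigma via Cholesky.
.log_dmvnorm <- function(X, mu, Sigma) {
  d <- ncol(X)
  R <- chol(Sigma)
  xc <- t(X) - mu
  quad <- colSums(backsolve(R, xc, transpose = TRUE)^2)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(R))) + quad)
}

# E-step: responsibilities and observed-data log-likelihood.
.gmm_estep <- function(X, weights, means, covariances) {
  n <- nrow(X); G <- length(weights)
  lp <- matrix(NA_real_, n, G)
  for (k in seq_len(G))
    lp[, k] <- log(weights[k]) + .log_dmvnorm(X, means[k, ], covariances[, , k])
  m <- apply(lp, 1L, max)
  lse <- m + log(rowSums(exp(lp - m)))
  list(z = exp(lp - lse), loglik = sum(lse))
}

# Floor the eigenvalues of a covariance at reg (degeneracy guard).
.pd_floor <- function(S, reg) {
  e <- eigen(S, symmetric = TRUE)
  if (all(e$values >= reg)) return(S)
  v <- pmax(e$values, reg)
  e$vectors %*% (v * t(e$vectors))
}

# det(A)^(1/d) via logs; A given as its diagonal (vector) here.
.gmean <- function(v) exp(mean(log(pmax(v, 1e-300))))

# M-step covariance update for one family. W is the list of G scatter
# matrices sum_i z_ik (x_i - mu_k)(x_i - mu_k)'; nk the component masses.
.gmm_cov_mstep <- function(family, W, nk, n, d, inner_iter = 20L) {
  G <- length(W)
  Sig <- array(NA_real_, c(d, d, G))
  set_all <- function(S) for (k in seq_len(G)) Sig[, , k] <<- S
  diag_mat <- function(v) diag(v, nrow = d)

  if (family == "EII") {
    lambda <- sum(vapply(W, function(w) sum(diag(w)), 0)) / (n * d)
    set_all(diag_mat(rep(lambda, d)))
  } else if (family == "VII") {
    for (k in seq_len(G))
      Sig[, , k] <- diag_mat(rep(sum(diag(W[[k]])) / (nk[k] * d), d))
  } else if (family == "EEI") {
    dw <- Reduce(`+`, lapply(W, diag))
    set_all(diag_mat(dw / n))
  } else if (family == "VEI") {
    # no joint closed form: alternate volume lambda_k and common shape A
    dwk <- vapply(W, diag, numeric(d))            # d x G
    lambda <- colSums(dwk) / (nk * d)
    a <- rep(1, d)
    for (it in seq_len(inner_iter)) {
      v <- rowSums(sweep(dwk, 2L, lambda, "/"))
      a <- v / .gmean(v)                          # det A = 1
      lambda <- colSums(dwk / a) / (nk * d)
    }
    for (k in seq_len(G)) Sig[, , k] <- diag_mat(lambda[k] * a)
  } else if (family == "EVI") {
    dwk <- vapply(W, diag, numeric(d))
    gm <- apply(dwk, 2L, .gmean)                  # |diag W_k|^(1/d)
    lambda <- sum(gm) / n
    for (k in seq_len(G))
      Sig[, , k] <- diag_mat(lambda * dwk[, k] / gm[k])
  } else if (family == "VVI") {
    for (k in seq_len(G)) Sig[, , k] <- diag_mat(diag(W[[k]]) / nk[k])
  } else if (family == "EEE") {
    set_all(Reduce(`+`, W) / n)
  } else if (family == "VVV") {
    for (k in seq_len(G)) Sig[, , k] <- W[[k]] / nk[k]
  } else if (family %in% c("EEV", "VEV")) {
    eig <- lapply(W, function(w) eigen((w + t(w)) / 2, symmetric = TRUE))
    Om <- vapply(eig, function(e) pmax(e$values, 0), numeric(d))  # d x G
    if (family == "EEV") {
      c_vec <- rowSums(Om) / n                    # lambda * A
      for (k in seq_len(G))
        Sig[, , k] <- eig[[k]]$vectors %*% (c_vec * t(eig[[k]]$vectors))
    } else {
      lambda <- colSums(Om) / (nk * d)
      a <- rep(1, d)
      for (it in seq_len(inner_iter)) {
        v <- rowSums(sweep(Om, 2L, lambda, "/"))
        a <- v / .gmean(v)
        lambda <- colSums(Om / a) / (nk * d)
      }
      for (k in seq_len(G))
        Sig[, , k] <- eig[[k]]$vectors %*% ((lambda[k] * a) *
                                            t(eig[[k]]$vectors))
    }
  }
  Sig
}

# k-means++ seeding followed by a short Lloyd refinement; returns hard
# labels in 1..G.
.kmeanspp_labels <- function(X, G, seed) {
  n <- nrow(X)
  with_seed(seed, {
    centers <- matrix(NA_real_, G, ncol(X))
    centers[1L, ] <- X[sample.int(n, 1L), ]
    if (G > 1L) {
      d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
      for (k in 2L:G) {
        p <- d2 / sum(d2)
        if (!all(is.finite(p)) || sum(d2) == 0)
          p <- rep(1 / n, n)
        centers[k, ] <- X[sample.int(n, 1L, prob = p), ]
        d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[k, ])^2))
      }
    }
    km <- tryCatch(
      suppressWarnings(stats::kmeans(X, centers = centers, iter.max = 10L)),
      error = function(e) NULL)
    if (is.null(km)) sample.int(G, n, replace = TRUE) else km$cluster
  })
}

.gmm_em_once <- function(X, G, family, z, tol, max_iter, reg) {
  n <- nrow(X); d <- ncol(X)
  trace <- numeric(0)
  ll <- -Inf
  weights <- NULL; means <- NULL; covariances <- NULL
  for (iter in seq_len(max_iter)) {
    nk <- colSums(z)
    if (any(nk < 1)) return(list(failed = TRUE, why = "component collapse"))
    weights <- nk / n
    means <- crossprod(z, X) / nk                 # G x d
    W <- vector("list", G)
    for (k in seq_len(G)) {
      xc <- sweep(X, 2L, means[k, ])
      W[[k]] <- crossprod(xc * z[, k], xc)
    }
    covariances <- .gmm_cov_mstep(family, W, nk, n, d)
    for (k in seq_len(G))
      covariances[, , k] <- .pd_floor((covariances[, , k] +
                                       t(covariances[, , k])) / 2, reg)
    es <- tryCatch(.gmm_estep(X, weights, means, covariances),
                   error = function(e) NULL)
    if (is.null(es) || !is.finite(es$loglik))
      return(list(failed = TRUE, why = "non-finite likelihood"))
    trace <- c(trace, es$loglik)
    if (is.finite(ll) && abs(es$loglik - ll) < tol * abs(es$loglik)) {
      ll <- es$loglik; z <- es$z
      return(list(failed = FALSE, weights = weights, means = means,
                  covariances = covariances, loglik = ll, z = es$z,
                  trace = trace, iterations = iter, converged = TRUE))
    }
    ll <- es$loglik
    z <- es$z
  }
  list(failed = FALSE, weights = weights, means = means,
       covariances = covariances, loglik = ll, z = z, trace = trace,
       iterations = max_iter, converged = FALSE)
}

#' Fit a Gaussian mixture under one covariance family
#'
#' Expectation-Maximisation under the family's covariance constraints.
#' The E-step computes component responsibilities; the M-step solves the
#' constrained covariance update (eigen-decomposition based for
#' EEV/VEV; a 20-step fixed-point alternation between volume and shape
#' for VEI, which has no joint closed form). Initialisation is k-means++
#' hard assignment converted to responsibilities, with `restarts`
#' independent starts and the best final log-likelihood kept; the fit is
#' reproducible given `seed`.
#'
#' @param X Numeric matrix (n x d), `n > G * d`.
#' @param G Number of components.
#' @param family Covariance family code (see [gmm_families()]).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per start.
#' @param reg Eigenvalue floor applied to every covariance (degeneracy
#'   guard).
#' @param restarts Number of k-means++ initialisations; a start whose
#'   components collapse (mass below one observation) is discarded and a
#'   fresh one drawn, and the fit errors only if every start fails.
#' @param seed Integer seed.
#' @return Object of class `phenoflag_gmm`: `family`, `G`, `d`,
#'   `weights`, `means` (G x d), `covariances` (d x d x G), `loglik`,
#'   `loglik_trace` (per accepted iteration of the winning start),
#'   `n_params`, `bic`, `n`, `z` (responsibilities), `converged`,
#'   `iterations`, `seed`.
#' @examples
#' X <- rbind(matrix(rnorm(100, 0), ncol = 2),
#'            matrix(rnorm(100, 6), ncol = 2))
#' fit <- gmm_fit(X, G = 2, family = "EII", seed = 1)
#' fit$bic
#' @export
gmm_fit <- function(X, G, family = "VVV", tol = 1e-8, max_iter = 500L,
                    reg = 1e-6, restarts = 5L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  family <- match.arg(family, .gmm_family_codes)
  if (n <= G * d)
    stop("need n > G * d (n = ", n, ", G = ", G, ", d = ", d, ")",
         call. = FALSE)
  best <- NULL
  fails <- character(0)
  for (r in seq_len(restarts)) {
    z <- if (G == 1L) matrix(1, n, 1L) else {
      lab <- .kmeanspp_labels(X, G, seed = seed * 131L + r)
      zz <- matrix(0, n, G)
      zz[cbind(seq_len(n), lab)] <- 1
      zz
    }
    fit <- .gmm_em_once(X, G, family, z, tol, max_iter, reg)
    if (isTRUE(fit$failed)) { fails <- c(fails, fit$why); next }
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
    if (G == 1L) break                    # deterministic: no need to restart
  }
  if (is.null(best))
    stop("all ", restarts, " starts failed for ", family, " G = ", G,
         " (", paste(unique(fails), collapse = "; "), ")", call. = FALSE)
  npar <- gmm_n_params(family, G, d)
  structure(
    list(family = family, G = as.integer(G), d = d,
         weights = as.numeric(best$weights), means = best$means,
         covariances = best$covariances, loglik = best$loglik,
         loglik_trace = best$trace, n_params = npar,
         bic = gmm_bic(best$loglik, npar, n), n = n, z = best$z,
         converged = best$converged, iterations = best$iterations,
         seed = as.integer(seed)),
    class = "phenoflag_gmm")
}

#' Select a mixture by BIC over families and component counts
#'
#' Fits every requested (family, G) pair and returns the fit maximising
#' `2 * loglik - n_params * log(n)`; ties are broken toward fewer
#' parameters, then toward the canonical family order. Pairs whose fit
#' fails are recorded and skipped.
#'
#' @param X Numeric matrix (n x d).
#' @param G_range Candidate component counts (default 1..50, capped so
#'   that `n > G * d`).
#' @param families Family codes to try (default all ten).
#' @param ... Passed to [gmm_fit()] (e.g. `restarts`, `tol`).
#' @param seed Integer seed.
#' @return The winning `phenoflag_gmm`, with extra elements `bic_table`
#'   (families x G matrix of BIC values, `NA` where the fit failed),
#'   `bic_by_family` (per-family maximum over G) and `failures`.
#' @export
gmm_select <- function(X, G_range = 1:50, families = .gmm_family_codes,
                       seed = 1L, ...) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  families <- match.arg(families, .gmm_family_codes, several.ok = TRUE)
  G_range <- sort(unique(as.integer(G_range)))
  G_range <- G_range[G_range >= 1L & G_range * d < n]
  if (length(G_range) == 0L) stop("empty admissible G_range", call. = FALSE)
  bic_table <- matrix(NA_real_, length(families), length(G_range),
                      dimnames = list(families, G_range))
  fits <- list()
  failures <- character(0)
  for (fam in families) for (g in G_range) {
    fit <- tryCatch(gmm_fit(X, G = g, family = fam, seed = seed, ...),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      failures <- c(failures,
                    paste0(fam, "/G=", g, ": ", conditionMessage(fit)))
      next
    }
    bic_table[fam, as.character(g)] <- fit$bic
    fits[[paste(fam, g)]] <- fit
  }
  if (length(fits) == 0L)
    stop("every (family, G) fit failed:\n  ",
         paste(failures, collapse = "\n  "), call. = FALSE)
  cand <- do.call(rbind, lapply(fits, function(f)
    data.frame(family = f$family, G = f$G, bic = f$bic,
               n_params = f$n_params)))
  cand$fam_rank <- match(cand$family, .gmm_family_codes)
  ord <- order(-cand$bic, cand$n_params, cand$fam_rank)
  winner <- fits[[rownames(cand)[ord[1L]]]]
  winner$bic_table <- bic_table
  winner$bic_by_family <- apply(bic_table, 1L, function(r)
    if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  winner$failures <- failures
  winner
}

#' Posterior component membership of observations
#'
#' Posterior probability of each component, the hard label (its argmax),
#' and the clustering uncertainty `1 - max(posterior)`.
#'
#' @param model A fitted `phenoflag_gmm`.
#' @param X Numeric matrix of points to classify (default: `NULL`, not
#'   available; pass the data explicitly).
#' @return Data frame with `label` (integer), `uncertainty`, and a
#'   `posterior` matrix attribute (n x G, rows summing to 1).
#' @export
gmm_assign <- function(model, X) {
  stopifnot(inherits(model, "phenoflag_gmm"))
  X <- as.matrix(X)
  es <- .gmm_estep(X, model$weights, model$means, model$covariances)
  lab <- max.col(es$z, ties.method = "first")
  out <- data.frame(label = lab,
                    uncertainty = 1 - es$z[cbind(seq_len(nrow(X)), lab)])
  attr(out, "posterior") <- es$z
  out
}

#' Partition assignments by clustering uncertainty
#'
#' Points whose uncertainty exceeds the threshold could be either
#' inconsistent or simply mis-clustered, so they are set aside rather
#' than judged: strictly greater than `threshold` (default 0.5) is
#' ignored.
#'
#' @param assignments Data frame from [gmm_assign()].
#' @param threshold Uncertainty cut-off; strict inequality.
#' @return List with integer index vectors `retained` and `ignored`.
#' @export
uncertainty_filter <- function(assignments, threshold = 0.5) {
  ig <- which(assignments$uncertainty > threshold)
  list(retained = setdiff(seq_len(nrow(assignments)), ig), ignored = ig)
}

#' @export
print.phenoflag_gmm <- function(x, ...) {
  fam <- gmm_families()
  row <- fam[fam$code == x$family, ]
  cat("Gaussian mixture (", x$family, "): ", row$distribution,
      ", volume ", row$volume, ", shape ", row$shape,
      if (row$orientation != "none") paste0(", orientation ",
                                            row$orientation),
      "\n", sep = "")
  cat("  G = ", x$G, " components, d = ", x$d, ", n = ", x$n, "\n",
      "  log-likelihood ", format(x$loglik, digits = 8),
      ", ", x$n_params, " parameters, BIC ",
      format(x$bic, digits = 8), "\n", sep = "")
  if (!x$converged) cat("  (EM did not converge in ", x$iterations,
                        " iterations)\n", sep = "")
  invisible(x)
}

#' @export
summary.phenoflag_gmm <- function(object, ...) {
  print(object)
  cat("  mixing weights:", paste(format(object$weights, digits = 3),
                                 collapse = " "), "\n")
  sizes <- tabulate(max.col(object$z), nbins = object$G)
  cat("  hard-label sizes:", paste(sizes, collapse = " "), "\n")
  invisible(object)
}

#' @export
logLik.phenoflag_gmm <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n,
            class = "logLik")
}

#' @rdname gmm_assign
#' @param object,newdata,... `predict` method arguments; `newdata` is the
#'   matrix of points to classify.
#' @export
predict.phenoflag_gmm <- function(object, newdata, ...) {
  gmm_assign(object, newdata)
}

#' Simulate draws from a fitted (or constructed) mixture
#'
#' @param object A `phenoflag_gmm` (fitted, or built by
#'   [simulate_family_parameters()]).
#' @param nsim Number of draws.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return Matrix (nsim x d) with attribute `component` (true component
#'   index per row).
#' @export
simulate.phenoflag_gmm <- function(object, nsim = 1L, seed = 1L, ...) {
  d <- object$d; G <- object$G
  with_seed(seed, {
    comp <- sample.int(G, nsim, replace = TRUE, prob = object$weights)
    X <- matrix(NA_real_, nsim, d)
    for (k in seq_len(G)) {
      idx <- which(comp == k)
      if (length(idx) == 0L) next
      R <- chol(object$covariances[, , k])
      Z <- matrix(stats::rnorm(length(idx) * d), length(idx), d)
      X[idx, ] <- sweep(Z %*% R, 2L, object$means[k, ], "+")
    }
    attr(X, "component") <- comp
    X
  })
}

#' @export
plot.phenoflag_gmm <- function(x, X = NULL, ...) {
  if (is.null(X)) {
    graphics::barplot(x$weights, names.arg = seq_len(x$G),
                      xlab = "component", ylab = "mixing weight", ...)
    return(invisible(x))
  }
  lab <- gmm_assign(x, X)$label
  graphics::plot(X[, 1:2], col = lab, pch = 16,
                 xlab = colnames(X)[1], ylab = colnames(X)[2], ...)
  graphics::points(x$means[, 1:2], pch = 3, cex = 2)
  invisible(x)
}
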
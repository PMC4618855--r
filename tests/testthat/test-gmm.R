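test_that("free-parameter counts match hand enumeration and mclust", {
  expect_equal(gmm_n_params("EII", 2, 2), 6L)   # 1 + 4 + 1
  expect_equal(gmm_n_params("VVV", 1, 2), 5L)   # 0 + 2 + 3
  expect_equal(gmm_n_params("VEI", 3, 2), 12L)  # 2 + 6 + (3 + 1)
  skip_if_not_installed("mclust")
  for (fam in gmm_families()$code)
    for (G in 1:3) for (d in 2:3)
      expect_equal(gmm_n_params(fam, G, d),
                   mclust::nMclustParams(fam, d, G),
                   info = paste(fam, G, d))
})

test_that("BIC follows the 2L - k log n convention", {
  expect_equal(gmm_bic(0, 0, 100), 0)
  expect_equal(gmm_bic(-50, 4, 100) - gmm_bic(-50, 8, 100), 4 * log(100))
  # single 1-D Gaussian: closed-form maximum likelihood
  phenoflag:::with_seed(2, {
    x <- matrix(rnorm(80), ncol = 1)
    fit <- gmm_fit(x, G = 1, family = "EII")
    mu <- mean(x); s2 <- mean((x - mu)^2)   # MLE variance, not sample
    ll <- sum(dnorm(x, mu, sqrt(s2), log = TRUE))
    expect_equal(fit$loglik, ll, tolerance = 1e-8)
    expect_equal(fit$n_params, 2L)
    expect_equal(fit$bic, 2 * ll - 2 * log(80), tolerance = 1e-8)
  })
})

test_that("G = 1 fits reduce to the family-constrained single-Gaussian MLE", {
  phenoflag:::with_seed(5, {
    X <- matrix(rnorm(200), ncol = 2) %*% rbind(c(1, 0.4), c(0, 0.8))
    n <- nrow(X)
    S <- crossprod(sweep(X, 2, colMeans(X))) / n
    fit_vvv <- gmm_fit(X, 1, "VVV")
    expect_equal(fit_vvv$means[1, ], colMeans(X), tolerance = 1e-8)
    expect_equal(fit_vvv$covariances[, , 1], S, tolerance = 1e-8)
    fit_eii <- gmm_fit(X, 1, "EII")
    expect_equal(fit_eii$covariances[, , 1],
                 diag(rep(mean(diag(S)), 2)), tolerance = 1e-8)
    fit_eei <- gmm_fit(X, 1, "EEI")
    expect_equal(fit_eei$covariances[, , 1], diag(diag(S)),
                 tolerance = 1e-8)
  })
})

test_that("EM log-likelihood is non-decreasing for every family", {
  phenoflag:::with_seed(13, {
    for (rep in 1:3) {
      X <- rbind(matrix(rnorm(60, -2), ncol = 2),
                 matrix(rnorm(60, 2), ncol = 2))
      for (fam in gmm_families()$code) {
        fit <- gmm_fit(X, G = 2, family = fam, seed = rep)
        dll <- diff(fit$loglik_trace)
        expect_true(all(dll >= -1e-8 * pmax(1, abs(fit$loglik))),
                    info = fam)
      }
    }
  })
})

test_that("fitted covariances satisfy their family constraints", {
  tol <- 1e-8
  norm_shape <- function(S) {
    v <- diag(S); v / exp(mean(log(v)))
  }
  phenoflag:::with_seed(17, {
    X <- rbind(matrix(rnorm(150, -3, 1.5), ncol = 2),
               matrix(rnorm(150, 3, 0.7), ncol = 2),
               cbind(rnorm(75, 0, 2), rnorm(75, 8, 0.5)))
    for (fam in gmm_families()$code) {
      fit <- gmm_fit(X, G = 3, family = fam, seed = 3)
      Sig <- fit$covariances
      offdiag <- function(k) max(abs(Sig[, , k][lower.tri(Sig[, , k])]))
      for (k in 1:3) {
        ev <- eigen(Sig[, , k], symmetric = TRUE, only.values = TRUE)$values
        expect_true(all(ev > 0), info = fam)
        expect_lt(max(abs(Sig[, , k] - t(Sig[, , k]))), tol)
      }
      if (fam %in% c("EII", "VII"))
        for (k in 1:3) {
          expect_lt(offdiag(k), tol)
          expect_lt(abs(Sig[1, 1, k] - Sig[2, 2, k]), tol)
        }
      if (fam %in% c("EEI", "VEI", "EVI", "VVI"))
        for (k in 1:3) expect_lt(offdiag(k), tol)
      if (fam %in% c("EII", "EEI", "EEE"))
        for (k in 2:3)
          expect_lt(max(abs(Sig[, , k] - Sig[, , 1])), tol)
      if (fam == "VEI")   # common shape after volume normalisation
        for (k in 2:3)
          expect_lt(max(abs(norm_shape(Sig[, , k]) -
                            norm_shape(Sig[, , 1]))), 1e-6)
      if (fam == "EVI") { # common volume det^(1/d)
        dets <- apply(Sig, 3, function(S) det(S)^(1 / 2))
        expect_lt(max(abs(dets - dets[1])), 1e-6)
      }
      if (fam %in% c("EEV", "VEV")) {  # shared eigenvalue shape
        evs <- apply(Sig, 3, function(S)
          eigen(S, symmetric = TRUE, only.values = TRUE)$values)
        shp <- apply(evs, 2, function(v) v / exp(mean(log(v))))
        for (k in 2:3)
          expect_lt(max(abs(shp[, k] - shp[, 1])), 1e-6)
        if (fam == "EEV")
          expect_lt(max(abs(evs[1, ] - evs[1, 1])) /
                      evs[1, 1], 1e-6)
      }
    }
  })
})

test_that("M-step updates agree with mclust on shared responsibilities", {
  skip_if_not_installed("mclust")
  phenoflag:::with_seed(23, {
    X <- rbind(matrix(rnorm(120, -2), ncol = 2),
               matrix(rnorm(120, 2, 1.6), ncol = 2))
    n <- nrow(X)
    z <- matrix(runif(n * 2), n)
    z <- z / rowSums(z)
    nk <- colSums(z)
    means <- crossprod(z, X) / nk
    W <- lapply(1:2, function(k) {
      xc <- sweep(X, 2, means[k, ])
      crossprod(xc * z[, k], xc)
    })
    for (fam in gmm_families()$code) {
      mine <- phenoflag:::.gmm_cov_mstep(fam, W, nk, n, 2)
      mstep_fam <- get(paste0("mstep", fam), envir = asNamespace("mclust"))
      ms <- mstep_fam(data = X, z = z)
      ref <- ms$parameters$variance$sigma
      if (is.null(ref)) {   # spherical/diagonal compact storage
        ref <- array(0, c(2, 2, 2))
        v <- ms$parameters$variance
        for (k in 1:2)
          ref[, , k] <- if (!is.null(v$Sigma)) v$Sigma else
            diag(if (length(v$sigmasq) > 1) rep(v$sigmasq[k], 2) else
                   rep(v$sigmasq, 2), 2)
      }
      tol <- if (fam %in% c("VEI", "VEV")) 1e-3 else 1e-6
      expect_equal(mine, ref, tolerance = tol, ignore_attr = TRUE,
                   info = fam)
    }
  })
})

test_that("posteriors match a brute-force density oracle", {
  phenoflag:::with_seed(31, {
    for (rep in 1:4) {
      X <- rbind(matrix(rnorm(40, -2), ncol = 2),
                 matrix(rnorm(40, 2), ncol = 2))
      fam <- sample(gmm_families()$code, 1)
      fit <- gmm_fit(X, 2, fam, seed = rep)
      a <- gmm_assign(fit, X)
      orc <- oracle_posterior(X, fit$weights, fit$means, fit$covariances)
      expect_equal(attr(a, "posterior"), orc$posterior, tolerance = 1e-10)
      expect_equal(fit$loglik,
                   phenoflag:::.gmm_estep(X, fit$weights, fit$means,
                                          fit$covariances)$loglik,
                   tolerance = 1e-8)
      expect_equal(rowSums(attr(a, "posterior")), rep(1, nrow(X)))
      expect_true(all(a$uncertainty >= 0 & a$uncertainty <= 0.5 + 1e-12))
    }
  })
})

test_that("assignment degenerate cases behave as symmetry dictates", {
  phenoflag:::with_seed(7, {
    X <- matrix(rnorm(60), ncol = 2)
    fit1 <- gmm_fit(X, 1, "VVV")
    expect_true(all(gmm_assign(fit1, X)$uncertainty == 0))
  })
  # a point exactly between two identical symmetric components
  m <- structure(list(family = "EII", G = 2L, d = 2L,
                      weights = c(0.5, 0.5),
                      means = rbind(c(-1, 0), c(1, 0)),
                      covariances = array(diag(2), c(2, 2, 2))),
                 class = "phenoflag_gmm")
  a <- gmm_assign(m, matrix(c(0, 0), 1))
  expect_equal(a$uncertainty, 0.5)
  expect_equal(attr(a, "posterior")[1, ], c(0.5, 0.5))
})

test_that("the uncertainty filter uses a strict threshold", {
  a <- data.frame(label = c(1L, 1L, 2L), uncertainty = c(0.1, 0.6, 0.5))
  p <- uncertainty_filter(a)
  expect_equal(p$retained, c(1L, 3L))
  expect_equal(p$ignored, 2L)
  expect_equal(uncertainty_filter(a, threshold = 0)$retained, integer(0) +
                 which(a$uncertainty == 0))
})

test_that("degenerate point-mass data is floored to the regularised covariance", {
  X <- matrix(1, 30, 2) + 0   # all points identical
  fit <- gmm_fit(X, 1, "EII", reg = 1e-6)
  expect_equal(fit$covariances[, , 1], diag(1e-6, 2), tolerance = 1e-9)
})

test_that("model selection picks parsimonious truth on easy fixtures", {
  # a single tight blob yields G = 1 whatever the family set
  X <- make_blobs(60, matrix(0, 1, 2), sd = 1, seed = 41)
  sel <- gmm_select(X, G_range = 1:3,
                    families = c("EII", "VVI", "VVV"), seed = 1,
                    restarts = 2)
  expect_equal(sel$G, 1L)
  expect_equal(dim(sel$bic_table), c(3L, 3L))
  expect_true(all(is.finite(sel$bic_by_family)))

  # the BIC table winner matches the returned model
  expect_equal(max(sel$bic_table, na.rm = TRUE), sel$bic)
})

test_that("parameter recovery on a well-separated equal-variance mixture", {
  phenoflag:::with_seed(47, {
    mu <- c(-4, 4)
    x <- matrix(c(rnorm(150, mu[1]), rnorm(150, mu[2])), ncol = 1)
    fit <- gmm_fit(x, 2, "EII", seed = 1)
    got <- sort(fit$means[, 1])
    se <- 1 / sqrt(150)
    expect_lt(max(abs(got - mu)), 3 * se)
  })
})

test_that("simulate() draws honour the mixture parameters", {
  par <- simulate_family_parameters("VVV", G = 2, d = 2, separation = 8,
                                    seed = 2)
  X <- simulate(par, nsim = 4000, seed = 3)
  comp <- attr(X, "component")
  for (k in 1:2) {
    expect_equal(colMeans(X[comp == k, ]), par$means[k, ],
                 tolerance = 0.15, ignore_attr = TRUE)
    expect_equal(cov(X[comp == k, ]), par$covariances[, , k],
                 tolerance = 0.15, ignore_attr = TRUE)
  }
  expect_identical(X, simulate(par, nsim = 4000, seed = 3))
})
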
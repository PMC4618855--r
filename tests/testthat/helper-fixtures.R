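# Shared fixture builders; everything is generated in code at test time.

# Gaussian blobs in d dimensions, one label per row.
make_blobs <- function(n_per, centers, sd = 1, seed = 1) {
  centers <- as.matrix(centers)
  phenoflag:::with_seed(seed, {
    X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k)
      sweep(matrix(rnorm(n_per * ncol(centers), sd = sd), n_per),
            2, centers[k, ], "+")))
    attr(X, "label") <- rep(seq_len(nrow(centers)), each = n_per)
    X
  })
}

# A small valid observation table.
make_obs <- function(n = 5, seed = 1) {
  phenoflag:::with_seed(seed, data.frame(
    obs_id = sprintf("o%02d", seq_len(n)),
    year = sample(1980:2013, n, replace = TRUE),
    onset_doy = sample(80:180, n, replace = TRUE),
    latitude = round(runif(n, 35, 47), 6),
    longitude = round(runif(n, -120, -70), 6),
    elevation = round(runif(n, 0, 2000), 2),
    onset_uncertainty_days = NA_integer_,
    multiple_onset = FALSE,
    stringsAsFactors = FALSE))
}

# Constant-parameter daily climate series for one location-year.
make_climate <- function(location_id, year, days = 1:365,
                         tmax = 10, tmin = 0, prcp = 1, vp = 500,
                         srad = 200, dayl = 43200, swe = 0) {
  data.frame(location_id = location_id, year = year, doy = days,
             tmax = tmax, tmin = tmin, prcp = prcp, vp = vp,
             srad = srad, dayl = dayl, swe = swe,
             stringsAsFactors = FALSE)
}

# Independent brute-force Gaussian mixture posterior/log-likelihood
# oracle: plain loops, solve() and det() instead of Cholesky.
oracle_posterior <- function(X, weights, means, covariances) {
  n <- nrow(X); G <- length(weights); d <- ncol(X)
  dens <- matrix(NA_real_, n, G)
  for (k in seq_len(G)) {
    S <- covariances[, , k]
    Sinv <- solve(S)
    nc <- 1 / sqrt((2 * pi)^d * det(S))
    for (i in seq_len(n)) {
      xc <- X[i, ] - means[k, ]
      dens[i, k] <- weights[k] * nc * exp(-0.5 * sum(xc * (Sinv %*% xc)))
    }
  }
  list(posterior = dens / rowSums(dens), loglik = sum(log(rowSums(dens))))
}
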
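# Synthetic phenology with known ground truth. The generator emulates the
# structure of a volunteered-phenology campaign: observation sites whose
# contextual conditions fall into separated clusters, daily climate series
# (seasonal sinusoids plus noise) whose accumulation reproduces that
# cluster structure, onset days driven by cluster and site climate with a
# planted long-term trend, and a planted fraction of inconsistent
# (shifted) onsets.

#' Construct mixture parameters for one covariance family
#'
#' Builds a `phenoflag_gmm` parameter object (usable with
#' [simulate.phenoflag_gmm()]) whose components genuinely exercise the
#' requested family's freedoms: volumes, shapes and orientations are
#' drawn distinct wherever the family allows them to vary, and held
#' shared where it does not. Component means are placed so that the
#' minimum pairwise separation is `separation` in units of the average
#' within-component standard deviation.
#'
#' @param family Covariance family code (see [gmm_families()]).
#' @param G Number of components.
#' @param d Dimensionality.
#' @param separation Minimum between-mean distance in pooled-sd units.
#' @param seed Integer seed.
#' @return A `phenoflag_gmm` object carrying `weights`, `means`,
#'   `covariances` (and `family`, `G`, `d`); likelihood fields are `NA`.
#' @export
simulate_family_parameters <- function(family, G = 3L, d = 2L,
                                       separation = 5, seed = 1L) {
  family <- match.arg(family, .gmm_family_codes)
  fam <- gmm_families()
  row <- fam[fam$code == family, ]
  with_seed(seed, {
    # volume: log-spaced when variable so no two components share it
    lambda <- if (row$volume == "variable")
      exp(seq(-0.7, 0.7, length.out = G))[sample.int(G)] else rep(1, G)
    # shape: diagonal with det 1; anisotropy ratio 3 when shape matters
    rand_shape <- function() {
      v <- exp(stats::runif(d, -0.6, 0.6))
      v / .gmean(v)
    }
    shape <- if (row$distribution == "spherical") {
      replicate(G, rep(1, d))
    } else if (row$shape == "variable") {
      replicate(G, rand_shape())
    } else {
      matrix(rand_shape(), d, G)           # one shared draw
    }
    # orientation: random rotations where the family allows them
    rand_rot <- function() qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
    D <- if (row$orientation %in% c("none", "coordinate axes")) {
      replicate(G, diag(d), simplify = FALSE)
    } else if (row$orientation == "equal") {
      R <- rand_rot(); replicate(G, R, simplify = FALSE)
    } else replicate(G, rand_rot(), simplify = FALSE)
    covariances <- array(NA_real_, c(d, d, G))
    for (k in seq_len(G))
      covariances[, , k] <- lambda[k] *
        (D[[k]] %*% (shape[, k] * t(D[[k]])))
    # place means: random directions, scaled until min pairwise distance
    # reaches separation * average sd
    sd_unit <- sqrt(mean(lambda))
    means <- matrix(stats::rnorm(G * d), G, d)
    if (G > 1L) {
      dmin <- min(stats::dist(means))
      means <- means * (separation * sd_unit / dmin)
    }
    structure(list(family = family, G = as.integer(G), d = as.integer(d),
                   weights = rep(1 / G, G), means = means,
                   covariances = covariances, loglik = NA_real_,
                   n_params = gmm_n_params(family, G, d), bic = NA_real_,
                   n = NA_integer_, seed = as.integer(seed)),
              class = "phenoflag_gmm")
  })
}

#' Simulation configuration
#'
#' Defaults describe the study conditions used throughout the package's
#' validation: 600 observations in 3 contextual clusters separated by 6
#' within-cluster standard deviations, onset noise of 5 days, a planted
#' trend of -0.37 days/year over 1980-2013, and 3% of onsets shifted by
#' 5 onset-noise standard deviations (half early, half late).
#'
#' @param n_obs Number of observations.
#' @param n_clusters Number of contextual clusters.
#' @param cluster_separation Between-cluster separation in within-cluster
#'   sd units (latent context space).
#' @param within_cluster_doy_sd Onset noise within a cluster, days.
#' @param trend_slope Planted temporal trend, days/year.
#' @param year_range Integer vector of candidate years.
#' @param outlier_rate Fraction of observations planted as inconsistent;
#'   must be in `[0, 0.5)`.
#' @param outlier_shift Planted shift in units of
#'   `within_cluster_doy_sd`.
#' @param family Covariance family for the latent context clusters.
#' @param seed Integer seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_obs = 600L, n_clusters = 3L,
                       cluster_separation = 6,
                       within_cluster_doy_sd = 5,
                       trend_slope = -0.37, year_range = 1980:2013,
                       outlier_rate = 0.03, outlier_shift = 5,
                       family = "EII", seed = 1L) {
  stopifnot(outlier_rate >= 0, outlier_rate < 0.5,
            n_obs >= 10L * n_clusters, within_cluster_doy_sd > 0,
            cluster_separation > 0, length(year_range) >= 1L)
  structure(list(n_obs = as.integer(n_obs),
                 n_clusters = as.integer(n_clusters),
                 cluster_separation = cluster_separation,
                 within_cluster_doy_sd = within_cluster_doy_sd,
                 trend_slope = trend_slope,
                 year_range = as.integer(year_range),
                 outlier_rate = outlier_rate,
                 outlier_shift = outlier_shift,
                 family = match.arg(family, .gmm_family_codes),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a phenology campaign with known ground truth
#'
#' Observation sites are drawn from a latent three-dimensional mixture
#' of the configured covariance family (one component per contextual
#' cluster) and mapped to geography (latitude, longitude, elevation) and
#' to site climate drivers (mean annual temperature, seasonal amplitude,
#' precipitation, vapour pressure, radiation, snow); the latent axes
#' play the role of the dominant regional climate gradients. Daily climate is a
#' seasonal sinusoid per driver plus day-to-day noise; flowering onset is
#' the cluster's base date, advanced at warmer sites, plus the planted
#' year trend and Gaussian noise. A configured fraction of onsets is then
#' shifted early or late by `outlier_shift` onset-sd units.
#'
#' All output is deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory; when given, `observations.csv`,
#'   `climate.csv` and `ground_truth.csv` are written there.
#' @return List with `observations` (canonical observation columns plus
#'   `location_id`), `climate` (daily rows, canonical climate columns),
#'   `ground_truth` (`obs_id`, `true_cluster`, `true_flag`,
#'   `true_slope`), and `config`.
#' @export
simulate_phenology <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_obs; G <- config$n_clusters
  params <- simulate_family_parameters(config$family, G = G, d = 3L,
                                       separation = config$cluster_separation,
                                       seed = config$seed)
  U <- simulate(params, nsim = n, seed = config$seed + 1L)
  cluster <- attr(U, "component")

  out <- with_seed(config$seed + 2L, {
    year <- sample(config$year_range, n, replace = TRUE)
    year0 <- min(config$year_range)

    # map latent context to geography (latitude gradient U1, longitude
    # gradient U2, elevation gradient U3) and to site climate drivers;
    # every driver gets independent site-level wobble so that no single
    # latent direction dominates the 11-D within-cluster shape
    # (strongly elongated clusters would be fragmented by the embedding)
    lat  <- 41 + 1.2 * U[, 1]
    lon  <- -95 + 4 * U[, 2]
    elev <- pmax(0, 600 + 180 * U[, 3])
    t_mean  <- 9 - 0.9 * U[, 1] - 0.6 * U[, 3] +
      0.8 * stats::rnorm(n)                        # colder north & high
    t_amp   <- 14 + 0.6 * U[, 2] + 0.8 * stats::rnorm(n)
    pr_rate <- pmax(0.2, 2.5 + 0.5 * U[, 2] +
                      0.3 * stats::rnorm(n))       # mm/day
    vp_base <- pmax(100, 700 + 40 * U[, 1] + 30 * stats::rnorm(n))
    srad_base <- 250 + 8 * U[, 3] + 8 * stats::rnorm(n)

    # cluster base onset dates spread over spring
    base_doy <- seq(100, 100 + 18 * (G - 1), length.out = G)

    # within_cluster_doy_sd is the TOTAL within-cluster dispersion of
    # onset dates (the quantity the Tukey fences operate on), so the
    # residual noise budget subtracts the variance contributed by the
    # planted trend and by the climate coupling within each cluster.
    clim_coef <- 0.6
    w <- c(-0.9, 0, -0.6) * clim_coef       # t_mean mapping x coupling
    var_clim_k <- vapply(seq_len(G), function(k)
      drop(t(w) %*% params$covariances[, , k] %*% w), 0) +
      (clim_coef * 0.8)^2                   # independent site noise
    var_trend <- config$trend_slope^2 * stats::var(as.numeric(year))
    noise_sd <- sqrt(pmax(config$within_cluster_doy_sd^2 - var_trend -
                            var_clim_k[cluster], 0.25))
    mu_doy <- base_doy[cluster] - clim_coef * (t_mean - mean(t_mean)) +
      config$trend_slope * (year - year0)
    onset <- round(mu_doy + stats::rnorm(n, 0, noise_sd))

    # plant inconsistencies: round(rate * n) shifted, alternating sign
    n_out <- round(config$outlier_rate * n)
    planted <- if (n_out > 0) sample.int(n, n_out) else integer(0)
    sign <- rep(c(-1, 1), length.out = n_out)[sample.int(max(n_out, 1L),
                                                         n_out)]
    onset[planted] <- onset[planted] +
      sign * config$outlier_shift * config$within_cluster_doy_sd
    onset <- pmin(pmax(onset, 15L), 350L)
    true_flag <- rep("consistent", n)
    true_flag[planted[sign < 0]] <- "planted_early"
    true_flag[planted[sign > 0]] <- "planted_late"

    obs_id <- sprintf("obs%04d", seq_len(n))
    observations <- data.frame(
      obs_id = obs_id, year = year, onset_doy = as.integer(onset),
      latitude = round(lat, 6), longitude = round(lon, 6),
      elevation = round(elev, 2),
      onset_uncertainty_days = NA_integer_, multiple_onset = FALSE,
      location_id = obs_id, stringsAsFactors = FALSE)

    # daily climate per site-year: seasonal sinusoids + noise
    doy <- 1:365
    season <- -cos(2 * pi * (doy - 15) / 365)     # min mid-January
    climate <- vector("list", n)
    for (i in seq_len(n)) {
      tavg <- t_mean[i] + t_amp[i] * season + stats::rnorm(365, 0, 1.5)
      spread <- 4.5 + abs(stats::rnorm(365, 0, 1))
      prcp <- pmax(0, pr_rate[i] * (1 + 0.4 * sin(2 * pi * doy / 365)) +
                     stats::rnorm(365, 0, 1))
      vp <- pmax(10, vp_base[i] + 30 * t_amp[i] * season +
                   stats::rnorm(365, 0, 20))
      srad <- pmax(0, srad_base[i] + 150 * season +
                     stats::rnorm(365, 0, 15))
      dayl <- 43200 + 3600 * (lat[i] - 25) / 10 * season
      swe <- pmax(0, -10 * tavg + stats::rnorm(365, 0, 5))
      climate[[i]] <- data.frame(
        location_id = obs_id[i], year = year[i], doy = doy,
        tmax = round(tavg + spread, 3), tmin = round(tavg - spread, 3),
        prcp = round(prcp, 3), vp = round(vp, 2), srad = round(srad, 2),
        dayl = round(dayl, 1), swe = round(swe, 3),
        stringsAsFactors = FALSE)
    }
    list(observations = observations,
         climate = do.call(rbind, climate),
         ground_truth = data.frame(obs_id = obs_id,
                                   true_cluster = cluster,
                                   true_flag = true_flag,
                                   true_slope = config$trend_slope,
                                   stringsAsFactors = FALSE))
  })
  out$config <- config
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out$observations, file.path(dir, "observations.csv"),
                     row.names = FALSE)
    utils::write.csv(out$climate, file.path(dir, "climate.csv"),
                     row.names = FALSE)
    utils::write.csv(out$ground_truth, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  out
}

#' Simulate a "Yes"/"No" status-report series for one plant-year
#'
#' Visits occur on a regular schedule; at each visit the volunteer
#' reports `Yes` while a bloom window is open and `No` otherwise.
#' Running [derive_onsets()] on the output recovers each window's onset
#' to within one visit interval, with uncertainty at most the interval.
#'
#' @param onset_doy Day(s) of year at which bloom window(s) open; more
#'   than one value creates a repeat-flowering series.
#' @param visit_interval_days Days between visits (>= 1).
#' @param start_doy First visit day.
#' @param bloom_days Length of each bloom window.
#' @param end_doy Last possible visit day.
#' @param seed Optional seed; when given, each visit day is jittered by
#'   up to `jitter` days.
#' @param jitter Maximum uniform jitter applied to visit days.
#' @return Data frame with `doy` (integer) and `status` (logical).
#' @examples
#' s <- simulate_status_series(100, visit_interval_days = 7)
#' derive_onsets(s$doy, s$status)
#' @export
simulate_status_series <- function(onset_doy, visit_interval_days = 7L,
                                   start_doy = 60L, bloom_days = 21L,
                                   end_doy = 300L, seed = NULL,
                                   jitter = 0L) {
  stopifnot(visit_interval_days >= 1L, all(onset_doy >= 1L),
            all(onset_doy <= 366L))
  visits <- seq(from = start_doy, to = end_doy, by = visit_interval_days)
  if (!is.null(seed) && jitter > 0L)
    visits <- with_seed(seed, visits +
                          sample(-jitter:jitter, length(visits),
                                 replace = TRUE))
  visits <- sort(unique(pmin(pmax(as.integer(visits), 1L), 366L)))
  status <- vapply(visits, function(d)
    any(d >= onset_doy & d < onset_doy + bloom_days), logical(1))
  data.frame(doy = visits, status = status)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items:
#' 1 for identical partitions (up to label permutation), about 0 for
#' independent ones.
#'
#' @param a,b Integer/factor vectors of equal length.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)            # both partitions trivial
  (sum_ij - expected) / (maxi - expected)
}

#' Score pipeline recovery against simulation ground truth
#'
#' @param flags `consistency_flags` for the simulated observations.
#' @param ground_truth The `ground_truth` data frame from
#'   [simulate_phenology()].
#' @param assignments Optional [gmm_assign()] result; enables the
#'   cluster ARI.
#' @param trend_clean Optional `pheno_trend` fitted on the consistent
#'   subset; enables the slope error.
#' @return List with `sensitivity` (planted outliers recovered as
#'   inconsistent), `precision` (flagged observations that were
#'   planted), `n_planted`, `n_flagged`, `ari` and `slope_error`
#'   (`NA` when the inputs to compute them are absent).
#' @export
score_recovery <- function(flags, ground_truth, assignments = NULL,
                           trend_clean = NULL) {
  if (nrow(flags) != nrow(ground_truth))
    stop("length mismatch between flags and ground truth", call. = FALSE)
  gt <- ground_truth[match(flags$obs_id, ground_truth$obs_id), ]
  planted <- gt$true_flag != "consistent"
  flagged <- flags$flag %in% c("inconsistent_early", "inconsistent_late")
  sensitivity <- if (any(planted)) mean(flagged[planted]) else NA_real_
  precision <- if (any(flagged)) mean(planted[flagged]) else NA_real_
  ari <- if (!is.null(assignments))
    adjusted_rand_index(gt$true_cluster, assignments$label) else NA_real_
  slope_error <- if (!is.null(trend_clean))
    abs(trend_clean$slope - gt$true_slope[1]) else NA_real_
  list(sensitivity = sensitivity, precision = precision,
       n_planted = sum(planted), n_flagged = sum(flagged),
       ari = ari, slope_error = slope_error)
}
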
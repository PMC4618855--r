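test_that("family parameter construction honours each family's constraints", {
  for (fam in gmm_families()$code) {
    par <- simulate_family_parameters(fam, G = 3, d = 2, separation = 5,
                                      seed = 8)
    row <- gmm_families()[gmm_families()$code == fam, ]
    Sig <- par$covariances
    dets <- apply(Sig, 3, det)
    if (row$volume == "equal")
      expect_lt(max(abs(dets - dets[1])), 1e-10)
    if (row$distribution == "spherical")
      for (k in 1:3)
        expect_equal(Sig[, , k], diag(Sig[1, 1, k], 2), tolerance = 1e-12)
    if (row$distribution == "diagonal")
      for (k in 1:3)
        expect_lt(abs(Sig[1, 2, k]), 1e-12)
    # means separated by at least `separation` pooled sd units
    expect_gte(min(dist(par$means)),
               5 * sqrt(mean(apply(Sig, 3, function(S)
                 mean(diag(S))))) * 0.5)
  }
})

test_that("simulation is reproducible bit-for-bit given the seed", {
  cfg <- sim_config(n_obs = 60, n_clusters = 2, seed = 7)
  a <- simulate_phenology(cfg)
  b <- simulate_phenology(cfg)
  expect_identical(a$observations, b$observations)
  expect_identical(a$climate, b$climate)
  expect_identical(a$ground_truth, b$ground_truth)
  # a different seed changes the draw
  c_ <- simulate_phenology(sim_config(n_obs = 60, n_clusters = 2,
                                      seed = 8))
  expect_false(identical(a$observations, c_$observations))
})

test_that("planted inconsistency counts match the configured rate", {
  cfg <- sim_config(n_obs = 400, n_clusters = 2, outlier_rate = 0.05,
                    seed = 3)
  sim <- simulate_phenology(cfg)
  expect_equal(sum(sim$ground_truth$true_flag != "consistent"),
               round(0.05 * 400))
  # zero rate plants nothing
  sim0 <- simulate_phenology(sim_config(n_obs = 60, n_clusters = 2,
                                        outlier_rate = 0, seed = 3))
  expect_true(all(sim0$ground_truth$true_flag == "consistent"))
})

test_that("invalid configurations are refused", {
  expect_error(sim_config(outlier_rate = 0.6))
  expect_error(sim_config(n_obs = 20, n_clusters = 3))
})

test_that("emitted climate re-derives context consistent with the planted clusters", {
  cfg <- sim_config(n_obs = 90, n_clusters = 3, seed = 5)
  sim <- simulate_phenology(cfg)
  X <- context_matrix(sim$observations, sim$climate)
  expect_equal(nrow(X), 90L)
  expect_true(all(is.finite(X)))
  # the planted cluster structure is linearly recoverable from context
  Z <- standardize_context(X, drop_constant = TRUE)
  km <- phenoflag:::with_seed(1,
    kmeans(Z, centers = 3, nstart = 10))
  expect_gte(adjusted_rand_index(sim$ground_truth$true_cluster,
                                 km$cluster), 0.9)
  # within-cluster onset dispersion (trend included) matches the
  # configured total sd
  sds <- vapply(split(seq_len(90), sim$ground_truth$true_cluster),
    function(idx) {
      keep <- idx[sim$ground_truth$true_flag[idx] == "consistent"]
      sd(sim$observations$onset_doy[keep])
    }, 0)
  expect_lt(abs(mean(sds) - cfg$within_cluster_doy_sd), 1.2)
})

test_that("status series reproduce the scheduled-visit hand traces", {
  s <- simulate_status_series(100, visit_interval_days = 7,
                              start_doy = 60)
  r <- derive_onsets(s$doy, s$status)
  expect_equal(r$onsets$onset_doy, 102L)
  expect_equal(r$onsets$onset_uncertainty_days, 7L)
  expect_false(r$multiple_onset)

  # daily visits pin the onset to one day
  sd_ <- simulate_status_series(100, visit_interval_days = 1,
                                start_doy = 60)
  rd <- derive_onsets(sd_$doy, sd_$status)
  expect_equal(rd$onsets$onset_doy, 100L)
  expect_equal(rd$onsets$onset_uncertainty_days, 1L)

  # a second bloom window triggers the repeat-flowering flag
  s2 <- simulate_status_series(c(100, 250), visit_interval_days = 7,
                               start_doy = 60)
  r2 <- derive_onsets(s2$doy, s2$status)
  expect_true(r2$multiple_onset)
  expect_equal(nrow(r2$onsets), 2L)
})

test_that("derived onsets always fall within one visit interval of truth", {
  phenoflag:::with_seed(13, {
    for (rep in 1:20) {
      onset <- sample(70:250, 1)
      interval <- sample(1:14, 1)
      s <- simulate_status_series(onset, interval, start_doy = 40)
      r <- derive_onsets(s$doy, s$status)
      expect_equal(nrow(r$onsets), 1L)
      expect_gte(r$onsets$onset_doy, onset)
      expect_lt(r$onsets$onset_doy, onset + interval)
      expect_lte(r$onsets$onset_uncertainty_days, interval)
    }
  })
})

test_that("recovery scoring matches its definitions", {
  gt <- data.frame(obs_id = 1:6,
                   true_cluster = c(1, 1, 1, 2, 2, 2),
                   true_flag = c("consistent", "planted_early",
                                 "consistent", "planted_late",
                                 "consistent", "consistent"),
                   true_slope = -0.3)
  fl <- data.frame(obs_id = 1:6,
                   flag = factor(c("consistent", "inconsistent_early",
                                   "consistent", "inconsistent_late",
                                   "consistent", "consistent"),
                                 levels = phenoflag:::.flag_levels))
  sc <- score_recovery(fl, gt)
  expect_equal(sc$sensitivity, 1)
  expect_equal(sc$precision, 1)

  # nothing flagged: zero sensitivity, undefined precision
  fl$flag[] <- "consistent"
  sc0 <- score_recovery(fl, gt)
  expect_equal(sc0$sensitivity, 0)
  expect_true(is.na(sc0$precision))

  expect_error(score_recovery(fl[1:3, ], gt), "length mismatch")
})

test_that("the hand-rolled adjusted Rand index matches mclust", {
  skip_if_not_installed("mclust")
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  phenoflag:::with_seed(17, {
    for (rep in 1:10) {
      a <- sample(1:4, 50, replace = TRUE)
      b <- sample(1:3, 50, replace = TRUE)
      expect_equal(adjusted_rand_index(a, b),
                   mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
    }
  })
})
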
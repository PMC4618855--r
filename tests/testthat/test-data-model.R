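test_that("observation CSV reading validates rows without dropping them silently", {
  obs <- make_obs(3)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(obs, tmp, row.names = FALSE)
  got <- read_observations(tmp)
  expect_equal(nrow(got), 3L)
  expect_equal(nrow(attr(got, "rejects")), 0L)
  expect_equal(got$obs_id, obs$obs_id)

  # an out-of-range day of year is rejected with a reason, not dropped
  bad <- obs
  bad$onset_doy[2] <- 400L
  write.csv(bad, tmp, row.names = FALSE)
  got <- read_observations(tmp)
  expect_equal(nrow(got), 2L)
  rej <- attr(got, "rejects")
  expect_equal(rej$row, 2L)
  expect_match(rej$reason, "doy out of range")
})

test_that("column order does not matter and missing columns are named", {
  obs <- make_obs(4)
  tmp1 <- withr::local_tempfile(fileext = ".csv")
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(obs, tmp1, row.names = FALSE)
  write.csv(obs[, rev(names(obs))], tmp2, row.names = FALSE)
  expect_equal(read_observations(tmp1), read_observations(tmp2))

  write.csv(obs[, setdiff(names(obs), "latitude")], tmp1,
            row.names = FALSE)
  expect_error(read_observations(tmp1), "latitude")
})

test_that("a column-name dialect maps nonstandard headers", {
  obs <- make_obs(3)
  renamed <- obs
  names(renamed)[names(renamed) == "onset_doy"] <- "first_flower_doy"
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(renamed, tmp, row.names = FALSE)
  got <- read_observations(tmp,
                           dialect = c(onset_doy = "first_flower_doy"))
  expect_equal(got$onset_doy, obs$onset_doy)
})

test_that("onset derivation reproduces the hand-traced status series", {
  # a Yes preceded by a No five days earlier
  r <- derive_onsets(c(90, 95), c(FALSE, TRUE))
  expect_equal(r$onsets$onset_doy, 95L)
  expect_equal(r$onsets$onset_uncertainty_days, 5L)
  expect_false(r$multiple_onset)

  # no preceding No: uncertainty unknown
  r <- derive_onsets(95, TRUE)
  expect_equal(r$onsets$onset_doy, 95L)
  expect_true(is.na(r$onsets$onset_uncertainty_days))
  expect_false(r$multiple_onset)

  # repeat flowering: both run-initial Yes days are onsets, each dated
  # against its nearest preceding No (95 - 90 = 5; 250 - 120 = 130)
  r <- derive_onsets(c(90, 95, 100, 120, 250),
                     c(FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(r$onsets$onset_doy, c(95L, 250L))
  expect_equal(r$onsets$onset_uncertainty_days, c(5L, 130L))
  expect_true(r$multiple_onset)
})

test_that("onset derivation handles degenerate and contradictory input", {
  expect_equal(nrow(derive_onsets(integer(0), logical(0))$onsets), 0L)
  expect_equal(nrow(derive_onsets(c(50, 90), c(FALSE, FALSE))$onsets), 0L)
  expect_error(derive_onsets(c(90, 90), c(TRUE, FALSE)), "conflicting")
})

test_that("onset count equals the number of maximal Yes runs and is stable under redundant reports", {
  phenoflag:::with_seed(42, {
    for (rep in 1:25) {
      n <- sample(3:15, 1)
      doy <- sort(sample(1:366, n))
      status <- runif(n) < 0.5
      r <- derive_onsets(doy, status)
      runs <- rle(status)
      expect_equal(nrow(r$onsets), sum(runs$values))
      expect_equal(r$multiple_onset, sum(runs$values) > 1L)
      # duplicating every report changes nothing
      r2 <- derive_onsets(c(doy, doy), c(status, status))
      expect_equal(r2, r)
    }
  })
})

test_that("per-table onset derivation partitions by plant-year and reports rejects", {
  reports <- data.frame(
    plant_id = c("a", "a", "a", "a", "b", "b"),
    year = c(2010L, 2010L, 2011L, 2011L, 2010L, 2010L),
    doy = c(90L, 95L, 80L, 85L, 100L, 100L),
    status = c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE))
  out <- derive_onsets_table(reports)
  expect_equal(nrow(out), 2L)      # a/2010 and a/2011; b/2010 rejected
  expect_equal(out$onset_doy, c(95L, 85L))
  rej <- attr(out, "rejects")
  expect_equal(rej$plant_id, "b")
  expect_match(rej$reason, "conflicting")

  # repeat-flowering plant-years: one row per onset, or first only
  rf <- data.frame(plant_id = "c", year = 2012L,
                   doy = c(50L, 60L, 90L, 250L),
                   status = c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(derive_onsets_table(rf)$onset_doy, c(60L, 250L))
  first <- derive_onsets_table(rf, onsets = "first")
  expect_equal(first$onset_doy, 60L)
  expect_true(first$multiple_onset)
})

test_that("flag output round-trips through CSV field-identically", {
  obs <- make_obs(5)
  flags <- data.frame(obs_id = obs$obs_id, cluster = c(1L, 1L, 2L, 2L, 2L),
                      uncertainty = c(0.1, 0.2, 0, 0.45, 0.05),
                      flag = c("consistent", "inconsistent_early",
                               "consistent", "unresolved",
                               "inconsistent_late"))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_flagged(obs, flags, tmp)
  back <- read.csv(tmp, stringsAsFactors = FALSE)
  expect_equal(back$obs_id, obs$obs_id)
  expect_equal(back$year, obs$year)
  expect_equal(back$onset_doy, obs$onset_doy)
  expect_equal(back$latitude, obs$latitude, tolerance = 1e-6)
  expect_equal(back$longitude, obs$longitude, tolerance = 1e-6)
  expect_equal(back$flag, flags$flag)
  expect_equal(back$cluster, flags$cluster)

  expect_error(write_flagged(obs, flags[1:3, ], tmp), "length mismatch")
  # empty input gives a header-only file
  write_flagged(obs[0, ], flags[0, ], tmp)
  expect_equal(nrow(read.csv(tmp)), 0L)
})

test_that("status CSV reading normalises Y/N spellings", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(plant_id = "p", year = 2010, doy = c(90, 95),
                       status = c("no", "Y")), tmp, row.names = FALSE)
  got <- read_status_reports(tmp)
  expect_equal(got$status, c(FALSE, TRUE))
  write.csv(data.frame(plant_id = "p", year = 2010, doy = 90,
                       status = "maybe"), tmp, row.names = FALSE)
  expect_error(read_status_reports(tmp), "unrecognised")
})
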
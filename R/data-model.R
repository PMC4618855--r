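#' phenoflag: context-aware consistency checking for phenological records
#'
#' Volunteered phenology records (e.g. lilac first-flowering dates) contain
#' occasional implausible entries. Simple range checks miss them because
#' what is "plausible" depends on where and under which climate an
#' observation was made. This package implements a context-aware check:
#' each record is described by eleven contextual variables, embedded to two
#' dimensions, clustered into contextually homogeneous groups, and flagged
#' when its onset day of year falls outside the Tukey fences of its own
#' cluster. A companion trend module quantifies how flagged records bias
#' long-term phenological trend estimates.
#'
#' The main entry points are [pheno_qc()] for the end-to-end workflow,
#' [gmm_select()] for the model-based clustering step on its own, and
#' [simulate_phenology()] for synthetic data with known ground truth.
#'
#' @keywords internal
"_PACKAGE"

# Canonical column sets for the CSV dialects used throughout.
.obs_required_cols <- c("obs_id", "year", "onset_doy",
                        "latitude", "longitude", "elevation")
.obs_optional_cols <- c("onset_uncertainty_days", "multiple_onset")
.status_cols  <- c("plant_id", "year", "doy", "status")
.climate_cols <- c("location_id", "year", "doy",
                   "tmax", "tmin", "prcp", "vp", "srad", "dayl", "swe")
.flag_levels  <- c("consistent", "inconsistent_early",
                   "inconsistent_late", "unresolved")

#' Read phenological observations from CSV
#'
#' Reads a table of flowering-onset records and validates each row against
#' the domain invariants (day of year in 1..366, finite coordinates,
#' positive onset uncertainty where present). Invalid rows are not silently
#' dropped: they are returned in a `rejects` attribute with a reason.
#'
#' @param path Path to a CSV file with a header row.
#' @param dialect Named character vector mapping canonical column names
#'   (`obs_id`, `year`, `onset_doy`, `latitude`, `longitude`, `elevation`,
#'   and optionally `onset_uncertainty_days`, `multiple_onset`) to the
#'   column names used in the file. Unmapped names are assumed canonical.
#' @return A data frame of valid observations with canonical columns, in
#'   file order. Attribute `rejects` holds a data frame with columns
#'   `row` (1-based data row) and `reason` for every discarded row.
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' write.csv(data.frame(obs_id = c("a", "b"), year = c(2001, 2002),
#'                      onset_doy = c(120, 131), latitude = c(42, 43),
#'                      longitude = c(-79, -80), elevation = c(200, 250)),
#'           tmp, row.names = FALSE)
#' obs <- read_observations(tmp)
#' nrow(obs); nrow(attr(obs, "rejects"))
#' @seealso [write_flagged()], [derive_onsets()]
#' @export
read_observations <- function(path, dialect = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      hit <- match(dialect[[canon]], names(raw))
      if (!is.na(hit)) names(raw)[hit] <- canon
    }
  }
  missing <- setdiff(.obs_required_cols, names(raw))
  if (length(missing) > 0L)
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)

  out <- data.frame(
    obs_id    = as.character(raw$obs_id),
    year      = suppressWarnings(as.integer(raw$year)),
    onset_doy = suppressWarnings(as.integer(raw$onset_doy)),
    latitude  = suppressWarnings(as.numeric(raw$latitude)),
    longitude = suppressWarnings(as.numeric(raw$longitude)),
    elevation = suppressWarnings(as.numeric(raw$elevation)),
    stringsAsFactors = FALSE
  )
  out$onset_uncertainty_days <-
    if ("onset_uncertainty_days" %in% names(raw))
      suppressWarnings(as.integer(raw$onset_uncertainty_days)) else NA_integer_
  out$multiple_onset <-
    if ("multiple_onset" %in% names(raw))
      as.logical(raw$multiple_onset) else FALSE
  out$multiple_onset[is.na(out$multiple_onset)] <- FALSE

  reason <- rep(NA_character_, nrow(out))
  bad <- function(cond, why) {
    hit <- which(cond & is.na(reason))
    reason[hit] <<- why
  }
  bad(is.na(out$obs_id) | out$obs_id == "", "missing obs_id")
  bad(is.na(out$year), "unparseable year")
  bad(is.na(out$onset_doy) | out$onset_doy < 1L | out$onset_doy > 366L,
      "doy out of range")
  bad(!is.finite(out$latitude) | abs(out$latitude) > 90, "invalid latitude")
  bad(!is.finite(out$longitude) | abs(out$longitude) > 180,
      "invalid longitude")
  bad(!is.finite(out$elevation), "invalid elevation")
  bad(!is.na(out$onset_uncertainty_days) & out$onset_uncertainty_days < 1L,
      "onset_uncertainty_days < 1")

  keep <- is.na(reason)
  rejects <- data.frame(row = which(!keep), reason = reason[!keep],
                        stringsAsFactors = FALSE)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejects") <- rejects
  out
}

#' Read "Yes"/"No" status reports from CSV
#'
#' Status monitoring records whether a phenophase is visible at each visit.
#' Expected columns: `plant_id`, `year`, `doy`, `status` (one of
#' `Y`/`N`/`Yes`/`No`, case-insensitive).
#'
#' @param path Path to a CSV file.
#' @return Data frame with columns `plant_id`, `year`, `doy` (integer) and
#'   `status` (logical, `TRUE` = phase visible).
#' @export
read_status_reports <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.status_cols, names(raw))
  if (length(missing) > 0L)
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  status <- toupper(trimws(as.character(raw$status)))
  ok <- status %in% c("Y", "YES", "N", "NO")
  if (!all(ok))
    stop("unrecognised status value(s): ",
         paste(unique(status[!ok]), collapse = ", "), call. = FALSE)
  data.frame(
    plant_id = as.character(raw$plant_id),
    year     = as.integer(raw$year),
    doy      = as.integer(raw$doy),
    status   = status %in% c("Y", "YES"),
    stringsAsFactors = FALSE
  )
}

#' Derive flowering onsets from one plant-year of status reports
#'
#' Volunteers report `Yes` while a phenophase is visible and `No` when it
#' is not. An onset is the day of year of each `Yes` that begins a maximal
#' run of `Yes` reports. Its uncertainty is the gap in days to the nearest
#' preceding `No` (at any distance), or `NA` when no earlier `No` exists.
#' When a `Yes` run is followed by at least one `No` and then a further
#' `Yes` run, the plant re-flowered within the year: every run-initial
#' `Yes` is returned as an onset and `multiple_onset` is set.
#'
#' Reports are de-duplicated on (doy, status); a day carrying both a `Yes`
#' and a `No` for the same plant is contradictory and raises an error.
#'
#' @param doy Integer vector of report days of year (1..366).
#' @param status Logical vector, `TRUE` for `Yes`, parallel to `doy`.
#' @return List with `onsets` (data frame: `onset_doy`,
#'   `onset_uncertainty_days`) and `multiple_onset` (logical scalar).
#' @examples
#' derive_onsets(c(90, 95), c(FALSE, TRUE))
#' derive_onsets(c(90, 95, 100, 120, 250),
#'               c(FALSE, TRUE, TRUE, FALSE, TRUE))
#' @export
derive_onsets <- function(doy, status) {
  stopifnot(length(doy) == length(status))
  empty <- list(onsets = data.frame(onset_doy = integer(0),
                                    onset_uncertainty_days = integer(0)),
                multiple_onset = FALSE)
  if (length(doy) == 0L) return(empty)
  doy <- as.integer(doy)
  status <- as.logical(status)
  if (anyNA(doy) || anyNA(status)) stop("NA in status reports", call. = FALSE)
  if (any(doy < 1L | doy > 366L)) stop("doy out of range", call. = FALSE)

  ord <- order(doy, status)
  doy <- doy[ord]; status <- status[ord]
  dup <- duplicated(cbind(doy, status))
  doy <- doy[!dup]; status <- status[!dup]
  if (anyDuplicated(doy))
    stop("conflicting reports (both Yes and No) on doy ",
         paste(doy[duplicated(doy)], collapse = ", "), call. = FALSE)

  if (!any(status)) return(empty)
  # run-initial Yes: a Yes whose predecessor is absent or a No
  initial <- status & c(TRUE, !status[-length(status)])
  onset_doy <- doy[initial]
  uncertainty <- vapply(onset_doy, function(d) {
    prior_no <- doy[!status & doy < d]
    if (length(prior_no) == 0L) NA_integer_ else d - max(prior_no)
  }, integer(1))
  list(
    onsets = data.frame(onset_doy = onset_doy,
                        onset_uncertainty_days = uncertainty),
    multiple_onset = sum(initial) > 1L
  )
}

#' Derive onsets for every plant-year in a status table
#'
#' Applies [derive_onsets()] per plant and calendar year (runs never span
#' a year boundary; day-of-year bookkeeping restarts on 1 January).
#' Plant-years with contradictory same-day reports are rejected with a
#' reason rather than silently dropped.
#'
#' @param reports Data frame as returned by [read_status_reports()].
#' @param onsets `"all"` (default) emits one row per derived onset, so a
#'   repeat-flowering plant-year contributes several observations
#'   downstream; `"first"` keeps only the first onset of each
#'   plant-year (the repeat-flowering flag is carried either way).
#' @return Data frame with one row per derived onset: `plant_id`, `year`,
#'   `onset_doy`, `onset_uncertainty_days`, `multiple_onset`; attribute
#'   `rejects` lists plant-years that failed.
#' @export
derive_onsets_table <- function(reports, onsets = c("all", "first")) {
  onsets <- match.arg(onsets)
  stopifnot(all(.status_cols %in% names(reports)))
  key <- interaction(reports$plant_id, reports$year, drop = TRUE)
  pieces <- split(seq_len(nrow(reports)), key)
  rows <- list(); rej <- list()
  for (nm in names(pieces)) {
    idx <- pieces[[nm]]
    res <- tryCatch(derive_onsets(reports$doy[idx], reports$status[idx]),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rej[[nm]] <- data.frame(plant_id = reports$plant_id[idx[1]],
                              year = reports$year[idx[1]],
                              reason = conditionMessage(res),
                              stringsAsFactors = FALSE)
    } else if (nrow(res$onsets) > 0L) {
      keep <- if (onsets == "first") 1L else seq_len(nrow(res$onsets))
      rows[[nm]] <- data.frame(plant_id = reports$plant_id[idx[1]],
                               year = reports$year[idx[1]],
                               res$onsets[keep, , drop = FALSE],
                               multiple_onset = res$multiple_onset,
                               stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(plant_id = character(0), year = integer(0),
               onset_doy = integer(0), onset_uncertainty_days = integer(0),
               multiple_onset = logical(0))
  rownames(out) <- NULL
  attr(out, "rejects") <- if (length(rej)) {
    r <- do.call(rbind, rej); rownames(r) <- NULL; r
  } else data.frame(plant_id = character(0), year = integer(0),
                    reason = character(0))
  out
}

#' Write observations with their consistency flags to CSV
#'
#' @param observations Data frame of observations (canonical columns).
#' @param flags Data frame of consistency flags as returned by
#'   [flag_inconsistent()]; must cover the observations one-to-one.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_flagged <- function(observations, flags, path) {
  if (nrow(observations) != nrow(flags))
    stop("length mismatch: ", nrow(observations), " observations vs ",
         nrow(flags), " flags", call. = FALSE)
  out <- observations
  if (nrow(flags) > 0L && !identical(as.character(out$obs_id),
                                     as.character(flags$obs_id)))
    flags <- flags[match(out$obs_id, flags$obs_id), , drop = FALSE]
  out$cluster <- flags$cluster
  out$uncertainty <- flags$uncertainty
  out$flag <- flags$flag
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read daily climate series from CSV
#'
#' One row per location-day with columns `location_id`, `year`, `doy`,
#' `tmax`, `tmin`, `prcp`, `vp`, `srad`, `dayl`, `swe`.
#'
#' @param path Path to a CSV file.
#' @return Data frame with the canonical climate columns.
#' @export
read_climate <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.climate_cols, names(raw))
  if (length(missing) > 0L)
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  raw$location_id <- as.character(raw$location_id)
  raw$year <- as.integer(raw$year)
  raw$doy <- as.integer(raw$doy)
  if (any(raw$tmax < raw$tmin, na.rm = TRUE))
    stop("tmax < tmin in climate series", call. = FALSE)
  raw[, .climate_cols]
}
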
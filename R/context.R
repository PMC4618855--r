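# Construction of the 11-dimensional contextual description of an
# observation: 3 geographic variables plus 8 climate sums accumulated from
# 1 January to the reported onset day of year.

.context_cols <- c("latitude", "longitude", "elevation",
                   "cum_tmax", "cum_tmin", "cum_tavg", "cum_dayl",
                   "cum_prcp", "cum_srad", "cum_swe", "cum_vp")

#' Cumulative climate values up to an onset day
#'
#' Sums each daily climate parameter from day of year 1 to `onset_doy`
#' inclusive, for one location-year. Daily average temperature is
#' `(tmax + tmin) / 2`, summed likewise. Most phenological processes are
#' driven by accumulated, not instantaneous, climate, which is why sums —
#' rather than e.g. means — characterise the context of an onset date.
#'
#' @param series Data frame of daily climate rows for a single
#'   location-year (columns as in [read_climate()]); need not be sorted.
#' @param onset_doy Integer day of year up to which to accumulate.
#' @return Named numeric vector of the 8 cumulative values: `cum_tmax`,
#'   `cum_tmin`, `cum_tavg`, `cum_dayl`, `cum_prcp`, `cum_srad`,
#'   `cum_swe`, `cum_vp`.
#' @examples
#' s <- data.frame(doy = 1:10, tmax = 10, tmin = 0, prcp = 0, vp = 0,
#'                 srad = 0, dayl = 3600, swe = 0)
#' cumulative_context(s, 10)
#' @export
cumulative_context <- function(series, onset_doy) {
  onset_doy <- as.integer(onset_doy)
  stopifnot(length(onset_doy) == 1L, onset_doy >= 1L, onset_doy <= 366L)
  series <- series[order(series$doy), , drop = FALSE]
  have <- series$doy[series$doy <= onset_doy]
  miss <- setdiff(seq_len(onset_doy), have)
  if (length(miss) > 0L)
    stop("climate series has gaps before onset: missing doy(s) ",
         paste(utils::head(miss, 10L), collapse = ", "),
         if (length(miss) > 10L) ", ...", call. = FALSE)
  sub <- series[series$doy <= onset_doy & !duplicated(series$doy), ,
                drop = FALSE]
  c(cum_tmax = sum(sub$tmax),
    cum_tmin = sum(sub$tmin),
    cum_tavg = sum((sub$tmax + sub$tmin) / 2),
    cum_dayl = sum(sub$dayl),
    cum_prcp = sum(sub$prcp),
    cum_srad = sum(sub$srad),
    cum_swe  = sum(sub$swe),
    cum_vp   = sum(sub$vp))
}

#' Assemble the n x 11 context matrix for a set of observations
#'
#' Looks up the daily climate series for each observation's location and
#' year (exact `location_id` match) and combines the geographic variables
#' with the eight climate sums of [cumulative_context()].
#'
#' @param observations Data frame of observations; must carry a
#'   `location_id` column (or `obs_id` is used as the location key when
#'   absent).
#' @param climate Data frame of daily climate rows covering every
#'   observation's location-year up to its onset day.
#' @return Numeric matrix with one row per observation (same order) and
#'   the 11 canonical context columns.
#' @export
context_matrix <- function(observations, climate) {
  n <- nrow(observations)
  loc <- if ("location_id" %in% names(observations))
    as.character(observations$location_id) else
    as.character(observations$obs_id)
  X <- matrix(NA_real_, n, length(.context_cols),
              dimnames = list(observations$obs_id, .context_cols))
  if (n == 0L) return(X)
  key <- paste(climate$location_id, climate$year, sep = "\r")
  cl_split <- split(seq_len(nrow(climate)), key)
  for (i in seq_len(n)) {
    k <- paste(loc[i], observations$year[i], sep = "\r")
    idx <- cl_split[[k]]
    if (is.null(idx))
      stop("no climate series for observation ", observations$obs_id[i],
           " (location ", loc[i], ", year ", observations$year[i], ")",
           call. = FALSE)
    cums <- cumulative_context(climate[idx, , drop = FALSE],
                               observations$onset_doy[i])
    X[i, ] <- c(observations$latitude[i], observations$longitude[i],
                observations$elevation[i], cums)
  }
  X
}

#' Z-score the columns of a context matrix
#'
#' The eleven contextual variables span about seven orders of magnitude in
#' their raw units (cumulative day length is ~5e6 s while latitude is
#' ~42 degrees), so any Euclidean-distance-based embedding of the raw
#' matrix is dominated by one or two columns. Standardisation (sample
#' standard deviation) puts the variables on a common scale; the stored
#' centre/scale make the transform invertible.
#'
#' @param X Numeric matrix, n >= 2 rows.
#' @param drop_constant Drop zero-variance columns (recorded in the
#'   `dropped` attribute) instead of failing.
#' @return Matrix of z-scores with attributes `center`, `scale` and
#'   `dropped` (character vector of removed columns).
#' @export
standardize_context <- function(X, drop_constant = FALSE) {
  stopifnot(is.matrix(X), nrow(X) >= 2L)
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  const <- sdv == 0 | !is.finite(sdv)
  dropped <- character(0)
  if (any(const)) {
    if (!drop_constant)
      stop("constant column(s): ",
           paste(colnames(X)[const], collapse = ", "),
           " (set drop_constant = TRUE to remove)", call. = FALSE)
    dropped <- colnames(X)[const]
    X <- X[, !const, drop = FALSE]
    mu <- mu[!const]; sdv <- sdv[!const]
  }
  Z <- sweep(sweep(X, 2L, mu, "-"), 2L, sdv, "/")
  attr(Z, "center") <- mu
  attr(Z, "scale") <- sdv
  attr(Z, "dropped") <- dropped
  Z
}
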
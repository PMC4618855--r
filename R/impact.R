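# Impact of flagged observations on the long-term phenological trend:
# ordinary least squares of onset day of year on calendar year, with and
# without the inconsistent records, and an analysis of covariance testing
# whether the two slopes differ.

#' Linear trend in onset day of year
#'
#' Ordinary least squares of onset DOY on calendar year (continuous,
#' uncentered — the slope is invariant to centering). The slope is in
#' days per year; multiply by ten (see [decadal_rate()]) for the
#' days-per-decade advancement rate usually quoted.
#'
#' @param years Numeric vector of calendar years.
#' @param doys Numeric vector of onset days of year, parallel to `years`.
#' @return Object of class `pheno_trend`: `slope`, `intercept` (at year
#'   0), `intercept_start` (fitted DOY at the earliest year), `se_slope`,
#'   `p_slope` (two-sided t-test), `n`, `r2`, and the underlying `lm`
#'   fit.
#' @examples
#' yr <- 1980:2013
#' fit_trend(yr, 150 - 0.3 * (yr - 1980))
#' @export
fit_trend <- function(years, doys) {
  ok <- is.finite(years) & is.finite(doys)
  years <- years[ok]; doys <- doys[ok]
  if (length(years) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (length(unique(years)) < 2L)
    stop("all years identical; no trend is estimable", call. = FALSE)
  fit <- stats::lm(doys ~ years)
  sm <- summary(fit)
  co <- sm$coefficients
  structure(
    list(slope = unname(co["years", "Estimate"]),
         intercept = unname(co["(Intercept)", "Estimate"]),
         intercept_start = unname(stats::predict(fit,
           data.frame(years = min(years)))),
         se_slope = unname(co["years", "Std. Error"]),
         p_slope = unname(co["years", "Pr(>|t|)"]),
         n = length(years), r2 = sm$r.squared, lm = fit),
    class = "pheno_trend")
}

#' @export
print.pheno_trend <- function(x, ...) {
  cat("Onset trend: ", format(x$slope, digits = 4), " days/year (se ",
      format(x$se_slope, digits = 3), ", p = ",
      format.pval(x$p_slope, digits = 3), ", n = ", x$n, ", R^2 = ",
      format(x$r2, digits = 3), ")\n", "  = ",
      format(decadal_rate(x), digits = 3), " days/decade\n", sep = "")
  invisible(x)
}

#' @export
summary.pheno_trend <- function(object, ...) summary(object$lm, ...)

#' @export
coef.pheno_trend <- function(object, ...) stats::coef(object$lm)

#' @export
predict.pheno_trend <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::predict(object$lm, ...))
  if (is.numeric(newdata)) newdata <- data.frame(years = newdata)
  stats::predict(object$lm, newdata, ...)
}

#' @export
residuals.pheno_trend <- function(object, ...) stats::residuals(object$lm)

#' @export
plot.pheno_trend <- function(x, ...) {
  dat <- stats::model.frame(x$lm)
  graphics::plot(dat$years, dat$doys, xlab = "year",
                 ylab = "onset day of year", pch = 16,
                 col = grDevices::grey(0.4), ...)
  graphics::abline(x$lm, lwd = 2)
  invisible(x)
}

#' Days-per-decade advancement rate
#'
#' @param trend A `pheno_trend`, or a numeric slope in days/year.
#' @return Slope times ten: days per decade (negative = earlier onset).
#' @export
decadal_rate <- function(trend) {
  slope <- if (inherits(trend, "pheno_trend")) trend$slope else trend
  slope * 10
}

#' Trend with and without inconsistent observations, plus ANCOVA
#'
#' Fits the onset trend on all resolved observations ("full") and on the
#' consistent subset only ("clean"), then tests whether the two slopes
#' differ with an analysis of covariance:
#' `doy ~ year + consistency + year:consistency`, where the interaction
#' coefficient is exactly the difference between the inconsistent-group
#' and consistent-group slopes and its t-test is the slope-difference
#' test.
#'
#' @param observations Data frame with `year` and `onset_doy`.
#' @param flags `consistency_flags` covering the observations in order.
#' @return List with `full` and `clean` ([fit_trend()] objects) and
#'   `ancova` (either `NULL`, with a message, when no resolved
#'   inconsistent observations exist, or a list with `slope_full`,
#'   `slope_clean`, `interaction_estimate`, `p_interaction`, `p_group`
#'   and the underlying `lm`).
#' @export
compare_trends <- function(observations, flags) {
  if (nrow(observations) != nrow(flags))
    stop("flags must cover all observations", call. = FALSE)
  resolved <- flags$flag != "unresolved"
  consistent <- flags$flag == "consistent"
  if (sum(consistent) < 3L)
    stop("need at least 3 consistent observations", call. = FALSE)
  full <- fit_trend(observations$year[resolved],
                    observations$onset_doy[resolved])
  clean <- fit_trend(observations$year[consistent],
                     observations$onset_doy[consistent])
  ancova <- NULL
  if (any(resolved & !consistent)) {
    dat <- data.frame(
      doy = as.numeric(observations$onset_doy[resolved]),
      year = as.numeric(observations$year[resolved]),
      group = factor(ifelse(consistent[resolved], "consistent",
                            "inconsistent"),
                     levels = c("consistent", "inconsistent")))
    fit <- stats::lm(doy ~ year * group, data = dat)
    co <- summary(fit)$coefficients
    ancova <- list(
      slope_full = full$slope,
      slope_clean = clean$slope,
      interaction_estimate = unname(co["year:groupinconsistent",
                                       "Estimate"]),
      p_interaction = unname(co["year:groupinconsistent", "Pr(>|t|)"]),
      p_group = unname(co["groupinconsistent", "Pr(>|t|)"]),
      lm = fit)
  } else {
    message("no resolved inconsistent observations; ANCOVA skipped")
  }
  list(full = full, clean = clean, ancova = ancova)
}
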
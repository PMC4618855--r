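# Intra-cluster outlier detection on onset day of year using the classic
# Tukey boxplot rule: points beyond 1.5 interquartile ranges from the
# quartiles are flagged. Quartiles are Tukey hinges (stats::fivenum), the
# convention behind R's boxplot; the convention matters at small n
# because it changes who is flagged.

#' Tukey fences of a sample
#'
#' Quartiles are computed as Tukey hinges — the medians of the lower and
#' upper halves of the sorted data, both halves including the overall
#' median when n is odd — and the fences placed 1.5 interquartile ranges
#' beyond them. Under a normal distribution about 0.7% of the data falls
#' outside the fences.
#'
#' @param values Numeric vector, at least `min_n` values.
#' @param coef Fence multiplier (1.5 for the classic boxplot).
#' @param min_n Minimum sample size; below it quartiles are too unstable
#'   and `NULL` is returned (an undersized-cluster signal).
#' @return List of class `tukey_fences` with `q1`, `median`, `q3`,
#'   `iqr`, `lower`, `upper`, `n`; or `NULL` when `n < min_n`.
#' @examples
#' tukey_fences(c(1:9, 100))   # fences [-4.5, 15.5]; 100 is outside
#' @export
tukey_fences <- function(values, coef = 1.5, min_n = 5L) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < min_n) return(NULL)
  fn <- stats::fivenum(values)
  iqr <- fn[4L] - fn[2L]
  structure(list(q1 = fn[2L], median = fn[3L], q3 = fn[4L], iqr = iqr,
                 lower = fn[2L] - coef * iqr, upper = fn[4L] + coef * iqr,
                 n = n),
            class = "tukey_fences")
}

#' @export
print.tukey_fences <- function(x, ...) {
  cat("Tukey fences (n = ", x$n, "): Q1 = ", x$q1, ", median = ",
      x$median, ", Q3 = ", x$q3, "; fences [", x$lower, ", ", x$upper,
      "]\n", sep = "")
  invisible(x)
}

#' Flag inconsistent observations within contextual clusters
#'
#' For every retained cluster the Tukey fences of the member onset days
#' of year are computed; members below the lower fence are flagged
#' `inconsistent_early`, above the upper fence `inconsistent_late`, and
#' otherwise `consistent`. Observations set aside by the uncertainty
#' filter, and members of clusters too small for stable quartiles, are
#' `unresolved`.
#'
#' @param observations Data frame with `obs_id` and `onset_doy`.
#' @param assignments Data frame from [gmm_assign()] covering the
#'   observations in order.
#' @param partition List with `retained`/`ignored` indices from
#'   [uncertainty_filter()]; default retains everything.
#' @param coef Fence multiplier.
#' @param min_cluster_size Minimum retained members for fences.
#' @return Data frame of class `consistency_flags`: `obs_id`, `cluster`,
#'   `uncertainty`, `flag` (one of consistent / inconsistent_early /
#'   inconsistent_late / unresolved) and `distance_to_fence` (days
#'   outside the fence; 0 when consistent, `NA` when unresolved).
#'   Attribute `fences` holds the per-cluster [tukey_fences()].
#' @export
flag_inconsistent <- function(observations, assignments, partition = NULL,
                              coef = 1.5, min_cluster_size = 5L) {
  n <- nrow(observations)
  if (nrow(assignments) != n)
    stop("assignments must cover all observations", call. = FALSE)
  if (is.null(partition))
    partition <- list(retained = seq_len(n), ignored = integer(0))
  doy <- as.numeric(observations$onset_doy)
  flag <- rep("unresolved", n)
  dist <- rep(NA_real_, n)
  fences <- list()
  for (k in sort(unique(assignments$label[partition$retained]))) {
    members <- intersect(which(assignments$label == k), partition$retained)
    tf <- tukey_fences(doy[members], coef = coef, min_n = min_cluster_size)
    fences[[as.character(k)]] <- tf
    if (is.null(tf)) next                      # undersized: stays unresolved
    early <- members[doy[members] < tf$lower]
    late <- members[doy[members] > tf$upper]
    flag[members] <- "consistent"; dist[members] <- 0
    flag[early] <- "inconsistent_early"; dist[early] <- tf$lower - doy[early]
    flag[late] <- "inconsistent_late"; dist[late] <- doy[late] - tf$upper
  }
  out <- data.frame(obs_id = observations$obs_id,
                    cluster = assignments$label,
                    uncertainty = assignments$uncertainty,
                    flag = factor(flag, levels = .flag_levels),
                    distance_to_fence = dist,
                    stringsAsFactors = FALSE)
  attr(out, "fences") <- fences
  class(out) <- c("consistency_flags", class(out))
  out
}

#' Summarise consistency flags
#'
#' Counts and rates per verdict, per cluster and overall. Because whether
#' unresolved points belong in the denominator is a judgement call, two
#' overall inconsistency rates are reported: over resolved observations
#' (`n - unresolved`) and over all observations.
#'
#' @param flags A `consistency_flags` data frame.
#' @return List with `overall` (named counts), `rate_inconsistent_pct`
#'   (percentage of resolved observations flagged inconsistent),
#'   `rate_inconsistent_all_pct` (denominator includes unresolved),
#'   `rate_consistent_pct`, and `per_cluster` (data frame: cluster, n,
#'   n_consistent, n_early, n_late, n_unresolved, q1, q3, lower, upper).
#' @export
summarize_flags <- function(flags) {
  counts <- table(factor(flags$flag, levels = .flag_levels))
  n <- nrow(flags)
  n_res <- n - counts[["unresolved"]]
  n_inc <- counts[["inconsistent_early"]] + counts[["inconsistent_late"]]
  fences <- attr(flags, "fences")
  per_cluster <- do.call(rbind, lapply(sort(unique(flags$cluster)),
    function(k) {
      f <- flags[flags$cluster == k, ]
      tf <- fences[[as.character(k)]]
      data.frame(cluster = k, n = nrow(f),
                 n_consistent = sum(f$flag == "consistent"),
                 n_early = sum(f$flag == "inconsistent_early"),
                 n_late = sum(f$flag == "inconsistent_late"),
                 n_unresolved = sum(f$flag == "unresolved"),
                 q1 = if (is.null(tf)) NA_real_ else tf$q1,
                 q3 = if (is.null(tf)) NA_real_ else tf$q3,
                 lower = if (is.null(tf)) NA_real_ else tf$lower,
                 upper = if (is.null(tf)) NA_real_ else tf$upper)
    }))
  list(
    overall = c(counts),
    rate_inconsistent_pct = if (n_res > 0) 100 * n_inc / n_res else NA_real_,
    rate_inconsistent_all_pct = if (n > 0) 100 * n_inc / n else NA_real_,
    rate_consistent_pct = if (n_res > 0)
      100 * counts[["consistent"]] / n_res else NA_real_,
    per_cluster = per_cluster
  )
}
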
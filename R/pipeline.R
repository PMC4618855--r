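# End-to-end orchestration: context features -> 2-D embedding ->
# model-based clustering -> intra-cluster flagging -> trend impact.

#' Run the context-aware consistency check end to end
#'
#' The full workflow on an observation table plus daily climate series:
#' build the 11-variable context matrix, standardise it, embed to 2-D
#' with exact t-SNE (a single perplexity, or the 5-50 step-5 sweep when
#' `perplexity = NULL`), cluster the embedding with BIC-selected
#' constrained Gaussian mixtures, set aside points with clustering
#' uncertainty above the threshold, flag intra-cluster Tukey outliers of
#' onset day of year, and quantify the impact of the flagged
#' observations on the long-term trend.
#'
#' @param observations Observation data frame (see
#'   [read_observations()]); a `location_id` column links to the climate
#'   table (defaults to `obs_id`).
#' @param climate Daily climate data frame (see [read_climate()]).
#' @param standardize Z-score the context matrix before embedding
#'   (recommended: the raw variables differ by orders of magnitude).
#' @param perplexity Single t-SNE perplexity, or `NULL` to run
#'   [perplexity_sweep()] over `perplexity_range`.
#' @param perplexity_range Candidate values for the sweep.
#' @param iters t-SNE iterations.
#' @param G_range,families Passed to [gmm_select()].
#' @param uncertainty_threshold Clustering-uncertainty cut-off above
#'   which points are left unresolved (strict inequality).
#' @param min_cluster_size Minimum cluster size for Tukey fences.
#' @param restarts EM restarts per (family, G).
#' @param seed Integer seed governing every stochastic step.
#' @return Object of class `pheno_qc`: `context` (n x 11 matrix),
#'   `embedding` ([tsne()] result), `model` (`phenoflag_gmm`),
#'   `assignments`, `partition`, `flags`, `flag_summary`, `impact`
#'   (from [compare_trends()], or `NULL` when too few consistent
#'   observations), `perplexity_sweep` (component counts per candidate,
#'   when the sweep ran) and `seed`.
#' @examples
#' \donttest{
#' sim <- simulate_phenology(sim_config(n_obs = 150, seed = 2))
#' qc <- pheno_qc(sim$observations, sim$climate, perplexity = 20,
#'                G_range = 1:4, iters = 400, seed = 2)
#' print(qc)
#' }
#' @export
pheno_qc <- function(observations, climate, standardize = TRUE,
                     perplexity = NULL,
                     perplexity_range = seq(5, 50, by = 5),
                     iters = 1000L, G_range = 1:50,
                     families = .gmm_family_codes,
                     uncertainty_threshold = 0.5, min_cluster_size = 5L,
                     restarts = 5L, seed = 1L) {
  X <- context_matrix(observations, climate)
  Z <- if (standardize) standardize_context(X, drop_constant = TRUE) else X

  sweep_G <- NULL
  cluster_fn <- function(Y) gmm_select(Y, G_range = G_range,
                                       families = families,
                                       restarts = restarts, seed = seed)
  if (is.null(perplexity)) {
    sw <- perplexity_sweep(Z, values = perplexity_range,
                           cluster_fn = cluster_fn, seed = seed,
                           iters = iters)
    embedding <- sw$embedding
    model <- sw$models[[which(names(sw$G) == as.character(sw$perplexity))]]
    sweep_G <- sw$G
  } else {
    embedding <- tsne(Z, perplexity = perplexity, seed = seed,
                      iters = iters)
    model <- cluster_fn(embedding$Y)
  }

  assignments <- gmm_assign(model, embedding$Y)
  partition <- uncertainty_filter(assignments,
                                  threshold = uncertainty_threshold)
  flags <- flag_inconsistent(observations, assignments, partition,
                             min_cluster_size = min_cluster_size)
  impact <- tryCatch(compare_trends(observations, flags),
                     error = function(e) NULL)
  structure(
    list(context = X, embedding = embedding, model = model,
         assignments = assignments, partition = partition, flags = flags,
         flag_summary = summarize_flags(flags), impact = impact,
         perplexity_sweep = sweep_G, standardized = standardize,
         seed = as.integer(seed)),
    class = "pheno_qc")
}

#' @export
print.pheno_qc <- function(x, ...) {
  s <- x$flag_summary
  cat("Context-aware consistency check (n = ", nrow(x$flags), ")\n",
      "  embedding: perplexity ", x$embedding$perplexity,
      ", final KL ", format(x$embedding$kl_final, digits = 4), "\n",
      "  clustering: ", x$model$family, ", G = ", x$model$G,
      ", BIC ", format(x$model$bic, digits = 8), "\n", sep = "")
  cat("  flags:", paste(names(s$overall), s$overall, collapse = ", "),
      "\n")
  cat("  inconsistency rate ",
      format(s$rate_inconsistent_pct, digits = 3),
      "% of resolved observations\n", sep = "")
  if (!is.null(x$impact)) {
    cat("  trend full ", format(x$impact$full$slope, digits = 3),
        " vs clean ", format(x$impact$clean$slope, digits = 3),
        " days/year", sep = "")
    if (!is.null(x$impact$ancova))
      cat(" (slope-difference p = ",
          format.pval(x$impact$ancova$p_interaction, digits = 3), ")",
          sep = "")
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.pheno_qc <- function(object, ...) {
  print(object)
  cat("\nPer-cluster fences and verdicts:\n")
  print(object$flag_summary$per_cluster, row.names = FALSE)
  invisible(object)
}

#' @export
plot.pheno_qc <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$embedding$Y, col = x$assignments$label, pch = 16,
                 cex = 0.6, xlab = "t-SNE 1", ylab = "t-SNE 2",
                 main = "contextual clusters")
  inc <- x$flags$flag %in% c("inconsistent_early", "inconsistent_late")
  graphics::points(x$embedding$Y[inc, , drop = FALSE], pch = 1, cex = 1.5)
  graphics::boxplot(split(as.numeric(x$flags$uncertainty),
                          x$flags$cluster),
                    xlab = "cluster", ylab = "uncertainty",
                    main = "clustering uncertainty")
  invisible(x)
}

#' Run the pipeline from a configuration and write its artifacts
#'
#' File-oriented driver used by the command-line interface: reads the
#' observation and climate CSVs, runs [pheno_qc()], and writes every
#' intermediate artifact (context matrix, embedding, BIC table,
#' assignments, flags, flag summary, impact report and a log of all
#' settings) into `out_dir`. Reruns with the same configuration are
#' identical.
#'
#' @param config Named list (or YAML file read with
#'   [read_pipeline_config()]): `observations`, `climate` (input paths),
#'   `out_dir`, and optionally `standardize`, `perplexity`,
#'   `perplexity_range`, `iters`, `G_range` (length-2 `c(min, max)` or
#'   vector), `families`, `uncertainty_threshold`, `min_cluster_size`,
#'   `restarts`, `seed`.
#' @return The `pheno_qc` object, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  need <- setdiff(c("observations", "climate", "out_dir"), names(config))
  if (length(need) > 0L)
    stop("config is missing field(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  get_or <- function(nm, default) if (is.null(config[[nm]])) default else
    config[[nm]]
  observations <- read_observations(config$observations)
  if ("location_id" %in% names(config) && is.character(config$location_id))
    names(observations)[names(observations) == config$location_id] <-
      "location_id"
  climate <- read_climate(config$climate)
  G_range <- get_or("G_range", 1:50)
  if (length(G_range) == 2L) G_range <- seq(G_range[1], G_range[2])

  qc <- pheno_qc(
    observations, climate,
    standardize = get_or("standardize", TRUE),
    perplexity = get_or("perplexity", NULL),
    perplexity_range = get_or("perplexity_range", seq(5, 50, by = 5)),
    iters = get_or("iters", 1000L),
    G_range = G_range,
    families = get_or("families", .gmm_family_codes),
    uncertainty_threshold = get_or("uncertainty_threshold", 0.5),
    min_cluster_size = get_or("min_cluster_size", 5L),
    restarts = get_or("restarts", 5L),
    seed = get_or("seed", 1L))

  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(obs_id = rownames(qc$context), qc$context),
                   file.path(out, "context.csv"), row.names = FALSE)
  utils::write.csv(data.frame(obs_id = observations$obs_id,
                              y1 = qc$embedding$Y[, 1],
                              y2 = qc$embedding$Y[, 2],
                              perplexity_used = qc$embedding$perplexity,
                              seed = qc$embedding$seed),
                   file.path(out, "embedding.csv"), row.names = FALSE)
  bt <- qc$model$bic_table
  fam <- gmm_families()
  utils::write.csv(cbind(fam[match(rownames(bt), fam$code),
                             c("distribution", "volume", "shape",
                               "orientation")],
                         bic_max = qc$model$bic_by_family, bt),
                   file.path(out, "bic_table.csv"), row.names = FALSE)
  utils::write.csv(data.frame(obs_id = observations$obs_id,
                              label = qc$assignments$label,
                              uncertainty = qc$assignments$uncertainty),
                   file.path(out, "assignments.csv"), row.names = FALSE)
  write_flagged(observations[, c(.obs_required_cols, .obs_optional_cols)],
                qc$flags, file.path(out, "flags.csv"))
  utils::write.csv(qc$flag_summary$per_cluster,
                   file.path(out, "flag_summary.csv"), row.names = FALSE)
  if (!is.null(qc$impact)) {
    imp <- rbind(
      data.frame(subset = "full", slope = qc$impact$full$slope,
                 se = qc$impact$full$se_slope, p = qc$impact$full$p_slope,
                 n = qc$impact$full$n,
                 days_per_decade = decadal_rate(qc$impact$full)),
      data.frame(subset = "clean", slope = qc$impact$clean$slope,
                 se = qc$impact$clean$se_slope,
                 p = qc$impact$clean$p_slope, n = qc$impact$clean$n,
                 days_per_decade = decadal_rate(qc$impact$clean)))
    if (!is.null(qc$impact$ancova))
      imp <- rbind(imp, data.frame(
        subset = "ancova_interaction",
        slope = qc$impact$ancova$interaction_estimate, se = NA_real_,
        p = qc$impact$ancova$p_interaction, n = qc$impact$full$n,
        days_per_decade =
          decadal_rate(qc$impact$ancova$interaction_estimate)))
    utils::write.csv(imp, file.path(out, "impact.csv"), row.names = FALSE)
  }
  log <- c(paste0("phenoflag run, seed ", qc$seed),
           paste0("standardize: ", qc$standardized),
           paste0("perplexity: ", qc$embedding$perplexity,
                  if (!is.null(qc$perplexity_sweep)) " (chosen by sweep)"),
           paste0("iters: ", qc$embedding$iters),
           paste0("model: ", qc$model$family, " G=", qc$model$G,
                  " BIC=", format(qc$model$bic, digits = 10)),
           paste0("uncertainty_threshold: ",
                  get_or("uncertainty_threshold", 0.5)),
           paste0("min_cluster_size: ", get_or("min_cluster_size", 5L)),
           paste0("flags: ",
                  paste(names(qc$flag_summary$overall),
                        qc$flag_summary$overall, collapse = ", ")))
  writeLines(log, file.path(out, "run.log"))
  invisible(qc)
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file; keys as documented in [run_pipeline()].
#' @param overrides Named list of values taking precedence over the file
#'   (used by the command line for flag overrides).
#' @return Named list.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  config <- yaml::read_yaml(path)
  if (!is.list(config))
    stop("malformed config file: ", path, call. = FALSE)
  for (nm in names(overrides)) config[[nm]] <- overrides[[nm]]
  config
}
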
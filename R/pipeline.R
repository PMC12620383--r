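# Pipeline orchestration: configuration, network-moderator attachment,
# end-to-end execution and result-bundle output.

# evaluated outside run_config(), whose `cohort_config` argument shadows
# the constructor
.default_cohort_config <- function(seed) cohort_config(seed = seed)

#' Attach network moderators to a cohort
#'
#' Builds one friendship network per school per wave and joins the per-pupil
#' metrics (clustering, eigenvector, closeness, betweenness) and the
#' school-level Gini degree coefficient to the cohort as
#' `<metric>_w<wave>` columns.
#'
#' @param cohort Cohort data frame.
#' @param nominations Nomination edge list with `wave` column.
#' @param symmetrization Projection rule for metric computation.
#' @param waves Waves to process.
#' @return The cohort with network moderator columns added; school
#'   summaries are attached as the `"school_networks"` attribute.
#' @export
attach_network_moderators <- function(cohort, nominations,
                                      symmetrization = "union",
                                      waves = c(0L, 1L)) {
  schools <- unique(cohort$school_id)
  summaries <- list()
  for (w in waves) {
    per_school <- lapply(schools, function(s) {
      roster <- cohort$pupil_id[cohort$school_id == s]
      noms_s <- nominations[nominations$nominator_id %in% roster, ,
                            drop = FALSE]
      net <- build_network(noms_s, roster, wave = w,
                           symmetrization = symmetrization, school_id = s)
      suppressWarnings(school_network_metrics(net))
    })
    nodes <- do.call(rbind, lapply(per_school, `[[`, "nodes"))
    idx <- match(as.character(cohort$pupil_id), nodes$pupil_id)
    for (m in c("clustering", "eigenvector", "closeness", "betweenness")) {
      cohort[[paste0(m, "_w", w)]] <- nodes[[m]][idx]
    }
    sch <- do.call(rbind, lapply(per_school, `[[`, "school"))
    cohort[[paste0("gini_degree_w", w)]] <-
      sch$gini_degree[match(cohort$school_id, sch$school_id)]
    summaries[[as.character(w)]] <- sch
  }
  attr(cohort, "school_networks") <- do.call(rbind, summaries)
  cohort
}

#' Pipeline run configuration
#'
#' @param seed Integer seed governing all randomness in synthetic mode.
#' @param synthetic Generate the cohort (TRUE) or read it from
#'   `cohort_path` / `nominations_path` (FALSE).
#' @param cohort_config A [cohort_config()] (synthetic mode); defaults to
#'   `cohort_config(seed)`.
#' @param cohort_path,nominations_path CSV inputs (when `synthetic = FALSE`).
#' @param out_dir Optional output directory for the result bundle.
#' @param moderators Moderator names to analyse (default: all in
#'   `moderator_specs`).
#' @param outcomes Outcome names (default: all in the outcome specs).
#' @param peer_groups,waves Grid axes.
#' @param symmetrization Network projection rule for centralities.
#' @param hc Robust covariance variant for linear fits.
#' @param alpha_sig Interaction significance criterion.
#' @param family_alpha Holm-Bonferroni family level.
#' @param outcome_specs,moderator_specs Specification tables.
#' @return A `run_config` object.
#' @export
run_config <- function(seed,
                       synthetic = TRUE,
                       cohort_config = NULL,
                       cohort_path = NULL, nominations_path = NULL,
                       out_dir = NULL,
                       moderators = NULL, outcomes = NULL,
                       peer_groups = c("friends", "class", "year"),
                       waves = c(0L, 1L),
                       symmetrization = "union", hc = "HC1",
                       alpha_sig = 0.01, family_alpha = 0.05,
                       outcome_specs = default_outcome_specs(),
                       moderator_specs = default_moderator_specs()) {
  if (missing(seed) || !is_count(seed)) pm_stop("run_config(): integer seed required")
  if (alpha_sig <= 0 || alpha_sig >= 1 || family_alpha <= 0 || family_alpha >= 1) {
    pm_stop("alpha values must lie in (0, 1)")
  }
  if (synthetic && is.null(cohort_config)) {
    cohort_config <- .default_cohort_config(seed)
  }
  moderators <- moderators %||% moderator_specs$name
  outcomes <- outcomes %||% outcome_specs$name
  bad <- setdiff(moderators, moderator_specs$name)
  if (length(bad) > 0) pm_stop("unknown moderator(s): %s", paste(bad, collapse = ", "))
  bad <- setdiff(outcomes, outcome_specs$name)
  if (length(bad) > 0) pm_stop("unknown outcome(s): %s", paste(bad, collapse = ", "))
  structure(list(seed = as.integer(seed), synthetic = synthetic,
                 cohort_config = cohort_config, cohort_path = cohort_path,
                 nominations_path = nominations_path, out_dir = out_dir,
                 moderators = moderators, outcomes = outcomes,
                 peer_groups = peer_groups, waves = as.integer(waves),
                 symmetrization = symmetrization, hc = hc,
                 alpha_sig = alpha_sig, family_alpha = family_alpha,
                 outcome_specs = outcome_specs,
                 moderator_specs = moderator_specs),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields map directly onto [run_config()] arguments; a
#' `cohort_config` block maps onto [cohort_config()] arguments. The seed
#' must be present in the file or supplied here.
#'
#' @param path YAML file.
#' @param seed Optional seed overriding the file's.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, seed = NULL) {
  if (!file.exists(path)) pm_stop("config file '%s' not found", path)
  y <- yaml::read_yaml(path)
  seed <- seed %||% y$seed
  if (is.null(seed)) pm_stop("seed required (config file or argument)")
  cc <- NULL
  if (!is.null(y$cohort_config)) {
    cc <- do.call(cohort_config, c(list(seed = seed), y$cohort_config))
  }
  args <- y[setdiff(names(y), c("seed", "cohort_config"))]
  do.call(run_config, c(list(seed = seed, cohort_config = cc), args))
}

.read_inputs <- function(config) {
  for (p in c(config$cohort_path, config$nominations_path)) {
    if (is.null(p) || !file.exists(p)) {
      pm_stop("input file '%s' not found; aborting before any model fit",
              p %||% "(unset)")
    }
  }
  list(cohort = utils::read.csv(config$cohort_path, stringsAsFactors = FALSE),
       nominations = utils::read.csv(config$nominations_path,
                                     stringsAsFactors = FALSE))
}

#' Run the full moderation-of-peer-influence pipeline
#'
#' Executes every stage for a [run_config()]: cohort acquisition (synthetic
#' generation or CSV input), per-school network construction and network
#' moderators, the peer-exposure table, the per-moderator model grids,
#' probing (simple slopes and 95%/99% Johnson-Neyman regions) of every
#' interaction at or below the significance criterion, per-moderator
#' summaries, multiverse summaries, and a provenance record. Deterministic
#' given the configuration and seed.
#'
#' @param config A `run_config`.
#' @return A result bundle: `cohort`, `nominations`, `school_networks`,
#'   `exposures`, `grids` (per moderator), `summaries`, `probes`,
#'   `multiverse`, `provenance`. Written to `config$out_dir` as delimited
#'   text plus a JSON archive when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$synthetic) {
    gen <- generate_cohort(config$cohort_config)
    cohort <- gen$cohort
    nominations <- gen$nominations
  } else {
    inp <- .read_inputs(config)
    cohort <- inp$cohort
    nominations <- inp$nominations
  }
  cohort <- attach_network_moderators(cohort, nominations,
                                      symmetrization = config$symmetrization,
                                      waves = config$waves)
  exposures <- build_exposure_table(cohort, nominations, config$outcomes,
                                    peer_groups = config$peer_groups,
                                    waves = config$waves)
  grids <- lapply(config$moderators, function(m) {
    run_model_grid(m, cohort, exposures, config$outcomes,
                   moderator_specs = config$moderator_specs,
                   peer_groups = config$peer_groups, waves = config$waves,
                   hc = config$hc, alpha_sig = config$alpha_sig)
  })
  names(grids) <- config$moderators
  summaries <- lapply(grids, summarize_moderator,
                      alpha_sig = config$alpha_sig,
                      family_alpha = config$family_alpha)
  probes <- list()
  for (g in grids) {
    for (f in g$fits) {
      if (is.null(f$unfit_reason) && !is.na(f$p_interaction) &&
          f$p_interaction <= config$alpha_sig) {
        key <- with(f$spec, sprintf("%s|%s|%s|w%d", moderator, outcome,
                                    peer_group, wave))
        probes[[key]] <- list(
          slopes = simple_slopes(f),
          jn95 = johnson_neyman(f, 95),
          jn99 = johnson_neyman(f, 99))
      }
    }
  }
  all_results <- do.call(rbind, lapply(grids, `[[`, "results"))
  rownames(all_results) <- NULL
  multiverse <- multiverse_tables(all_results, alpha_sig = config$alpha_sig,
                                  outcome_specs = config$outcome_specs)
  provenance <- list(
    package_version = as.character(utils::packageVersion("peermod")),
    seed = config$seed, synthetic = config$synthetic,
    symmetrization = config$symmetrization, hc = config$hc,
    alpha_sig = config$alpha_sig, family_alpha = config$family_alpha,
    peer_definition = "directed out-neighbours (friends the pupil nominated)",
    metric_scaling = "node metrics and Gini degree reported x10",
    n_pupils = nrow(cohort), n_models = nrow(all_results),
    timestamp = format(Sys.time(), tz = "UTC"))
  bundle <- list(cohort = cohort, nominations = nominations,
                 school_networks = attr(cohort, "school_networks"),
                 exposures = exposures, grids = grids,
                 summaries = summaries, probes = probes,
                 multiverse = multiverse, results = all_results,
                 provenance = provenance)
  if (!is.null(config$out_dir)) write_result_bundle(bundle, config$out_dir)
  bundle
}

#' Write a result bundle as delimited text plus a JSON archive
#'
#' @param bundle Result of [run_pipeline()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_result_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    cohort = file.path(out_dir, "cohort.csv"),
    nominations = file.path(out_dir, "nominations.csv"),
    school_networks = file.path(out_dir, "school_networks.csv"),
    exposures = file.path(out_dir, "exposures.csv"),
    results = file.path(out_dir, "model_results.csv"),
    summaries = file.path(out_dir, "moderator_summaries.csv"),
    heatmap = file.path(out_dir, "multiverse_heatmap.csv"),
    archive = file.path(out_dir, "results.json"))
  utils::write.csv(bundle$cohort, paths["cohort"], row.names = FALSE)
  utils::write.csv(bundle$nominations, paths["nominations"], row.names = FALSE)
  utils::write.csv(bundle$school_networks, paths["school_networks"],
                   row.names = FALSE)
  utils::write.csv(bundle$exposures, paths["exposures"], row.names = FALSE)
  utils::write.csv(bundle$results, paths["results"], row.names = FALSE)
  utils::write.csv(summary_table(bundle$summaries), paths["summaries"],
                   row.names = FALSE)
  utils::write.csv(bundle$multiverse$heatmap, paths["heatmap"],
                   row.names = FALSE)
  archive <- list(provenance = bundle$provenance,
                  summaries = lapply(bundle$summaries, unclass),
                  multiverse_stats = bundle$multiverse$stats)
  jsonlite::write_json(archive, paths["archive"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(paths)
}

#' Flatten moderator summaries into an overview table
#'
#' One row per moderator, mirroring a results-overview table: grid size,
#' significant-interaction counts (total, per peer group, per direction),
#' binomial meta-test p-values and the conclusion.
#'
#' @param summaries List of `moderator_summary` objects.
#' @return Data frame.
#' @export
summary_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s) {
    data.frame(moderator = s$moderator, n_models = s$n_models,
               k_sig = s$k_sig, pct_sig = s$pct_sig,
               k_friends = s$k_sig_by_group[["friends"]],
               k_class = s$k_sig_by_group[["class"]],
               k_year = s$k_sig_by_group[["year"]],
               k_pos = s$k_pos, k_neg = s$k_neg,
               dir_pos = s$direction_labels[["pos"]],
               dir_neg = s$direction_labels[["neg"]],
               binom_p = s$binom_p, binom_p_pos = s$binom_p_pos,
               binom_p_neg = s$binom_p_neg,
               n_holm_survivors = s$n_holm_survivors,
               n_unfit = s$n_unfit, conclusion = s$conclusion,
               stringsAsFactors = FALSE)
  }))
}
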
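## End-to-end pipeline: (simulate or read) -> validate -> impute ->
## quantify -> normalize -> SOM -> two-level merge -> profile -> tier ->
## chart export, with every artifact and the effective configuration
## written to a run directory. All randomness flows from the single seed.

#' Pipeline configuration
#'
#' @param out_dir Run directory for artifacts (created if absent).
#' @param seed Integer seed governing all randomness in the run.
#' @param cohort_path Optional CSV of an existing cohort; when `NULL` a
#'   synthetic cohort is generated from `params`.
#' @param params Generator configuration ([cohort_parameters()]).
#' @param missingness Named vector passed to [inject_missingness()] after
#'   simulation (`NULL` to skip; ignored when reading from file).
#' @param grid SOM grid specification ([som_grid()]).
#' @param k Number of high-level clusters, or `"auto"` for Davies-Bouldin
#'   selection over 2..10.
#' @param merge_strategy `"ward"` or `"kmeans"` (see [merge_nodes()]).
#' @param thresholds Risk-tier cutoffs ([risk_thresholds()]).
#' @param exclude_outcome_like Drop outcome-adjacent feature columns (see
#'   [build_feature_matrix()]).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1, cohort_path = NULL,
                            params = cohort_parameters(),
                            missingness = reference_missingness(),
                            grid = som_grid(), k = 5,
                            merge_strategy = c("ward", "kmeans"),
                            thresholds = risk_thresholds(),
                            exclude_outcome_like = FALSE) {
  merge_strategy <- match.arg(merge_strategy)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 cohort_path = cohort_path, params = params,
                 missingness = missingness, grid = grid, k = k,
                 merge_strategy = merge_strategy,
                 thresholds = thresholds,
                 exclude_outcome_like = exclude_outcome_like),
            class = "pipeline_config")
}

#' Run the full clustering and risk-stratification pipeline
#'
#' Executes impute -> quantify -> normalize -> SOM -> merge -> profile ->
#' tier -> export and writes seven artifacts to the run directory
#' (cohort.csv, similarity.csv, features.csv, som_model.json,
#' assignment.csv, profiles.json, chart.json) plus the effective
#' configuration (config_echo.json) and a stage log (run_log.txt). Output
#' files contain no timestamps, so a rerun with the same configuration and
#' seed is byte-identical. Any stage error aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the fitted objects (`cohort`, `labels`,
#'   `features`, `som`, `assignment`, `profiles`, `tiers`, `chart`,
#'   diagnostics) and `artifacts` (named vector of the 7 artifact paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(stage, msg) {
    line <- sprintf("[%s] %s", stage, msg)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  art <- function(f) file.path(config$out_dir, f)

  ## --- input cohort ---------------------------------------------------
  labels <- NULL
  if (is.null(config$cohort_path)) {
    gen <- stage("simulate", generate_cohort(config$params, config$seed))
    cohort <- gen$cohort
    labels <- gen$labels
    if (!is.null(config$missingness)) {
      cohort <- stage("simulate",
                      inject_missingness(cohort, config$missingness,
                                         seed = config$seed + 1L))
    }
    note("simulate", sprintf("generated %d patients", n_patients(cohort)))
  } else {
    cohort <- stage("read", read_cohort(config$cohort_path))
    note("read", sprintf("read %d patients from %s", n_patients(cohort),
                         config$cohort_path))
  }
  report <- validate_cohort(cohort)
  if (nrow(report$errors)) {
    stop("pipeline stage 'validate' failed: ", nrow(report$errors),
         " invariant violation(s); first: ", report$errors$rule[1],
         call. = FALSE)
  }
  note("validate", sprintf("%d warnings, %d missing cells",
                           nrow(report$warnings), sum(report$missing_counts)))
  write_cohort(cohort, art("cohort.csv"))

  ## --- impute + quantify ----------------------------------------------
  cohort_imp <- stage("impute", impute_missing(cohort))
  note("impute", sprintf("%d variables imputed",
                         nrow(attr(cohort_imp, "imputation_log"))))
  counts <- stage("quantify", count_cooccurrence(cohort_imp))
  S <- cooccurrence_similarity(counts)
  ybar <- base_prevalence(cohort_imp)
  F_c <- quantify_labels(S, ybar)
  sim_df <- data.frame(label = rownames(S), total = counts$O_i,
                       round(S, 10), check.names = FALSE)
  utils::write.csv(sim_df, art("similarity.csv"), row.names = FALSE)
  note("quantify", paste("F:", paste(sprintf("%s=%.4f", names(F_c), F_c),
                                     collapse = " ")))

  ## --- features + normalization ---------------------------------------
  features <- stage("features",
                    build_feature_matrix(cohort_imp, F_c,
                                         config$exclude_outcome_like))
  wgs <- within_group_stats(features[, intersect(numeric_feature_names(),
                                                 colnames(features)),
                                     drop = FALSE])
  note("features", sprintf("SSw = %.4g, Vw = %.4g (n=%d, g=%d)",
                           wgs$SSw, wgs$Vw, wgs$n, wgs$g))
  norm <- stage("normalize", normalize_features(features))
  utils::write.csv(data.frame(patient_id = rownames(features),
                              norm$matrix, check.names = FALSE),
                   art("features.csv"), row.names = FALSE)

  ## --- SOM + two-level merge ------------------------------------------
  som <- stage("som", {
    m <- init_som(config$grid, norm$matrix, seed = config$seed + 2L)
    train_som(m, norm$matrix)
  })
  note("som", sprintf("quantization error %.5g after %d epochs",
                      utils::tail(som$qe_log, 1), length(som$qe_log)))
  jsonlite::write_json(
    list(grid = unclass(som$grid), codebook = som$codebook,
         qe_log = som$qe_log, seed = som$seed),
    art("som_model.json"), auto_unbox = TRUE, digits = NA)
  bmu <- assign_bmu(som, norm$matrix)
  k <- if (identical(config$k, "auto")) {
    stage("merge", select_k(som, bmu, 2:10))
  } else {
    config$k
  }
  node_map <- stage("merge", merge_nodes(som, bmu, k,
                                         strategy = config$merge_strategy,
                                         seed = config$seed + 3L))
  assignment <- assign_patients(bmu, node_map)
  note("merge", sprintf("k = %d, cluster sizes %s", assignment$k,
                        paste(assignment$counts, collapse = "/")))
  utils::write.csv(data.frame(patient_id = cohort_data(cohort)$patient_id,
                              node_index = bmu$bmu,
                              cluster_index = assignment$cluster),
                   art("assignment.csv"), row.names = FALSE)

  ## --- profiles, tiers, chart -----------------------------------------
  profiles <- stage("profile", profile_clusters(cohort_imp, assignment))
  tiers <- stage("tier", assign_risk_tiers(profiles, config$thresholds))
  note("tier", paste(sprintf("cluster %d: %s", tiers$cluster, tiers$tier),
                     collapse = "; "))
  jsonlite::write_json(lapply(profiles, function(p) p),
                       art("profiles.json"), auto_unbox = TRUE, digits = NA)
  chart <- export_chart_data(profiles, tiers, assignment,
                             patient_ids = cohort_data(cohort)$patient_id,
                             path = art("chart.json"))

  cfg_echo <- config
  cfg_echo$grid <- unclass(cfg_echo$grid)
  cfg_echo$params <- lapply(unclass(cfg_echo$params), function(x) x)
  jsonlite::write_json(unclass(cfg_echo), art("config_echo.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  writeLines(log_lines, art("run_log.txt"))

  artifacts <- c(cohort = art("cohort.csv"), similarity = art("similarity.csv"),
                 features = art("features.csv"), som = art("som_model.json"),
                 assignment = art("assignment.csv"),
                 profiles = art("profiles.json"), chart = art("chart.json"))
  invisible(list(cohort = cohort, labels = labels, quantified = F_c,
                 similarity = S, counts = counts, within_group = wgs,
                 features = features, normalized = norm$matrix,
                 norm_params = norm$params, som = som, bmu = bmu,
                 node_map = node_map, assignment = assignment,
                 profiles = profiles, tiers = tiers, chart = chart,
                 validation = report, artifacts = artifacts))
}
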
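#' Pipeline stage: build and write the feature table
#'
#' Composes structure parsing, WCN/ASA/RSA computation and score
#' aggregation into the per-mutant feature table and writes it as CSV
#' (fixed column order `mutant_id, rsa, wcn, ss, mean_score, functional`)
#' together with a JSON run log recording the configuration and its hash.
#'
#' @param structure A `deltol_structure` or a PDB file path.
#' @param mutants A mutant data frame or a CSV/TSV path
#'   (see [read_mutant_table()]).
#' @param scores Optional: a data frame of `mutant_id`/`mean_score`, a
#'   named numeric vector, or a directory of per-mutant score files.
#' @param out_dir Output directory.
#' @param chain Optional chain filter when `structure` is a path.
#' @inheritParams asa_per_residue
#' @return The feature table, invisibly. Files: `feature_table.csv`,
#'   `features_log.json`.
#' @export
run_features <- function(structure, mutants, scores = NULL, out_dir = ".",
                         chain = NULL, probe_radius = 1.4,
                         n_sphere_points = 960) {
  if (is.character(structure)) structure <- read_structure(structure, chain = chain)
  if (is.character(mutants)) mutants <- read_mutant_table(mutants)
  if (is.character(scores) && length(scores) == 1 && dir.exists(scores)) {
    scores <- read_score_files(scores)
  }
  tab <- build_feature_table(structure, mutants, scores,
                             probe_radius = probe_radius,
                             n_sphere_points = n_sphere_points)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  readr::write_csv(tab, file.path(out_dir, "feature_table.csv"))
  config <- list(structure_id = attr(structure, "id"), chain = chain,
                 probe_radius = probe_radius,
                 n_sphere_points = n_sphere_points,
                 n_mutants = nrow(tab))
  write_run_log(config, file.path(out_dir, "features_log.json"))
  invisible(tab)
}

#' Pipeline stage: evaluate all models with both learners
#'
#' Runs [evaluate_models()] for the requested learners, writes one CSV per
#' learner (`model, model_auc, mean_cv_auc, se_cv_auc`, sorted by
#' descending cross-validated AUC) and a JSON report comparing the top two
#' models of each learner by Welch t-test on their repetition AUCs.
#'
#' @param table Feature table or path to a feature-table CSV.
#' @param out_dir Output directory.
#' @inheritParams repeated_cv_auc
#' @param learners Which learners to run.
#' @return A named list of evaluation tibbles, invisibly. Files:
#'   `evaluation_<learner>.csv`, `evaluation_report.json`,
#'   `evaluation_log.json`.
#' @export
run_evaluate <- function(table, out_dir = ".", k = 10, repetitions = 100,
                         seed = 1, learners = c("logistic", "svm_rbf"),
                         cost = 1) {
  if (is.character(table)) table <- read_feature_table(table)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  results <- list()
  comparisons <- list()
  for (learner in learners) {
    ev <- evaluate_models(table, learner, k = k, repetitions = repetitions,
                          seed = seed, cost = cost)
    readr::write_csv(dplyr::select(ev, -"cv"),
                     file.path(out_dir, paste0("evaluation_", learner, ".csv")))
    cmp <- compare_models(ev$cv[[1]], ev$cv[[2]])
    comparisons[[learner]] <- as.list(cmp)
    results[[learner]] <- ev
  }
  config <- list(k = k, repetitions = repetitions, seed = seed,
                 learners = learners, cost = cost, n_mutants = nrow(table))
  jsonlite::write_json(
    list(config = c(config, config_hash = rlang::hash(config)),
         top_model_comparison = comparisons),
    file.path(out_dir, "evaluation_report.json"),
    auto_unbox = TRUE, digits = NA
  )
  write_run_log(config, file.path(out_dir, "evaluation_log.json"))
  invisible(results)
}

#' Pipeline stage: group statistics and PCA
#'
#' Writes the per-predictor Welch t-tests, the secondary-structure
#' contingency table with its chi-squared test, and the predictor PCA
#' (rotation, variances, per-mutant scores).
#'
#' @param table Feature table or path to a feature-table CSV.
#' @param out_dir Output directory.
#' @return A list with elements `t_tests`, `contingency`, `chi_square`,
#'   `pca`, invisibly. Files: `group_tests.csv`, `contingency.json`,
#'   `pca_rotation.csv`, `pca_variances.csv`, `pca_scores.csv`,
#'   `stats_log.json`.
#' @export
run_stats <- function(table, out_dir = ".") {
  if (is.character(table)) table <- read_feature_table(table)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tt <- predictor_group_tests(table)
  ct <- ss_contingency(table)
  chi <- chi_square_test(ct)
  pca <- pca_predictors(table)

  readr::write_csv(tt, file.path(out_dir, "group_tests.csv"))
  jsonlite::write_json(
    list(
      counts = as.data.frame(ct$counts),
      tolerated_fraction = as.list(ct$tolerated_fraction),
      chi_square = as.list(chi)
    ),
    file.path(out_dir, "contingency.json"), auto_unbox = TRUE, digits = NA
  )
  rot <- tibble::as_tibble(as.data.frame(pca$rotation), rownames = "column")
  readr::write_csv(rot, file.path(out_dir, "pca_rotation.csv"))
  readr::write_csv(glance(pca), file.path(out_dir, "pca_variances.csv"))
  readr::write_csv(pca$scores, file.path(out_dir, "pca_scores.csv"))
  write_run_log(list(n_mutants = nrow(table)),
                file.path(out_dir, "stats_log.json"))
  invisible(list(t_tests = tt, contingency = ct, chi_square = chi, pca = pca))
}

#' Read a feature table written by [run_features()]
#'
#' @param path Path to the CSV.
#' @return A feature-table tibble with `ss` as a factor and `functional`
#'   logical.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("feature table not found: ", path))
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("mutant_id", "rsa", "wcn", "ss", "functional")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    rlang::abort(paste0("feature table lacks column(s): ",
                        paste(missing, collapse = ", ")))
  }
  tab$ss <- factor(tolower(as.character(tab$ss)), levels = .ss_levels)
  tab$functional <- as.logical(tab$functional)
  if (!"mean_score" %in% names(tab)) tab$mean_score <- NA_real_
  tab
}

write_run_log <- function(config, path) {
  jsonlite::write_json(
    list(config = config, config_hash = rlang::hash(config),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
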
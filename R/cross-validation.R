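#' Random k-fold partition
#'
#' Partitions row indices `1:n` into k disjoint random folds whose sizes
#' differ by at most one. Folds are plain random draws, not stratified by
#' class.
#'
#' @param n Number of rows.
#' @param k Number of folds, `2 <= k <= n`.
#' @param seed Optional integer seed; the same seed reproduces the same
#'   partition and the global RNG state is left untouched.
#' @return A list of k integer vectors covering `1:n` exactly once.
#' @examples
#' lengths(kfold_partition(72, 10, seed = 1)) # two 8s, eight 7s
#' @export
kfold_partition <- function(n, k, seed = NULL) {
  stopifnot(k >= 2, k <= n)
  draw <- function() sample.int(n)
  shuffled <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  unname(split(shuffled, rep(seq_len(k), length.out = n)))
}

#' Pooled out-of-fold classifier scores
#'
#' For each fold, fits the classifier on the other k-1 folds and scores
#' the held-out rows; the k held-out score sets are pooled so that every
#' row is scored exactly once by a model that never saw it. Pooled scores
#' feed one ROC curve per cross-validation round.
#'
#' @param table Feature table.
#' @param predictors Predictor subset (see [encode_design()]).
#' @param learner `"logistic"` or `"svm_rbf"`.
#' @param folds A partition from [kfold_partition()].
#' @param cost,gamma SVM parameters, passed to [fit_svm_rbf()].
#' @return Numeric vector of out-of-fold scores aligned with the rows of
#'   `table`.
#' @export
pooled_cv_scores <- function(table, predictors, learner, folds,
                             cost = 1, gamma = NULL) {
  design <- encode_design(table, predictors, learner)
  n <- nrow(design$x)
  stopifnot(sort(unlist(folds)) == seq_len(n))
  scores <- rep(NA_real_, n)
  for (test_idx in folds) {
    train_idx <- setdiff(seq_len(n), test_idx)
    y_train <- design$y[train_idx]
    if (length(unique(y_train)) < 2) {
      rlang::abort("training fold contains a single class",
                   class = "deltol_degenerate_fold")
    }
    train_design <- structure(
      list(x = design$x[train_idx, , drop = FALSE], y = y_train,
           predictors = predictors, learner = learner),
      class = "deltol_design"
    )
    scores[test_idx] <- fit_and_score(
      train_design, design$x[test_idx, , drop = FALSE], learner,
      cost = cost, gamma = gamma
    )
  }
  scores
}

#' Repeated cross-validated pooled-ROC AUC
#'
#' The primary performance measure: for each of `repetitions` rounds a
#' fresh random k-fold partition is drawn, out-of-fold scores are pooled
#' into one ROC curve, and its AUC recorded; the summary is the mean and
#' standard error (sd across rounds / sqrt(rounds)) of these
#' cross-validated AUCs. A round whose partition produces a single-class
#' training fold is re-drawn with a derived seed (the event is reported).
#'
#' @inheritParams pooled_cv_scores
#' @param k Number of folds.
#' @param repetitions Number of cross-validation rounds.
#' @param seed Integer base seed; round r uses `seed + r`.
#' @return An object of class `deltol_cv`: `model` (display label),
#'   `predictors`, `learner`, `repetition_aucs`, `mean_auc`, `se_auc`,
#'   `k`, `repetitions`, `seed`, `redraws`.
#' @examples
#' tab <- synth_feature_table(synth_params(n_mutants = 60, seed = 7))
#' cv <- repeated_cv_auc(tab, c("rsa", "wcn"), "logistic", repetitions = 5)
#' glance(cv)
#' @export
repeated_cv_auc <- function(table, predictors, learner = c("logistic", "svm_rbf"),
                            k = 10, repetitions = 100, seed = 1,
                            cost = 1, gamma = NULL) {
  learner <- match.arg(learner)
  n <- nrow(table)
  stopifnot(repetitions >= 1, k >= 2, k <= n)
  aucs <- numeric(repetitions)
  redraws <- 0L
  labels <- as.logical(table$functional)
  for (r in seq_len(repetitions)) {
    attempt <- 0L
    repeat {
      fold_seed <- seed + r + attempt * 7919L
      folds <- kfold_partition(n, k, seed = fold_seed)
      scores <- tryCatch(
        pooled_cv_scores(table, predictors, learner, folds,
                         cost = cost, gamma = gamma),
        deltol_degenerate_fold = function(e) NULL
      )
      if (!is.null(scores)) break
      attempt <- attempt + 1L
      redraws <- redraws + 1L
      if (attempt > 100L) {
        rlang::abort("could not draw a partition with both classes in every training fold")
      }
    }
    aucs[r] <- roc_auc(scores, labels)$auc
  }
  if (redraws > 0) {
    rlang::inform(sprintf("re-drew %d degenerate partition(s)", redraws))
  }
  structure(
    list(
      model = predictor_label(predictors), predictors = predictors,
      learner = learner, repetition_aucs = aucs,
      mean_auc = mean(aucs),
      se_auc = stats::sd(aucs) / sqrt(repetitions),
      k = k, repetitions = repetitions, seed = seed, redraws = redraws
    ),
    class = "deltol_cv"
  )
}

#' @export
print.deltol_cv <- function(x, ...) {
  cat(sprintf("%s (%s): mean CV AUC = %.3f +/- %.4f (%d x %d-fold)\n",
              x$model, x$learner, x$mean_auc, x$se_auc, x$repetitions, x$k))
  invisible(x)
}

#' @method tidy deltol_cv
#' @export
tidy.deltol_cv <- function(x, ...) {
  tibble::tibble(repetition = seq_along(x$repetition_aucs),
                 auc = x$repetition_aucs)
}

#' @method glance deltol_cv
#' @export
glance.deltol_cv <- function(x, ...) {
  tibble::tibble(
    model = x$model, learner = x$learner,
    mean_cv_auc = x$mean_auc, se_cv_auc = x$se_auc,
    k = x$k, repetitions = x$repetitions, seed = x$seed, redraws = x$redraws
  )
}

#' In-sample AUC of the full fit
#'
#' Fits the classifier on the entire data set and computes the AUC of the
#' in-sample scores (the "Model AUC" companion to the cross-validated AUC).
#'
#' @inheritParams pooled_cv_scores
#' @return A single AUC value.
#' @export
full_fit_auc <- function(table, predictors, learner = c("logistic", "svm_rbf"),
                         cost = 1, gamma = NULL) {
  learner <- match.arg(learner)
  design <- encode_design(table, predictors, learner)
  check_two_classes(design$y)
  scores <- if (learner == "logistic") {
    fit_logistic(design)$fitted
  } else {
    fit_svm_rbf(design, cost = cost, gamma = gamma)$decision_values
  }
  roc_auc(scores, design$y)$auc
}

#' Compare two cross-validation summaries
#'
#' Two-sample t-test on the repetition-wise AUC lists of two models.
#' Welch's unequal-variance test by default; set `paired = TRUE` when both
#' summaries were produced with shared partition seeds.
#'
#' @param a,b `deltol_cv` objects with at least 2 repetitions each.
#' @param paired Pair AUCs by repetition index.
#' @return A one-row tibble: models, mean difference, `statistic` (t),
#'   `df`, `p_value`, `method`.
#' @export
compare_models <- function(a, b, paired = FALSE) {
  stopifnot(inherits(a, "deltol_cv"), inherits(b, "deltol_cv"),
            length(a$repetition_aucs) >= 2, length(b$repetition_aucs) >= 2)
  ht <- stats::t.test(a$repetition_aucs, b$repetition_aucs,
                      paired = paired, var.equal = FALSE)
  tibble::tibble(
    model_a = a$model, model_b = b$model,
    estimate = a$mean_auc - b$mean_auc,
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    method = if (paired) "paired t" else "Welch t"
  )
}

#' Evaluate all predictor subsets with one learner
#'
#' Scores every non-empty subset of the four predictors by full-fit AUC
#' and repeated cross-validated AUC, mirroring the structure of the
#' reference summary tables.
#'
#' @inheritParams repeated_cv_auc
#' @return A tibble with one row per model, sorted by descending
#'   `mean_cv_auc`: `model`, `model_auc`, `mean_cv_auc`, `se_cv_auc`, and
#'   a list column `cv` of the underlying `deltol_cv` objects.
#' @export
evaluate_models <- function(table, learner = c("logistic", "svm_rbf"),
                            k = 10, repetitions = 100, seed = 1,
                            cost = 1, gamma = NULL) {
  learner <- match.arg(learner)
  specs <- model_specs(learner)
  rows <- purrr::map(specs$predictors, function(p) {
    cv <- repeated_cv_auc(table, p, learner, k = k, repetitions = repetitions,
                          seed = seed, cost = cost, gamma = gamma)
    tibble::tibble(
      model = cv$model,
      model_auc = full_fit_auc(table, p, learner, cost = cost, gamma = gamma),
      mean_cv_auc = cv$mean_auc,
      se_cv_auc = cv$se_auc,
      cv = list(cv)
    )
  })
  purrr::list_rbind(rows) |>
    dplyr::arrange(dplyr::desc(.data$mean_cv_auc))
}
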
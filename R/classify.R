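#' Enumerate classifier model specifications
#'
#' All 15 non-empty subsets of the four predictors (RSA, WCN, SS, mean
#' score), in deterministic order: by subset size, then lexically by
#' predictor column name.
#'
#' @param learner `"logistic"` or `"svm_rbf"`.
#' @return A tibble with columns `model` (display label such as
#'   `"RSA + WCN"`), `predictors` (list column of column-name vectors) and
#'   `learner`.
#' @examples
#' nrow(model_specs("logistic")) # 15
#' @export
model_specs <- function(learner = c("logistic", "svm_rbf")) {
  learner <- match.arg(learner)
  vars <- c("mean_score", "rsa", "ss", "wcn")
  subsets <- unlist(
    lapply(seq_along(vars), function(k) {
      utils::combn(vars, k, simplify = FALSE)
    }),
    recursive = FALSE
  )
  tibble::tibble(
    model = vapply(subsets, predictor_label, character(1)),
    predictors = subsets,
    learner = learner
  )
}

predictor_label <- function(predictors) {
  display <- c(rsa = "RSA", wcn = "WCN", ss = "SS", mean_score = "Mean Score")
  # display order follows the field's convention: RSA + WCN + SS + Mean Score
  ord <- c("rsa", "wcn", "ss", "mean_score")
  paste(display[intersect(ord, predictors)], collapse = " + ")
}

#' Encode a feature table as a numeric design
#'
#' Continuous predictors (`rsa`, `wcn`, `mean_score`) are copied as-is;
#' the categorical `ss` is expanded to indicator columns. For the logistic
#' learner one reference level (helix, alphabetically first) is dropped to
#' keep the design full rank; for the SVM and PCA all three indicators are
#' retained.
#'
#' @param table A feature table (see [build_feature_table()]).
#' @param predictors Character vector, non-empty subset of
#'   `c("rsa", "wcn", "ss", "mean_score")`.
#' @param learner `"logistic"` or `"svm_rbf"` (controls SS coding).
#' @return A list of class `deltol_design`: `x` (numeric matrix), `y`
#'   (logical labels, `TRUE` = tolerated), `predictors`, `learner`.
#' @export
encode_design <- function(table, predictors, learner = c("logistic", "svm_rbf")) {
  learner <- match.arg(learner)
  if (length(predictors) == 0) rlang::abort("predictor set must be non-empty")
  bad <- setdiff(predictors, c("rsa", "wcn", "ss", "mean_score"))
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown predictor(s): ", paste(bad, collapse = ", ")))
  }
  used <- c(intersect(predictors, c("rsa", "wcn", "mean_score")),
            if ("ss" %in% predictors) "ss", "functional")
  miss <- !stats::complete.cases(table[, used, drop = FALSE])
  if (any(miss)) {
    rlang::abort(paste0("missing values in rows: ",
                        paste(which(miss), collapse = ", ")))
  }
  cols <- list()
  for (p in intersect(c("rsa", "wcn", "mean_score"), predictors)) {
    cols[[p]] <- as.numeric(table[[p]])
  }
  if ("ss" %in% predictors) {
    ss <- factor(as.character(table$ss), levels = .ss_levels)
    if (anyNA(ss)) rlang::abort("unknown secondary-structure category in ss")
    levs <- if (learner == "logistic") .ss_levels[-1] else .ss_levels
    for (l in levs) cols[[paste0("ss_", l)]] <- as.numeric(ss == l)
  }
  x <- do.call(cbind, cols)
  colnames(x) <- names(cols)
  structure(
    list(x = x, y = as.logical(table$functional),
         predictors = predictors, learner = learner),
    class = "deltol_design"
  )
}

check_two_classes <- function(y) {
  if (length(unique(y)) < 2) {
    rlang::abort("degenerate labels: both classes must be present")
  }
}

#' Fit a logistic-regression classifier
#'
#' Maximum-likelihood logistic fit (binomial GLM with logit link) of the
#' tolerated/non-tolerated label on the encoded predictors. Complete
#' separation is detected from the usual fitted-probability warning and
#' reported; the fit at the iteration cap is still returned.
#'
#' @param design A `deltol_design` from [encode_design()].
#' @return A list of class `deltol_logit`: `fit` (the `glm` object),
#'   `coefficients`, `fitted` (in-sample probabilities), `separation`
#'   (logical).
#' @export
fit_logistic <- function(design) {
  stopifnot(inherits(design, "deltol_design"))
  check_two_classes(design$y)
  df <- as.data.frame(design$x)
  df$.y <- design$y
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., family = stats::binomial(), data = df),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg) ||
          grepl("algorithm did not converge", msg)) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (separation) {
    rlang::inform("logistic fit: complete or quasi-complete separation detected; returning the iteration-cap fit")
  }
  structure(
    list(fit = fit, coefficients = stats::coef(fit),
         fitted = unname(stats::fitted(fit)), separation = separation),
    class = "deltol_logit"
  )
}

#' @method tidy deltol_logit
#' @export
tidy.deltol_logit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std_error = s[, "Std. Error"],
    statistic = s[, "z value"],
    p_value = s[, "Pr(>|z|)"]
  )
}

#' @method glance deltol_logit
#' @export
glance.deltol_logit <- function(x, ...) {
  tibble::tibble(
    null_deviance = x$fit$null.deviance, deviance = x$fit$deviance,
    aic = x$fit$aic, n = length(x$fitted), separation = x$separation
  )
}

predict_logit <- function(model, newdata_x) {
  df <- as.data.frame(newdata_x)
  unname(stats::predict(model$fit, newdata = df, type = "response"))
}

#' Fit a radial-kernel support vector machine
#'
#' Soft-margin SVM with a radial basis kernel at the defaults used in the
#' reference analysis: cost of constraint violation C = 1 and kernel width
#' gamma = 1/d, where d is the number of encoded predictor columns.
#' Features are standardized (centered and unit-scaled) with training-set
#' statistics, which the underlying \pkg{e1071} fit applies to any new
#' data as well. Continuous decision values, oriented so that larger means
#' more likely tolerated, are used for ROC ranking.
#'
#' @param design A `deltol_design` from [encode_design()].
#' @param cost Constraint-violation cost C.
#' @param gamma Kernel width; default `1/ncol(design$x)`.
#' @return A list of class `deltol_svm`: `fit`, `gamma`, `cost`,
#'   `decision_values` (in-sample, oriented), `flip` (internal orientation
#'   flag).
#' @export
fit_svm_rbf <- function(design, cost = 1, gamma = NULL) {
  stopifnot(inherits(design, "deltol_design"))
  check_two_classes(design$y)
  d <- ncol(design$x)
  if (is.null(gamma)) gamma <- 1 / d
  y <- factor(design$y, levels = c(FALSE, TRUE))
  const <- apply(design$x, 2, stats::var) == 0
  fit <- suppressWarnings(e1071::svm(
    x = design$x, y = y, kernel = "radial", cost = cost, gamma = gamma,
    scale = !const
  ))
  pred <- stats::predict(fit, design$x, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # e1071 labels the decision column "<first>/<second>"; positive values
  # favor the first class, so flip when that first class is FALSE
  flip <- startsWith(colnames(dv)[1], "FALSE")
  structure(
    list(fit = fit, gamma = gamma, cost = cost,
         decision_values = if (flip) -as.numeric(dv) else as.numeric(dv),
         flip = flip),
    class = "deltol_svm"
  )
}

#' @method glance deltol_svm
#' @export
glance.deltol_svm <- function(x, ...) {
  tibble::tibble(
    gamma = x$gamma, cost = x$cost, n_support = x$fit$tot.nSV,
    n = length(x$decision_values)
  )
}

predict_svm <- function(model, newdata_x) {
  pred <- stats::predict(model$fit, newdata_x, decision.values = TRUE)
  dv <- as.numeric(attr(pred, "decision.values"))
  if (model$flip) -dv else dv
}

# fit + score dispatch shared by CV and full fits: returns the ranking
# score (logistic: probability of tolerated; SVM: oriented decision value).
# Per-fold separation messages are silenced; the flag stays on the fit object.
fit_and_score <- function(train_design, test_x, learner, cost = 1, gamma = NULL) {
  if (learner == "logistic") {
    model <- suppressMessages(fit_logistic(train_design))
    predict_logit(model, test_x)
  } else {
    model <- fit_svm_rbf(train_design, cost = cost, gamma = gamma)
    predict_svm(model, test_x)
  }
}
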
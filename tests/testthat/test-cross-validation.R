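test_that("k-fold partitions are balanced, exhaustive and seed-reproducible", {
  folds <- kfold_partition(72, 10, seed = 1)
  expect_equal(sort(lengths(folds)), c(rep(7, 8), 8, 8))
  expect_equal(sort(unlist(folds)), 1:72)
  expect_equal(folds, kfold_partition(72, 10, seed = 1))
  expect_false(identical(folds, kfold_partition(72, 10, seed = 2)))

  loo <- kfold_partition(10, 10, seed = 3)
  expect_equal(sort(lengths(loo)), rep(1, 10))
  expect_error(kfold_partition(5, 6))
})

test_that("every row is scored exactly once by a model that never saw it", {
  tab <- synth_feature_table(synth_params(n_mutants = 20, n_tolerated = 10, seed = 2))
  folds <- kfold_partition(20, 10, seed = 4)
  scores <- pooled_cv_scores(tab, c("rsa", "wcn"), "logistic", folds)
  expect_length(scores, 20)
  expect_false(anyNA(scores))
})

test_that("leave-one-out pooled scores match a hand-rolled glm loop", {
  tab <- synth_feature_table(synth_params(n_mutants = 16, n_tolerated = 8, seed = 6))
  folds <- as.list(1:16)
  got <- pooled_cv_scores(tab, c("rsa", "wcn"), "logistic", folds)
  df <- data.frame(y = tab$functional, rsa = tab$rsa, wcn = tab$wcn)
  oracle <- vapply(1:16, function(i) {
    fit <- glm(y ~ rsa + wcn, binomial(), data = df[-i, ])
    unname(predict(fit, newdata = df[i, , drop = FALSE], type = "response"))
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("a single-class training fold raises a degenerate-fold condition", {
  tab <- synth_feature_table(synth_params(n_mutants = 20, n_tolerated = 2, seed = 2))
  pos <- which(tab$functional)
  folds <- list(pos, setdiff(1:20, pos)) # both positives held out together
  expect_error(
    pooled_cv_scores(tab, "rsa", "logistic", folds),
    class = "deltol_degenerate_fold"
  )
})

test_that("repeated CV is deterministic per seed and summarises correctly", {
  tab <- synth_feature_table(synth_params(seed = 10))
  cv1 <- repeated_cv_auc(tab, c("rsa", "wcn"), "logistic", repetitions = 4, seed = 9)
  cv2 <- repeated_cv_auc(tab, c("rsa", "wcn"), "logistic", repetitions = 4, seed = 9)
  expect_equal(cv1$repetition_aucs, cv2$repetition_aucs)
  expect_length(cv1$repetition_aucs, 4)
  expect_equal(cv1$mean_auc, mean(cv1$repetition_aucs))
  expect_equal(cv1$se_auc, sd(cv1$repetition_aucs) / sqrt(4))
  expect_equal(glance(cv1)$model, "RSA + WCN")
})

test_that("a perfectly informative predictor gives AUC 1 in every round, hence se 0", {
  tab <- synth_feature_table(synth_params(n_mutants = 40, n_tolerated = 20,
                                          rsa = list(tolerated = c(10, 0.1),
                                                     non_tolerated = c(-10, 0.1)),
                                          seed = 3))
  cv <- suppressMessages(
    repeated_cv_auc(tab, "rsa", "logistic", repetitions = 5, seed = 1)
  )
  expect_equal(cv$repetition_aucs, rep(1, 5))
  expect_equal(cv$se_auc, 0)
  expect_equal(suppressMessages(full_fit_auc(tab, "rsa", "logistic")), 1)
})

test_that("full-fit AUC is optimistic relative to cross-validated AUC on signal", {
  tab <- synth_feature_table(synth_params(seed = 12))
  cv <- repeated_cv_auc(tab, c("rsa", "wcn", "ss"), "logistic",
                        repetitions = 20, seed = 2)
  full <- full_fit_auc(tab, c("rsa", "wcn", "ss"), "logistic")
  expect_gt(full, cv$mean_auc - 2 * cv$se_auc)
})

test_that("label-shuffled data drives the full-fit AUC toward chance", {
  tab <- synth_feature_table(synth_params(n_mutants = 1000, n_tolerated = 500,
                                          seed = 5))
  tab$functional <- withr::with_seed(11, sample(tab$functional))
  expect_lt(abs(full_fit_auc(tab, c("rsa", "wcn"), "logistic") - 0.5), 0.07)
})

test_that("model comparison reproduces the Welch formulas and detects separation", {
  a_list <- c(0.81, 0.84, 0.80, 0.83, 0.82)
  b_list <- c(0.70, 0.74, 0.69, 0.75)
  fake_cv <- function(aucs, model) {
    structure(list(model = model, repetition_aucs = aucs,
                   mean_auc = mean(aucs),
                   se_auc = sd(aucs) / sqrt(length(aucs))),
              class = "deltol_cv")
  }
  cmp <- compare_models(fake_cv(a_list, "A"), fake_cv(b_list, "B"))
  o <- oracle_welch(a_list, b_list)
  expect_equal(cmp$statistic, o$t, tolerance = 1e-12)
  expect_equal(cmp$df, o$df, tolerance = 1e-12)
  expect_equal(cmp$p_value, o$p, tolerance = 1e-12)

  same <- compare_models(fake_cv(a_list, "A"), fake_cv(a_list, "A"))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  hi <- fake_cv(0.9 + rnorm(100, 0, 1e-4), "hi")
  lo <- fake_cv(0.5 + rnorm(100, 0, 1e-4), "lo")
  expect_lt(compare_models(hi, lo)$p_value, 1e-3)
  expect_error(compare_models(fake_cv(0.5, "x"), fake_cv(a_list, "A")))
})

test_that("evaluate_models scores all 15 subsets sorted by cross-validated AUC", {
  tab <- synth_feature_table(synth_params(seed = 20))
  ev <- evaluate_models(tab, "logistic", repetitions = 2, seed = 1)
  expect_equal(nrow(ev), 15)
  expect_equal(ev$mean_cv_auc, sort(ev$mean_cv_auc, decreasing = TRUE))
  expect_true(all(c("model", "model_auc", "mean_cv_auc", "se_cv_auc") %in% names(ev)))
})
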
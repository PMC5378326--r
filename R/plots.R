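#' Class-conditional distributions of the continuous predictors
#'
#' Boxplots of RSA, WCN and mean score split by functional status, the
#' standard first look at a deletion feature table.
#'
#' @param table Feature table.
#' @return A ggplot object.
#' @export
plot_feature_distributions <- function(table) {
  vars <- c("rsa", "wcn", if (!all(is.na(table$mean_score))) "mean_score")
  long <- tidyr::pivot_longer(
    dplyr::select(table, dplyr::all_of(c(vars, "functional"))),
    dplyr::all_of(vars), names_to = "predictor", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$functional, y = .data$value,
                                     fill = .data$functional)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~predictor, scales = "free_y") +
    ggplot2::scale_x_discrete(labels = c(`TRUE` = "tolerated",
                                         `FALSE` = "non-tolerated")) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#d7301f",
                                          `FALSE` = "#0570b0")) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Compare cross-validated AUCs of two learners
#'
#' Scatter of mean cross-validated AUC per model, one learner against the
#' other, with the identity line.
#'
#' @param eval_a,eval_b Evaluation tibbles from [evaluate_models()] (their
#'   models are matched by name).
#' @param names Axis labels.
#' @return A ggplot object.
#' @export
plot_cv_comparison <- function(eval_a, eval_b,
                               names = c("logistic", "svm_rbf")) {
  joined <- dplyr::inner_join(
    dplyr::select(eval_a, "model", a = "mean_cv_auc"),
    dplyr::select(eval_b, "model", b = "mean_cv_auc"),
    by = "model"
  )
  ggplot2::ggplot(joined, ggplot2::aes(x = .data$a, y = .data$b)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste("mean CV AUC,", names[1]),
                  y = paste("mean CV AUC,", names[2])) +
    ggplot2::theme_minimal()
}
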
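#' ROC curve and AUC
#'
#' Builds the receiver operating characteristic by sweeping a threshold
#' over the unique score values (larger score = more likely tolerated) and
#' computes the area under the curve by the trapezoidal rule. With ties
#' handled by grouping equal scores, the trapezoidal AUC equals the
#' tie-corrected rank statistic
#' \eqn{P(s^+ > s^-) + \frac{1}{2} P(s^+ = s^-)}.
#'
#' @param scores Numeric vector of classifier scores.
#' @param labels Logical (or 0/1) vector; `TRUE` = positive (tolerated).
#' @return An object of class `deltol_roc`: a list with `curve` (tibble of
#'   `threshold`, `fpr`, `tpr`), `auc`, `n_pos`, `n_neg`. `tidy()` returns
#'   the curve, `glance()` the AUC, `autoplot()` draws the curve.
#' @examples
#' r <- roc_auc(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE))
#' r$auc # 1
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels),
            all(is.finite(scores)))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    rlang::abort("AUC undefined: both classes must be present")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  n <- length(s)
  # last index of each tie group of equal scores
  keep <- c(s[-n] != s[-1], TRUE)
  tpr <- cumsum(y)[keep] / n_pos
  fpr <- cumsum(!y)[keep] / n_neg
  curve <- tibble::tibble(
    threshold = c(Inf, s[keep]),
    fpr = c(0, fpr),
    tpr = c(0, tpr)
  )
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + curve$tpr[-1]) / 2)
  structure(
    list(curve = curve, auc = auc, n_pos = n_pos, n_neg = n_neg),
    class = "deltol_roc"
  )
}

#' @export
print.deltol_roc <- function(x, ...) {
  cat(sprintf("ROC: %d positives, %d negatives, AUC = %.4f\n",
              x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

#' @method tidy deltol_roc
#' @export
tidy.deltol_roc <- function(x, ...) x$curve

#' @method glance deltol_roc
#' @export
glance.deltol_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @rdname roc_auc
#' @param object A `deltol_roc` object.
#' @param ... Unused.
#' @method autoplot deltol_roc
#' @export
autoplot.deltol_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC curve (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}
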
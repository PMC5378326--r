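#' Principal component analysis of the structural predictors
#'
#' Encodes the predictors (RSA, WCN, mean score when available, and all
#' three secondary-structure indicators), centers and unit-scales every
#' column, and eigendecomposes the resulting correlation structure.
#' Components are ordered by decreasing variance; the sign of each axis is
#' fixed so that its largest-magnitude loading is positive, making results
#' deterministic. Zero-variance columns are dropped with a message.
#'
#' @param table Feature table.
#' @return An object of class `deltol_pca`: `rotation` (loadings matrix,
#'   columns PC1, PC2, ...), `explained_variance` (eigenvalues, summing to
#'   the number of retained columns), `scores` (tibble of per-mutant
#'   component coordinates with `mutant_id` and `functional`), `columns`
#'   (encoded column names), `center`, `scale`.
#' @examples
#' tab <- synth_feature_table(synth_params(seed = 3))
#' p <- pca_predictors(tab)
#' p$explained_variance
#' @export
pca_predictors <- function(table) {
  stopifnot(nrow(table) >= 3)
  preds <- c("rsa", "wcn",
             if ("mean_score" %in% names(table) && !all(is.na(table$mean_score))) "mean_score",
             "ss")
  design <- encode_design(table, preds, learner = "svm_rbf") # keeps all 3 SS levels
  x <- design$x
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    rlang::inform(paste0("dropping zero-variance column(s): ",
                         paste(colnames(x)[v == 0], collapse = ", ")))
    x <- x[, v > 0, drop = FALSE]
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  z <- scale(x, center = ctr, scale = scl)
  eig <- eigen(stats::cor(x), symmetric = TRUE)
  eig$values <- pmax(eig$values, 0) # guard against -1e-16 from collinearity
  rotation <- eig$vectors
  # sign convention: largest-magnitude loading on each axis is positive
  for (j in seq_len(ncol(rotation))) {
    lead <- which.max(abs(rotation[, j]))
    if (rotation[lead, j] < 0) rotation[, j] <- -rotation[, j]
  }
  dimnames(rotation) <- list(colnames(x), paste0("PC", seq_len(ncol(rotation))))
  scores <- z %*% rotation
  score_tab <- tibble::as_tibble(as.data.frame(scores))
  if ("mutant_id" %in% names(table)) {
    score_tab <- dplyr::bind_cols(
      tibble::tibble(mutant_id = table$mutant_id,
                     functional = as.logical(table$functional)),
      score_tab
    )
  }
  structure(
    list(rotation = rotation,
         explained_variance = eig$values,
         scores = score_tab,
         columns = colnames(x), center = ctr, scale = scl),
    class = "deltol_pca"
  )
}

#' @export
print.deltol_pca <- function(x, ...) {
  pct <- 100 * x$explained_variance / sum(x$explained_variance)
  cat("PCA of", length(x$columns), "predictor columns\n")
  cat("variance explained:",
      paste(sprintf("%s %.1f%%", colnames(x$rotation), pct), collapse = ", "),
      "\n")
  invisible(x)
}

#' @method tidy deltol_pca
#' @export
tidy.deltol_pca <- function(x, ...) {
  as_tibble(as.data.frame.table(x$rotation, responseName = "loading")) |>
    rlang::set_names(c("column", "component", "loading")) |>
    dplyr::mutate(column = as.character(.data$column),
                  component = as.character(.data$component))
}

#' @method glance deltol_pca
#' @export
glance.deltol_pca <- function(x, ...) {
  tibble::tibble(
    component = colnames(x$rotation),
    variance = x$explained_variance,
    proportion = x$explained_variance / sum(x$explained_variance)
  )
}

#' @rdname pca_predictors
#' @param object A `deltol_pca` object.
#' @param ... Unused.
#' @method autoplot deltol_pca
#' @export
autoplot.deltol_pca <- function(object, ...) {
  sc <- object$scores
  load <- tibble::tibble(
    column = rownames(object$rotation),
    PC1 = object$rotation[, 1],
    PC2 = object$rotation[, 2]
  )
  r <- max(abs(c(sc$PC1, sc$PC2)))
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if ("functional" %in% names(sc)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$functional)) +
      ggplot2::scale_colour_manual(
        values = c(`TRUE` = "#d7301f", `FALSE` = "#0570b0"),
        labels = c(`TRUE` = "tolerated", `FALSE` = "non-tolerated"),
        name = NULL
      )
  } else {
    p <- p + ggplot2::geom_point()
  }
  p +
    ggplot2::geom_segment(
      data = load,
      ggplot2::aes(x = 0, y = 0, xend = .data$PC1 * r, yend = .data$PC2 * r),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "grey30"
    ) +
    ggplot2::geom_text(
      data = load,
      ggplot2::aes(x = .data$PC1 * r * 1.08, y = .data$PC2 * r * 1.08,
                   label = .data$column),
      size = 3, colour = "grey30"
    ) +
    ggplot2::labs(x = "PC1", y = "PC2") +
    ggplot2::theme_minimal()
}
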
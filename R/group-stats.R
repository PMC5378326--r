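#' Welch t-test between tolerated and non-tolerated groups
#'
#' Two-sided two-sample t-test with unequal variances (Welch) comparing a
#' continuous structural property between the two functional classes.
#'
#' @param values Numeric vector.
#' @param labels Logical vector, `TRUE` = tolerated; both groups need at
#'   least 2 values.
#' @return A one-row tibble: group means, mean difference
#'   (tolerated - non-tolerated), `statistic` (t), `df`, `p_value`.
#' @examples
#' group_t_test(c(1, 2, 3, 7, 8, 9), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
#' @export
group_t_test <- function(values, labels) {
  labels <- as.logical(labels)
  stopifnot(length(values) == length(labels), !anyNA(values), !anyNA(labels))
  if (sum(labels) < 2 || sum(!labels) < 2) {
    rlang::abort("each group needs at least 2 values")
  }
  ht <- stats::t.test(values[labels], values[!labels], var.equal = FALSE)
  tibble::tibble(
    mean_tolerated = mean(values[labels]),
    mean_non_tolerated = mean(values[!labels]),
    estimate = mean(values[labels]) - mean(values[!labels]),
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value
  )
}

#' Group tests for every continuous predictor
#'
#' Runs [group_t_test()] for RSA, WCN and (when present) mean score of a
#' feature table.
#'
#' @param table Feature table.
#' @return A tibble with one row per predictor tested.
#' @export
predictor_group_tests <- function(table) {
  vars <- c("rsa", "wcn", if (!all(is.na(table$mean_score))) "mean_score")
  purrr::map(vars, function(v) {
    dplyr::bind_cols(
      tibble::tibble(predictor = v),
      group_t_test(table[[v]], table$functional)
    )
  }) |>
    purrr::list_rbind()
}

#' Cross-tabulate functional status by secondary structure
#'
#' Counts tolerated and non-tolerated deletions per secondary-structure
#' category (loop/helix/sheet) and the tolerated fraction per category.
#'
#' @param table Feature table with complete `ss` and `functional` columns,
#'   or a pre-counted tibble with columns `functional`, `ss`, `n` (as
#'   returned by [egfp_ss_counts()]).
#' @return A list of class `deltol_contingency`: `counts` (2x3 matrix,
#'   rows tolerated/non-tolerated, columns loop/helix/sheet),
#'   `tolerated_fraction` (named per-category fractions).
#' @examples
#' ss_contingency(egfp_ss_counts())$tolerated_fraction
#' @export
ss_contingency <- function(table) {
  cols <- c("loop", "helix", "sheet")
  ss <- as.character(table$ss)
  bad <- setdiff(unique(ss), cols)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown secondary-structure category: ",
                        paste(bad, collapse = ", ")))
  }
  if (anyNA(table$functional)) rlang::abort("functional labels contain NA")
  w <- if ("n" %in% names(table)) table$n else rep(1L, nrow(table))
  counts <- matrix(0L, nrow = 2, ncol = 3,
                   dimnames = list(c("tolerated", "non_tolerated"), cols))
  for (i in seq_along(ss)) {
    r <- if (table$functional[i]) 1L else 2L
    counts[r, ss[i]] <- counts[r, ss[i]] + w[i]
  }
  totals <- colSums(counts)
  frac <- ifelse(totals > 0, counts["tolerated", ] / totals, NA_real_)
  structure(list(counts = counts, tolerated_fraction = frac),
            class = "deltol_contingency")
}

#' @export
print.deltol_contingency <- function(x, ...) {
  print(x$counts)
  cat("tolerated fraction:",
      paste(sprintf("%s %.1f%%", names(x$tolerated_fraction),
                    100 * x$tolerated_fraction), collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy deltol_contingency
#' @export
tidy.deltol_contingency <- function(x, ...) {
  as_tibble(as.data.frame.table(x$counts, responseName = "n")) |>
    rlang::set_names(c("functional", "ss", "n")) |>
    dplyr::mutate(functional = .data$functional == "tolerated",
                  ss = as.character(.data$ss))
}

#' Pearson chi-squared test on a contingency table
#'
#' Plain Pearson chi-squared test of independence, without continuity
#' correction, with `df = (rows - 1) * (cols - 1)`.
#'
#' @param counts A `deltol_contingency` object or a count matrix.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @examples
#' chi_square_test(ss_contingency(egfp_ss_counts()))
#' @export
chi_square_test <- function(counts) {
  m <- if (inherits(counts, "deltol_contingency")) counts$counts else as.matrix(counts)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    rlang::abort("degenerate table: zero row or column marginal")
  }
  ht <- stats::chisq.test(m, correct = FALSE)
  tibble::tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value
  )
}
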
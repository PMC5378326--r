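#' Parse a table of protein-design scores
#'
#' Reads one mutant's design scores (Rosetta-style total scores, one per
#' modeled structure; lower = more favorable) from a delimited table.
#' Comma- and whitespace-delimited dialects are auto-detected from the
#' header row.
#'
#' @param file Path to the score table.
#' @param score_column Name of the column holding the totals.
#' @return Numeric vector of scores, in file order.
#' @examples
#' f <- tempfile()
#' writeLines(c("total_score description", "-500 a", "-510 b", "-490 c"), f)
#' parse_score_table(f)
#' @export
parse_score_table <- function(file, score_column = "total_score") {
  if (!file.exists(file)) rlang::abort(paste0("score file not found: ", file))
  header <- readLines(file, n = 1)
  if (grepl(",", header, fixed = TRUE)) {
    tab <- readr::read_csv(file, show_col_types = FALSE, progress = FALSE)
  } else {
    tab <- utils::read.table(file, header = TRUE, stringsAsFactors = FALSE)
  }
  if (!score_column %in% names(tab)) {
    rlang::abort(sprintf("score file %s lacks column '%s'", file, score_column))
  }
  if (nrow(tab) == 0) rlang::abort(paste0("score file has no data rows: ", file))
  scores <- suppressWarnings(as.numeric(tab[[score_column]]))
  if (anyNA(scores)) {
    rlang::abort(sprintf("non-numeric entries in column '%s' of %s",
                         score_column, file))
  }
  scores
}

#' Mean design score
#'
#' The predictor used for classification is the arithmetic mean of the
#' design totals over all modeled structures of one mutant (nominally 100:
#' 25 initial models times 4 relaxations). A count differing from
#' `expected_count` warns but does not fail.
#'
#' @param scores Numeric vector of per-structure totals.
#' @param expected_count Nominal number of models per mutant.
#' @return The arithmetic mean.
#' @examples
#' mean_score(c(-500, -510, -490)) # -500
#' @export
mean_score <- function(scores, expected_count = 100) {
  if (length(scores) == 0) rlang::abort("empty score set")
  stopifnot(all(is.finite(scores)))
  if (length(scores) != expected_count) {
    rlang::warn(sprintf("score set has %d entries (expected %d)",
                        length(scores), expected_count))
  }
  mean(scores)
}

#' Aggregate per-mutant score files to mean scores
#'
#' Reads one score file per mutant (file name pattern `<mutant_id>.*`) and
#' reduces each to its mean score.
#'
#' @param paths Character vector of score-file paths, or a single directory
#'   whose files are all score tables.
#' @inheritParams parse_score_table
#' @inheritParams mean_score
#' @return A tibble with columns `mutant_id`, `mean_score`, `n_models`.
#' @export
read_score_files <- function(paths, score_column = "total_score",
                             expected_count = 100) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, full.names = TRUE)
  }
  if (length(paths) == 0) rlang::abort("no score files given")
  purrr::map(paths, function(p) {
    s <- parse_score_table(p, score_column)
    tibble::tibble(
      mutant_id = sub("\\.[^.]*$", "", basename(p)),
      mean_score = mean_score(s, expected_count),
      n_models = length(s)
    )
  }) |>
    purrr::list_rbind()
}
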
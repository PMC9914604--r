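# Scoring actual vs. predicted heart rates: per-volunteer error percentage
# and the summary metrics (MAE, MSE, accuracy, fraction exactly correct).
# Two transcribed result tables of 20 volunteers each ship as CSV fixtures
# in inst/extdata/ (table3.csv, table4.csv).

#' Per-pair error percentage
#'
#' `100 * |actual - predicted| / actual`, at full precision. This is the
#' relative-error definition that reproduces every published per-volunteer
#' error cell in the shipped tables to within 0.002 (the published cells mix
#' round-half-up and truncation at the third decimal).
#'
#' @param actual actual bpm (> 0); vectorized.
#' @param predicted predicted bpm; vectorized.
#' @return error percentage(s), full precision.
#' @export
error_percent <- function(actual, predicted) {
  if (any(actual <= 0)) stop_input("'actual' must be positive")
  100 * abs(actual - predicted) / actual
}

#' Read actual/predicted bpm pairs from CSV
#'
#' Expects a header with columns `volunteer_id`, `actual_bpm`,
#' `predicted_bpm` (extra columns are kept and ignored).
#'
#' @param path CSV path.
#' @return data.frame of validated pairs.
#' @export
read_rate_pairs <- function(path) {
  if (!file.exists(path)) stop_input("pairs file does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("volunteer_id", "actual_bpm", "predicted_bpm")
  if (!all(need %in% names(df))) {
    stop_input("pairs CSV must have header columns: ", paste(need, collapse = ", "))
  }
  validate_pairs(df)
  df
}

validate_pairs <- function(pairs) {
  if (nrow(pairs) == 0L) stop_input("no rate pairs supplied")
  b <- c(pairs$actual_bpm, pairs$predicted_bpm)
  if (any(!is.finite(b)) || any(b < 20) || any(b > 300)) {
    stop_input("bpm values must lie in [20, 300]")
  }
  invisible(pairs)
}

#' Summarize actual/predicted pairs into an evaluation report
#'
#' Computes per-pair error percentages and the summary metrics:
#' MAE (mean |actual - predicted|, bpm), MSE (mean squared difference,
#' bpm^2), `accuracy_percent` = 100 - mean error % ("pipeline accuracy,
#' definition D1"), and `correct_fraction_percent` = share of pairs
#' predicted exactly.
#'
#' @param pairs data.frame with columns `volunteer_id`, `actual_bpm`,
#'   `predicted_bpm` (as from [read_rate_pairs()]).
#' @return An `evaluation_report`: list with `pairs` (including an
#'   `error_percent` column), `mae`, `mse`, `accuracy_percent`,
#'   `correct_fraction_percent`, `n`.
#' @export
summarize_rate_pairs <- function(pairs) {
  validate_pairs(pairs)
  err <- error_percent(pairs$actual_bpm, pairs$predicted_bpm)
  d <- pairs$actual_bpm - pairs$predicted_bpm
  pairs$error_percent <- err
  structure(
    list(pairs = pairs,
         mae = mean(abs(d)),
         mse = mean(d^2),
         accuracy_percent = 100 - mean(err),
         correct_fraction_percent = 100 * mean(d == 0),
         n = nrow(pairs)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Heart-rate evaluation over", x$n, "pairs\n\n")
  tab <- x$pairs[, c("volunteer_id", "actual_bpm", "predicted_bpm",
                     "error_percent")]
  tab$error_percent <- sprintf("%.3f%%", tab$error_percent)
  print(tab, row.names = FALSE)
  cat(sprintf(
    "\nMAE: %.3f bpm   MSE: %.3f bpm^2\naccuracy (D1, 100 - mean error %%): %.3f%%\nexactly correct: %.1f%%\n",
    x$mae, x$mse, x$accuracy_percent, x$correct_fraction_percent))
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report an `evaluation_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path) {
  out <- list(
    n = report$n,
    mae = report$mae,
    mse = report$mse,
    accuracy_percent = report$accuracy_percent,
    accuracy_definition = "D1: 100 - mean per-pair error percent",
    correct_fraction_percent = report$correct_fraction_percent,
    pairs = report$pairs
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Path to a shipped evaluation fixture table
#'
#' @param name `"table3"` or `"table4"`.
#' @return Path to the installed CSV.
#' @export
evaluation_table_path <- function(name = c("table3", "table4")) {
  name <- match.arg(name)
  system.file("extdata", paste0(name, ".csv"), package = "pulsebeat",
              mustWork = TRUE)
}
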
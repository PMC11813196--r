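#' Score a System Usability Scale response
#'
#' Standard SUS scoring: for the ten items rated 1-5, odd-numbered
#' (positively worded) items contribute `rating - 1` and even-numbered
#' (negatively worded) items contribute `5 - rating`; the summed
#' contributions are multiplied by 2.5, giving a score from 0 to 100 in
#' steps of 2.5. Higher is more usable; scores above 68 are considered
#' above average and above 80 in the top decile.
#'
#' @param ratings Integer vector of exactly 10 ratings, each in 1..5, in
#'   instrument order (no reverse-scoring auto-detection).
#' @return Numeric scalar in \[0, 100\].
#' @export
sus_score <- function(ratings) {
  ratings <- as.numeric(ratings)
  if (length(ratings) != 10L) {
    lbp_domain_error(sprintf("a SUS response has exactly 10 items (got %d)",
                             length(ratings)))
  }
  if (anyNA(ratings) || any(ratings < 1 | ratings > 5) ||
      any(ratings != round(ratings))) {
    lbp_domain_error("SUS ratings must be integers in 1..5")
  }
  odd <- ratings[c(1, 3, 5, 7, 9)] - 1
  even <- 5 - ratings[c(2, 4, 6, 8, 10)]
  (sum(odd) + sum(even)) * 2.5
}

#' Read SUS responses from CSV
#'
#' Expects a header `respondent,q1,...,q10`.
#'
#' @param path CSV file path.
#' @return Data frame with a `respondent` column and `q1`..`q10`.
#' @export
read_sus <- function(path) {
  if (!file.exists(path)) {
    lbp_format_error(sprintf("SUS file not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("respondent", paste0("q", 1:10))
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    lbp_format_error(sprintf("SUS CSV is missing column(s): %s",
                             paste(missing, collapse = ", ")))
  }
  df[, need, drop = FALSE]
}

#' Summarise SUS results across respondents
#'
#' @param responses Either a data frame as returned by [read_sus()] or a
#'   numeric vector of already-computed SUS scores.
#' @param thresholds Benchmark thresholds for the `percent_above`
#'   summaries (defaults: 68 = above average, 80 = top decile).
#' @return List with `n`, `mean`, `min`, `max`, `scores`, and
#'   `percent_above` (named numeric, percentages).
#' @export
sus_summary <- function(responses, thresholds = c(68, 80)) {
  scores <- if (is.data.frame(responses)) {
    vapply(seq_len(nrow(responses)), function(i) {
      sus_score(as.numeric(responses[i, paste0("q", 1:10)]))
    }, numeric(1L))
  } else {
    as.numeric(responses)
  }
  if (length(scores) == 0L) {
    lbp_domain_error("SUS summary requires at least one response")
  }
  pa <- vapply(thresholds, function(t) 100 * mean(scores > t), numeric(1L))
  out <- list(
    n = length(scores),
    mean = mean(scores),
    min = min(scores),
    max = max(scores),
    scores = scores,
    percent_above = stats::setNames(pa, paste0(">", thresholds))
  )
  class(out) <- "lbp_sus_summary"
  out
}

#' @export
print.lbp_sus_summary <- function(x, ...) {
  cat(sprintf("SUS summary: n=%d, mean=%.2f (range %.1f-%.1f)\n",
              x$n, x$mean, x$min, x$max))
  for (nm in names(x$percent_above)) {
    cat(sprintf("  %% of scores %s: %.2f\n", nm, x$percent_above[[nm]]))
  }
  invisible(x)
}
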
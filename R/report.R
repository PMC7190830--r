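#' Boxplot summary statistics
#'
#' Median and quartiles by linear interpolation between order statistics
#' (`stats::quantile` type 7), with Tukey whiskers at the most extreme data
#' points within 1.5 x IQR of the quartiles. This is the conventional reading
#' of "whiskers extend to the most extreme data points not considered as an
#' outlier".
#'
#' @param x numeric vector (NAs dropped).
#' @return a list with `n`, `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`
#'   and `outliers`.
#' @export
boxplot_stats <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0)
    return(list(n = 0L, median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                whisker_lo = NA_real_, whisker_hi = NA_real_,
                outliers = numeric(0)))
  q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- x[x >= lo_fence & x <= hi_fence]
  list(n = length(x), median = q[2], q1 = q[1], q3 = q[3],
       whisker_lo = min(inside), whisker_hi = max(inside),
       outliers = sort(x[x < lo_fence | x > hi_fence]))
}

#' Write a per-animal index report
#'
#' Writes the per-animal table as TSV and per-group descriptive summaries
#' (median, quartiles, Tukey whiskers; see [boxplot_stats()]) as JSON. Output
#' is deterministic given the inputs.
#'
#' @param indices data frame of per-animal values; must contain `worm_id`,
#'   may contain a `group` column, all other numeric columns are summarized.
#' @param path_prefix output files are `<path_prefix>.tsv` and
#'   `<path_prefix>.json`.
#' @return list with the paths written, invisibly.
#' @export
write_report <- function(indices, path_prefix) {
  stopifnot(is.data.frame(indices))
  tsv <- paste0(path_prefix, ".tsv")
  json <- paste0(path_prefix, ".json")
  utils::write.table(indices, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  metric_cols <- names(indices)[vapply(indices, is.numeric, logical(1))]
  groups <- if ("group" %in% names(indices)) split(indices, indices$group)
            else list(all = indices)
  summary <- lapply(groups, function(d)
    lapply(stats::setNames(metric_cols, metric_cols), function(col) {
      s <- boxplot_stats(d[[col]])
      s[c("n", "median", "q1", "q3", "whisker_lo", "whisker_hi")]
    }))
  jsonlite::write_json(summary, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(tsv = tsv, json = json))
}
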
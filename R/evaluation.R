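# Accuracy evaluation: the symmetric fold-error metric and benchmark
# summaries (mean error, max error, % of data points within 10-fold) per
# approach, dataset kind and correction mode.

#' Symmetric fold prediction error
#'
#' \deqn{error = \max(pred / ref,\ ref / pred)}
#' The fold (multiplicative) error treats over- and underestimation equally
#' and is comparable across low and high concentrations. It is always
#' \eqn{\ge 1}; a zero prediction gives `Inf`. Vectorised.
#'
#' @param predicted_c Predicted molar concentration(s), \eqn{\ge 0}.
#' @param measured_c Reference molar concentration(s), strictly positive.
#' @return Fold error(s), numeric \eqn{\ge 1} (possibly `Inf`).
#' @examples
#' fold_error(2e-10, 1e-10) # 2
#' fold_error(1e-10, 2e-10) # 2
#' @export
fold_error <- function(predicted_c, measured_c) {
  if (any(is.na(measured_c)) || any(measured_c <= 0)) {
    stop_fmt("measured (reference) concentration must be strictly positive")
  }
  if (any(predicted_c < 0, na.rm = TRUE)) {
    stop_fmt("predicted concentration cannot be negative")
  }
  out <- pmax(predicted_c / measured_c, measured_c / predicted_c)
  out[!is.na(predicted_c) & predicted_c == 0] <- Inf
  out
}

#' Benchmark summary per approach, dataset kind and correction mode
#'
#' Aggregates quantification results into the usual benchmark table: per
#' (approach x dataset kind x ISTD-correction mode) the arithmetic mean fold
#' error, the geometric mean (auxiliary), the maximum fold error, and the
#' percentage of data points with fold error below 10. One data point is one
#' compound in one run; the number of distinct compounds is reported
#' alongside. Infinite fold errors (zero predictions) are excluded from the
#' mean and max but kept in the within-10-fold denominator and counted in
#' `n_infinite`. Not-applicable rows (`NA` fold error) are ignored; groups
#' with no usable rows are omitted with a message.
#'
#' @param results Results `data.frame` from [quantify_dataset()] (columns
#'   `approach`, `istd_corrected`, `fold_error`, `compound_id`, and `run_type`
#'   or `dataset_kind`).
#' @return `data.frame` with one row per group: `approach`, `dataset_kind`,
#'   `istd_corrected`, `n_compounds`, `n_datapoints`, `n_infinite`,
#'   `mean_error`, `geom_mean_error`, `max_error`, `pct_within_10x`.
#' @export
summarize_benchmark <- function(results) {
  results$dataset_kind <- dataset_kind_of(results)
  results <- results[!is.na(results$fold_error), , drop = FALSE]
  groups <- split(results, list(results$approach, results$dataset_kind,
                                results$istd_corrected), drop = TRUE)
  rows <- lapply(groups, function(g) {
    fe <- g$fold_error
    fin <- is.finite(fe)
    if (!any(fin)) {
      message(sprintf("group %s/%s omitted: no finite fold errors",
                      g$approach[[1]], g$dataset_kind[[1]]))
      return(NULL)
    }
    data.frame(
      approach = g$approach[[1]],
      dataset_kind = g$dataset_kind[[1]],
      istd_corrected = g$istd_corrected[[1]],
      n_compounds = length(unique(g$compound_id)),
      n_datapoints = length(fe),
      n_infinite = sum(!fin),
      mean_error = mean(fe[fin]),
      geom_mean_error = 10^mean(log10(fe[fin])),
      max_error = max(fe[fin]),
      pct_within_10x = 100 * sum(fe[fin] < 10) / length(fe),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop_fmt("no usable results to summarize")
  kind_order <- c("standards", "spiked_samples", "samples")
  out <- out[order(match(out$approach, c("parent", "closest", "ie")),
                   match(out$dataset_kind, kind_order),
                   !out$istd_corrected), , drop = FALSE]
  rownames(out) <- NULL
  out
}

dataset_kind_of <- function(results) {
  if (!is.null(results$dataset_kind)) return(results$dataset_kind)
  if (is.null(results$run_type)) {
    stop_fmt("results need a run_type or dataset_kind column")
  }
  map <- c(standard = "standards", spiked_sample = "spiked_samples",
           sample = "samples")
  unname(map[results$run_type])
}

#' Fold-error histogram on a log10 scale
#'
#' Bins fold errors on log10(fold error) per approach and dataset kind, with
#' deterministic bin edges included in the output. Left-closed bins; the top
#' edge is extended to cover the largest finite error. Infinite errors are
#' counted separately in `n_infinite`.
#'
#' @param results Results `data.frame` (see [summarize_benchmark()]).
#' @param breaks Bin edges on the log10(fold error) scale; defaults to decade
#'   bins `0, 1, 2, ...` covering the data.
#' @return `data.frame` with `approach`, `dataset_kind`, `log10_lo`,
#'   `log10_hi`, `count`, `n_infinite` (repeated per group).
#' @export
error_histogram <- function(results, breaks = NULL) {
  results$dataset_kind <- dataset_kind_of(results)
  results <- results[!is.na(results$fold_error), , drop = FALSE]
  fe <- results$fold_error
  if (is.null(breaks)) {
    top <- if (any(is.finite(fe))) max(log10(fe[is.finite(fe)])) else 0
    breaks <- seq(0, max(1, ceiling(top + 1e-12)))
  }
  breaks <- sort(unique(breaks))
  groups <- split(results, list(results$approach, results$dataset_kind),
                  drop = TRUE)
  rows <- lapply(groups, function(g) {
    lfe <- log10(g$fold_error[is.finite(g$fold_error)])
    idx <- findInterval(lfe, breaks, rightmost.closed = TRUE)
    counts <- tabulate(idx[idx >= 1 & idx < length(breaks)],
                       nbins = length(breaks) - 1)
    data.frame(
      approach = g$approach[[1]],
      dataset_kind = g$dataset_kind[[1]],
      log10_lo = breaks[-length(breaks)],
      log10_hi = breaks[-1],
      count = counts,
      n_infinite = sum(!is.finite(g$fold_error)),
      stringsAsFactors = FALSE
    )
  })
  if (length(rows) == 0) {
    return(data.frame(approach = character(), dataset_kind = character(),
                      log10_lo = numeric(), log10_hi = numeric(),
                      count = integer(), n_infinite = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
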
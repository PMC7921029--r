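# Response-factor calibration: per-compound zero-intercept response factors
# averaged over the linear range of the standard series, and random selection
# of the calibration-compound set used by the closest-eluting and
# ionization-efficiency approaches.

#' Linear-range filter for a calibration series
#'
#' Standards below the quantification limit or above the upper limit of
#' linearity bias a zero-intercept response factor. The filter trims such
#' points from the *endpoints* of the concentration-sorted series only:
#' repeatedly compute the per-level response factor `signal / conc` and the
#' median over the current set, and drop the endpoint whose response factor
#' deviates most from the median if its relative deviation exceeds
#' `tol_fraction`; stop when both endpoints are within tolerance or only
#' `min_levels` levels remain. Interior levels are never dropped. Series with
#' at most `min_levels` levels are returned untrimmed.
#'
#' @param series `data.frame` with columns `nominal_conc_M` (> 0) and
#'   `corrected_signal`; an optional `run_id` column is carried through.
#' @param tol_fraction Maximum tolerated relative deviation of an endpoint's
#'   response factor from the median (default 0.30).
#' @param min_levels Minimum number of levels retained (default 3).
#' @return List with `retained` (subset of `series`, sorted by concentration)
#'   and `exclusions` (`data.frame` of dropped levels with the triggering
#'   rule).
#' @export
linear_range_filter <- function(series, tol_fraction = 0.30, min_levels = 3) {
  if (nrow(series) == 0) stop_fmt("no linear range: empty calibration series")
  if (any(series$nominal_conc_M <= 0)) {
    stop_fmt("calibration concentrations must be strictly positive")
  }
  series <- series[order(series$nominal_conc_M), , drop = FALSE]
  rf_level <- series$corrected_signal / series$nominal_conc_M
  keep <- seq_len(nrow(series))
  dropped <- integer()
  side <- character()
  while (length(keep) > min_levels) {
    rf <- rf_level[keep]
    med <- stats::median(rf)
    if (!is.finite(med) || med <= 0) {
      stop_fmt("no linear range: median response factor is not positive")
    }
    dev_lo <- abs(rf[[1]] - med) / med
    dev_hi <- abs(rf[[length(rf)]] - med) / med
    if (max(dev_lo, dev_hi) <= tol_fraction) break
    if (dev_lo >= dev_hi) {
      dropped <- c(dropped, keep[[1]])
      side <- c(side, "below linear range")
      keep <- keep[-1]
    } else {
      dropped <- c(dropped, keep[[length(keep)]])
      side <- c(side, "above linear range")
      keep <- keep[-length(keep)]
    }
  }
  exclusions <- data.frame(
    run_id = if (!is.null(series$run_id)) series$run_id[dropped] else
      rep(NA_character_, length(dropped)),
    nominal_conc_M = series$nominal_conc_M[dropped],
    rf_level = rf_level[dropped],
    reason = side,
    stringsAsFactors = FALSE
  )
  list(retained = series[keep, , drop = FALSE], exclusions = exclusions)
}

#' Response factor of one compound from its standard series
#'
#' The response factor (RF, in 1/M) is the proportionality constant of the
#' zero-intercept calibration `signal = RF * c`. Per retained level,
#' `RF_level = corrected_signal / nominal_conc_M`; the compound's RF is the
#' arithmetic mean of the retained per-level values (the calibration
#' intercept is assumed negligible). Levels outside the linear range are
#' excluded by [linear_range_filter()] first.
#'
#' @inheritParams linear_range_filter
#' @return List with `rf` (mean response factor, 1/M), `n_levels_used`, and
#'   `levels_excluded` (the filter's exclusion table).
#' @examples
#' s <- data.frame(nominal_conc_M = 1e-10, corrected_signal = 200)
#' compute_rf(s)$rf # 2e12
#' @export
compute_rf <- function(series, tol_fraction = 0.30, min_levels = 3) {
  flt <- linear_range_filter(series, tol_fraction = tol_fraction,
                             min_levels = min_levels)
  ret <- flt$retained
  rf <- mean(ret$corrected_signal / ret$nominal_conc_M)
  if (!is.finite(rf) || rf <= 0) {
    stop_fmt("no linear range: retained levels give a non-positive response factor")
  }
  list(rf = rf, n_levels_used = nrow(ret), levels_excluded = flt$exclusions)
}

#' Response factors for every compound in a measurement table
#'
#' Builds each compound's calibration series from the `standard` runs of a
#' measurement table (after signal correction via [correct_signals()]) and
#' computes its response factor with [compute_rf()]. Compounds whose series
#' has no linear range are dropped with a warning.
#'
#' @param measurements Measurement `data.frame`.
#' @param compounds Compound `data.frame`.
#' @param istd,isotope Signal-correction switches, see [correct_signals()].
#' @inheritParams linear_range_filter
#' @return `data.frame` with columns `compound_id`, `rf`, `n_levels_used`,
#'   `levels_excluded` (semicolon-separated `conc:reason` entries).
#' @export
compute_rf_table <- function(measurements, compounds, istd = TRUE,
                             isotope = TRUE, tol_fraction = 0.30,
                             min_levels = 3) {
  std <- measurements[measurements$run_type == "standard", , drop = FALSE]
  if (nrow(std) == 0) stop_fmt("measurement table contains no standard runs")
  corr <- correct_signals(measurements, compounds, istd = istd,
                          isotope = isotope)
  corr <- corr[corr$run_type == "standard", , drop = FALSE]
  out <- lapply(split(corr, corr$compound_id), function(g) {
    series <- data.frame(run_id = g$run_id,
                         nominal_conc_M = g$nominal_conc_M,
                         corrected_signal = g$corrected_area,
                         stringsAsFactors = FALSE)
    res <- tryCatch(compute_rf(series, tol_fraction, min_levels),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    excl <- res$levels_excluded
    data.frame(
      compound_id = g$compound_id[[1]],
      rf = res$rf,
      n_levels_used = res$n_levels_used,
      levels_excluded = paste(sprintf("%.3g:%s", excl$nominal_conc_M,
                                      excl$reason), collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  failed <- names(out)[vapply(out, is.null, logical(1))]
  if (length(failed) > 0) {
    warning(sprintf("no linear range for %d compound(s): %s",
                    length(failed), paste(failed, collapse = ", ")),
            call. = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

#' Select the calibration-compound set by repeated random sampling
#'
#' Draws `n_repeats` random subsets of `k` compounds (without replacement)
#' from the eligible pool and keeps the subset with the widest joint coverage
#' of retention time and response factor. Coverage is scored as
#' `(RT span of subset / RT span of pool) + (log10-RF span of subset /
#' log10-RF span of pool)`, bounded in (0, 2] and equal to 2 only when the
#' subset attains both full spans. The draw is deterministic for a given
#' seed; candidates are put in canonical `compound_id` order first so the
#' result does not depend on input row order.
#'
#' @param candidates `data.frame` with columns `compound_id`, `rt_min`, `rf`.
#' @param k Subset size (default 20).
#' @param n_repeats Number of random draws (default 3).
#' @param seed Integer seed for the subset draws.
#' @return List with `compound_ids` (the selected set, in canonical order),
#'   `score`, `k`, `n_repeats`, `seed`.
#' @export
select_calibrants <- function(candidates, k = 20, n_repeats = 3, seed = 1) {
  if (k > nrow(candidates)) {
    stop_fmt("cannot sample %d calibrants from %d eligible compounds",
             k, nrow(candidates))
  }
  candidates <- candidates[order(candidates$compound_id), , drop = FALSE]
  if (any(candidates$rf <= 0)) stop_fmt("calibrant candidates must have rf > 0")
  span <- function(x) diff(range(x))
  rt_all <- span(candidates$rt_min)
  rf_all <- span(log10(candidates$rf))
  score_subset <- function(idx) {
    s_rt <- if (rt_all > 0) span(candidates$rt_min[idx]) / rt_all else 1
    s_rf <- if (rf_all > 0) span(log10(candidates$rf[idx])) / rf_all else 1
    s_rt + s_rf
  }
  draws <- with_seed(seed, {
    lapply(seq_len(n_repeats), function(i) sample(nrow(candidates), k))
  })
  scores <- vapply(draws, score_subset, numeric(1))
  best <- draws[[which.max(scores)]]
  list(compound_ids = sort(candidates$compound_id[best]),
       score = max(scores), k = k, n_repeats = n_repeats, seed = seed)
}
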
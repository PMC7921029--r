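# The three standard-free quantification approaches:
#   I   parent-compound surrogate (TPs only): c = signal / RF_parent
#   II  closest-eluting calibration compound: c = signal / RF_closest
#   III ionization-efficiency calibration transfer:
#         log10 RF = slope * logIE_pred + intercept, c = signal / RF_pred

#' Approach I: quantify a transformation product with its parent's RF
#'
#' Assumes the TP responds like its parent compound (justified when the
#' transformation preserves the hydrophobic and basic moieties that drive
#' electrospray response). Only applicable to TPs with a measurable parent.
#'
#' @param tp_corrected_signal Corrected signal of the TP (vectorised).
#' @param parent_rf Parent compound's response factor, 1/M.
#' @return Predicted molar concentration(s).
#' @export
quantify_parent <- function(tp_corrected_signal, parent_rf) {
  if (any(parent_rf <= 0)) stop_fmt("parent response factor must be positive")
  tp_corrected_signal / parent_rf
}

#' Approach II: find the closest-eluting calibration compound
#'
#' Returns the calibrant whose retention time is nearest the analyte's
#' (elution proximity measured on retention time). Exact ties are broken by
#' the earlier-eluting calibrant, then lexicographic id, so the choice is
#' deterministic.
#'
#' @param analyte_rt Analyte retention time(s), minutes (vectorised).
#' @param calibrants `data.frame` with columns `compound_id`, `rt_min`.
#' @return Character vector of calibrant ids, one per analyte.
#' @export
closest_calibrant <- function(analyte_rt, calibrants) {
  if (nrow(calibrants) == 0) stop_fmt("calibrant list is empty")
  vapply(analyte_rt, function(rt) {
    d <- abs(calibrants$rt_min - rt)
    ord <- order(d, calibrants$rt_min, calibrants$compound_id)
    calibrants$compound_id[ord[[1]]]
  }, character(1))
}

#' Approach II: quantify with the closest calibrant's RF
#'
#' @param corrected_signal Corrected analyte signal (vectorised).
#' @param calibrant_rf Response factor of the closest-eluting calibration
#'   compound, 1/M.
#' @return Predicted molar concentration(s).
#' @export
quantify_closest <- function(corrected_signal, calibrant_rf) {
  if (any(calibrant_rf <= 0)) stop_fmt("calibrant response factor must be positive")
  corrected_signal / calibrant_rf
}

#' Approach III: fit the ionization-efficiency to response-factor transfer
#'
#' Predicted ionization efficiencies are universal (instrument-independent)
#' values; converting them to response factors for a given LC/ESI/HRMS setup
#' requires an instrument-specific anchor. The transfer is an unweighted
#' ordinary least-squares line in double-log space over the calibration
#' compounds:
#' \deqn{\log_{10} RF = slope \cdot \log_{10} IE_{pred} + intercept}
#' Base-10 logs give even weight across the several orders of magnitude that
#' both quantities span.
#'
#' @param log_ie_pred Predicted log10 ionization efficiencies of the
#'   calibration compounds.
#' @param rf Their measured response factors, 1/M (all > 0).
#' @return Object of class `ie_transfer`: list with `slope`, `intercept`
#'   (log10(1/M)), `n_calibrants`, `residual_sd`, and the standard errors
#'   `se_slope`, `se_intercept`.
#' @export
fit_ie_transfer <- function(log_ie_pred, rf) {
  if (length(log_ie_pred) != length(rf)) {
    stop_fmt("log_ie_pred and rf must have equal length")
  }
  ok <- !is.na(log_ie_pred) & !is.na(rf)
  log_ie_pred <- log_ie_pred[ok]
  rf <- rf[ok]
  if (length(rf) < 2) stop_fmt("need at least 2 calibrants to fit the transfer")
  if (any(rf <= 0)) stop_fmt("response factors must be positive")
  if (length(unique(log_ie_pred)) < 2) {
    stop_fmt("degenerate fit: all calibrants share the same predicted logIE")
  }
  fit <- stats::lm(log10(rf) ~ log_ie_pred)
  cf <- stats::coef(fit)
  n <- length(rf)
  rss <- sum(stats::residuals(fit)^2)
  residual_sd <- if (n > 2) sqrt(rss / (n - 2)) else 0
  sxx <- sum((log_ie_pred - mean(log_ie_pred))^2)
  se_slope <- residual_sd / sqrt(sxx)
  se_intercept <- residual_sd * sqrt(1 / n + mean(log_ie_pred)^2 / sxx)
  structure(list(slope = unname(cf[[2]]), intercept = unname(cf[[1]]),
                 n_calibrants = n, residual_sd = residual_sd,
                 se_intercept = se_intercept, se_slope = se_slope),
            class = "ie_transfer")
}

#' @export
print.ie_transfer <- function(x, ...) {
  cat(sprintf("IE->RF calibration transfer: log10(RF) = %.4f * logIE + %.4f\n",
              x$slope, x$intercept))
  cat(sprintf("  %d calibrants, residual sd %.4f log10 units\n",
              x$n_calibrants, x$residual_sd))
  invisible(x)
}

#' Approach III: predict a response factor from ionization efficiency
#'
#' @param log_ie_pred Predicted log10 ionization efficiency (vectorised).
#' @param model An `ie_transfer` model from [fit_ie_transfer()].
#' @return Predicted response factor(s), 1/M.
#' @export
predict_rf_from_ie <- function(log_ie_pred, model) {
  10^(model$slope * log_ie_pred + model$intercept)
}

#' Approach III: quantify with the IE-predicted RF
#'
#' @param corrected_signal Corrected analyte signal (vectorised).
#' @param predicted_rf IE-predicted response factor, 1/M.
#' @return Predicted molar concentration(s).
#' @export
quantify_ie <- function(corrected_signal, predicted_rf) {
  if (any(predicted_rf <= 0)) stop_fmt("predicted response factor must be positive")
  corrected_signal / predicted_rf
}

#' Quantify a full measurement table with the three approaches
#'
#' Runs the requested standard-free approaches over every detected peak
#' (rows with `peak_area > 0`) in a measurement table and evaluates each
#' prediction against its reference concentration: the nominal concentration
#' for standards and spiked samples, or the supplied `references` for real
#' samples. Approach `parent` is emitted only for TPs; a TP whose parent has
#' no response factor yields an explicit not-applicable row (`NA` prediction)
#' rather than a silent fallback to another approach.
#'
#' @param measurements Measurement `data.frame`.
#' @param compounds Compound `data.frame`.
#' @param rf_table Response factors from [compute_rf_table()] computed with
#'   the same `istd`/`isotope` settings.
#' @param calibrants Character vector of calibration-compound ids (must
#'   appear in `rf_table` and `compounds`).
#' @param transfer_model `ie_transfer` model; if `NULL` it is fitted from the
#'   calibrants' `log_ie_pred` and `rf`.
#' @param istd,isotope Signal-correction switches, see [correct_signals()].
#' @param references Optional `data.frame` `run_id, compound_id,
#'   reference_conc_M` supplying reference concentrations for `sample` runs.
#' @param approaches Subset of `c("parent", "closest", "ie")`.
#' @return Results `data.frame` with columns `compound_id`, `sample_id`,
#'   `approach`, `istd_corrected`, `predicted_conc_M`, `reference_conc_M`,
#'   `fold_error`, plus `run_type` for downstream grouping.
#' @export
quantify_dataset <- function(measurements, compounds, rf_table, calibrants,
                             transfer_model = NULL, istd = TRUE,
                             isotope = TRUE, references = NULL,
                             approaches = c("parent", "closest", "ie")) {
  check_choice(approaches, c("parent", "closest", "ie"), "approach")
  corr <- correct_signals(measurements, compounds, istd = istd,
                          isotope = isotope)
  corr <- corr[corr$peak_area > 0, , drop = FALSE]

  ref <- corr$nominal_conc_M
  if (!is.null(references)) {
    key <- paste(corr$run_id, corr$compound_id, sep = "\r")
    rkey <- paste(references$run_id, references$compound_id, sep = "\r")
    hit <- match(key, rkey)
    take <- corr$run_type == "sample" & !is.na(hit)
    ref[take] <- references$reference_conc_M[hit[take]]
  }
  usable <- !is.na(ref) & ref > 0
  corr <- corr[usable, , drop = FALSE]
  ref <- ref[usable]

  ci <- match(corr$compound_id, compounds$compound_id)
  rt <- compounds$rt_min[ci]
  role <- compounds$role[ci]
  parent_id <- compounds$parent_id[ci]
  log_ie <- compounds$log_ie_pred[ci]
  rf_of <- function(ids) rf_table$rf[match(ids, rf_table$compound_id)]

  pieces <- list()
  base_cols <- function(pred) {
    data.frame(compound_id = corr$compound_id, sample_id = corr$run_id,
               istd_corrected = istd, predicted_conc_M = pred,
               reference_conc_M = ref, run_type = corr$run_type,
               stringsAsFactors = FALSE)
  }

  if ("parent" %in% approaches) {
    is_tp <- role == "tp" & !is.na(parent_id)
    prf <- rf_of(parent_id)
    pred <- rep(NA_real_, nrow(corr))
    ok <- is_tp & !is.na(prf) & prf > 0
    pred[ok] <- quantify_parent(corr$corrected_area[ok], prf[ok])
    p <- base_cols(pred)
    p$approach <- "parent"
    pieces$parent <- p[is_tp, , drop = FALSE]
  }

  if ("closest" %in% approaches) {
    cal <- data.frame(compound_id = calibrants,
                      rt_min = compounds$rt_min[match(calibrants,
                                                      compounds$compound_id)],
                      stringsAsFactors = FALSE)
    cal <- cal[cal$compound_id %in% rf_table$compound_id, , drop = FALSE]
    if (nrow(cal) == 0) stop_fmt("no calibrant has a response factor")
    nearest <- closest_calibrant(rt, cal)
    pred <- quantify_closest(corr$corrected_area, rf_of(nearest))
    p <- base_cols(pred)
    p$approach <- "closest"
    pieces$closest <- p
  }

  if ("ie" %in% approaches) {
    if (is.null(transfer_model)) {
      cal_ie <- compounds$log_ie_pred[match(calibrants, compounds$compound_id)]
      transfer_model <- fit_ie_transfer(cal_ie, rf_of(calibrants))
    }
    has_ie <- !is.na(log_ie)
    pred <- rep(NA_real_, nrow(corr))
    pred[has_ie] <- quantify_ie(corr$corrected_area[has_ie],
                                predict_rf_from_ie(log_ie[has_ie],
                                                   transfer_model))
    p <- base_cols(pred)
    p$approach <- "ie"
    pieces$ie <- p[has_ie, , drop = FALSE]
  }

  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out$fold_error <- rep(NA_real_, nrow(out))
  known <- !is.na(out$predicted_conc_M)
  out$fold_error[known] <- fold_error(out$predicted_conc_M[known],
                                      out$reference_conc_M[known])
  out[, c(result_columns, "run_type")]
}
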
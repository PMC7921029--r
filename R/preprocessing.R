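# Signal corrections and compound/ISTD eligibility rules applied before any
# quantification: internal-standard normalisation, isotopologue correction,
# the recovery/adduct compound filter and the coelution-based ISTD assignment.

#' Internal-standard signal correction
#'
#' Normalises an analyte peak area by the response of its assigned internal
#' standard (ISTD) in the same run, anchored to the mean ISTD response across
#' all calibration standards:
#' \deqn{Signal^{corr} = Signal \cdot
#'   \frac{\overline{Signal}^{ISTD}_{standards}}{Signal^{ISTD}_{run}}}
#' The correction cancels run-to-run drift and that part of matrix-induced
#' ionization suppression shared between analyte and ISTD. All arguments are
#' vectorised and recycled.
#'
#' @param analyte_area Analyte peak area(s), arbitrary area units.
#' @param istd_area_in_run ISTD peak area in the same run; must be positive.
#' @param mean_istd_area_in_standards Mean area of the same ISTD across all
#'   measured calibration standards; must be positive.
#' @return Corrected analyte area(s).
#' @examples
#' istd_correct(1000, 50, 100) # ISTD at half its usual response -> area doubled
#' @export
istd_correct <- function(analyte_area, istd_area_in_run,
                         mean_istd_area_in_standards) {
  if (any(analyte_area < 0)) stop_fmt("analyte_area must be non-negative")
  if (any(istd_area_in_run <= 0)) {
    stop_fmt("ISTD area is zero or negative in at least one run; the ISTD is unusable there")
  }
  if (any(mean_istd_area_in_standards <= 0)) {
    stop_fmt("mean ISTD area in standards must be positive")
  }
  analyte_area * mean_istd_area_in_standards / istd_area_in_run
}

#' Apply signal corrections to a measurement table
#'
#' Adds a `corrected_area` column to a measurement table: the peak area,
#' optionally ISTD-corrected via [istd_correct()] (the per-compound mean ISTD
#' area is computed from the table's own `standard` runs) and optionally
#' multiplied by the compound's isotopologue correction factor
#' ([isotope_correction_factor()]).
#'
#' @param measurements Measurement `data.frame` (see
#'   [read_measurement_table()]).
#' @param compounds Compound `data.frame` (needed for formulas when
#'   `isotope = TRUE`).
#' @param istd Apply the ISTD correction?
#' @param isotope Apply the isotopologue correction?
#' @param abundances Isotope abundance table.
#' @return `measurements` with an added numeric `corrected_area` column.
#' @export
correct_signals <- function(measurements, compounds, istd = TRUE,
                            isotope = TRUE, abundances = isotope_abundances) {
  area <- measurements$peak_area
  if (istd) {
    std <- measurements$run_type == "standard"
    if (!any(std)) {
      stop_fmt("ISTD correction requires standard runs to anchor the mean ISTD area")
    }
    mean_istd <- tapply(measurements$istd_area[std],
                        measurements$compound_id[std], mean)
    m <- mean_istd[measurements$compound_id]
    no_anchor <- unique(measurements$compound_id[is.na(m)])
    if (length(no_anchor) > 0) {
      stop_fmt("no standard runs found to anchor the ISTD correction for compound '%s'",
               no_anchor[[1]])
    }
    area <- istd_correct(area, measurements$istd_area, as.numeric(m))
  }
  if (isotope) {
    formulas <- compounds$formula[match(measurements$compound_id,
                                        compounds$compound_id)]
    if (anyNA(formulas)) {
      bad <- measurements$compound_id[is.na(formulas)][[1]]
      stop_fmt("compound '%s' in measurements is missing from the compound table", bad)
    }
    icf <- vapply(unique(formulas), isotope_correction_factor,
                  numeric(1), abundances = abundances)
    area <- area * icf[formulas]
  }
  measurements$corrected_area <- as.numeric(area)
  measurements
}

#' Filter compounds by recovery quality and adduct quantification
#'
#' Removes compounds that cannot be reliably quantified: those quantified via
#' sodium/ammonium adducts (ionization efficiency cannot be predicted for
#' adducts) and those with relative recovery < 50% or > 150% or a relative
#' standard deviation of relative recoveries across spiked samples > 50%.
#' Boundary values (exactly 50%, 150%, 50%) are retained. Compounds without a
#' recovery record are retained but flagged as unchecked.
#'
#' @param compounds Compound `data.frame`.
#' @param recoveries `data.frame` with columns `compound_id`,
#'   `relative_recovery_pct`, `rsd_pct` (at most one row per compound).
#' @param adduct_compounds Character vector of compound ids quantified via
#'   adducts.
#' @return List with `retained` (filtered compound `data.frame`), `removed`
#'   (`data.frame` of `compound_id`, `reason`), and `unchecked` (ids retained
#'   without recovery evidence).
#' @export
filter_compounds <- function(compounds, recoveries = NULL,
                             adduct_compounds = character()) {
  if (is.null(recoveries)) {
    recoveries <- data.frame(compound_id = character(),
                             relative_recovery_pct = numeric(),
                             rsd_pct = numeric())
  }
  if (anyDuplicated(recoveries$compound_id)) {
    stop_fmt("more than one recovery record for compound '%s'",
             recoveries$compound_id[duplicated(recoveries$compound_id)][[1]])
  }
  idx <- match(compounds$compound_id, recoveries$compound_id)
  rr <- recoveries$relative_recovery_pct[idx]
  rsd <- recoveries$rsd_pct[idx]

  reason <- rep(NA_character_, nrow(compounds))
  reason[!is.na(rsd) & rsd > 50] <- "recovery RSD>50%"
  reason[!is.na(rr) & rr > 150] <- "recovery>150%"
  reason[!is.na(rr) & rr < 50] <- "recovery<50%"
  reason[compounds$compound_id %in% adduct_compounds] <- "adduct-quantified"

  unchecked <- compounds$compound_id[is.na(idx) & is.na(reason)]
  if (length(unchecked) > 0) {
    warning(sprintf("%d compound(s) retained without recovery evidence",
                    length(unchecked)), call. = FALSE)
  }
  removed <- data.frame(compound_id = compounds$compound_id[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  list(retained = compounds[is.na(reason), , drop = FALSE],
       removed = removed,
       unchecked = unchecked)
}

#' Assign an internal standard to an analyte
#'
#' Mirrors common practice in multi-residue water analysis: a structurally
#' identical (isotope-labelled analogue) ISTD is always preferred; otherwise
#' the ISTD coeluting with the analyte within \eqn{\pm}`rt_window` minutes
#' with the best relative recovery is chosen. "Best" is scored as
#' `|RR - 100| + max(0, RSD - 10)` (smaller is better; an ideal ISTD recovers
#' 100% with low spread), with ties broken by smaller retention-time
#' difference, then lexicographic `istd_id`. If no ISTD coelutes, an explicit
#' no-assignment result is returned so the caller can decide between
#' uncorrected quantification and exclusion.
#'
#' @param analyte_rt Analyte retention time, minutes.
#' @param istds `data.frame` with columns `istd_id`, `rt_min`.
#' @param recoveries `data.frame` with columns `istd_id`,
#'   `relative_recovery_pct`, `rsd_pct` observed for each candidate ISTD;
#'   candidates without a record are only chosen as a last resort.
#' @param structural_istd_id Id of a structurally identical ISTD, if one
#'   exists; returned immediately regardless of retention time.
#' @param rt_window Coelution window in minutes (default 2).
#' @return List with `istd_id` (`NA` if none assignable) and `reason` (one of
#'   `"structural"`, `"coeluting"`, `"none within rt window"`).
#' @export
assign_istd <- function(analyte_rt, istds, recoveries = NULL,
                        structural_istd_id = NULL, rt_window = 2) {
  if (nrow(istds) == 0) stop_fmt("ISTD catalogue is empty")
  if (!is.null(structural_istd_id) && !is.na(structural_istd_id)) {
    if (!structural_istd_id %in% istds$istd_id) {
      stop_fmt("structural ISTD '%s' not in the catalogue", structural_istd_id)
    }
    return(list(istd_id = structural_istd_id, reason = "structural"))
  }
  drt <- abs(istds$rt_min - analyte_rt)
  cand <- istds[drt <= rt_window, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(list(istd_id = NA_character_, reason = "none within rt window"))
  }
  drt <- drt[abs(istds$rt_min - analyte_rt) <= rt_window]
  score <- rep(Inf, nrow(cand))
  if (!is.null(recoveries)) {
    idx <- match(cand$istd_id, recoveries$istd_id)
    rr <- recoveries$relative_recovery_pct[idx]
    rsd <- recoveries$rsd_pct[idx]
    ok <- !is.na(rr) & !is.na(rsd)
    score[ok] <- abs(rr[ok] - 100) + pmax(0, rsd[ok] - 10)
  }
  ord <- order(score, drt, cand$istd_id)
  list(istd_id = cand$istd_id[ord[[1]]], reason = "coeluting")
}
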
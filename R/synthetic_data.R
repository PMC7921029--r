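# Seeded synthetic-data generator emulating the structure of a groundwater
# non-target screening campaign: a compound pool with retention times,
# response factors tied to ionization efficiency through a log-linear law,
# parent/TP pairs, a multi-level calibration series with LOQ censoring and
# saturation, and matrix-affected sample and spiked-sample runs. A hidden
# truth table (true RF, true logIE, true concentrations) makes every pipeline
# stage verifiable.

# CHNOS(Cl,F) formula templates in typical pesticide/pharmaceutical ranges;
# they only exist so the isotopologue correction has realistic work to do.
formula_templates <- c(
  "C8H14ClN5", "C10H13N5O", "C9H13N3O", "C14H18N4O3", "C10H12N2O",
  "C12H14Cl2N2O", "C16H14F3N3O2S", "C7H10N2O2S", "C11H15NO2", "C13H18ClNO",
  "C15H22N2O2", "C9H11Cl2N3O2", "C10H14N2O4S", "C17H19N3O3", "C8H9NO2",
  "C12H17N3O2S", "C14H12F2N2O", "C11H13ClN2O2", "C16H21N3O2", "C9H10ClN3O"
)

#' Configuration of the synthetic groundwater study
#'
#' Bundles every knob of the generator. The defaults emulate the structure of
#' a Swiss groundwater monitoring campaign: 341 compounds eluting between 3.2
#' and 22.1 min with response factors between 1.5e18 and 5.3e20 1/M, 60
#' parent/TP pairs with TP response mostly below the parent's, a 22-level
#' calibration series spanning 0.1-1000 ng/L (about 5e-13 to 1e-8 M), 31
#' samples containing 4-44 compounds each, 6 spiked samples at 10 or
#' 100 ng/L, and internal standards spiked at 100 ng/L.
#'
#' Response factors follow the log-linear ionization-efficiency law
#' `log10(RF) = true_slope * logIE + true_intercept + N(0, sigma_ie)`
#' (clamped to `rf_range`); the generator plays the role of the external
#' ionization-efficiency predictor, so the visible `log_ie_pred` column
#' equals the true logIE.
#'
#' @param n_compounds Number of analytes.
#' @param n_tp_pairs Number of parent/TP pairs carved out of the pool.
#' @param n_samples Number of real-sample runs.
#' @param n_spiked_samples Number of spiked-sample runs.
#' @param n_istds Size of the isotope-labelled internal-standard pool.
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   tables.
#' @param rt_range_min Retention-time range, minutes.
#' @param rf_range Response-factor range, 1/M.
#' @param conc_range_M Molar concentration range of sample detections.
#' @param calib_levels_ngL Calibration levels in ng/L (geometric series).
#' @param istd_spike_ngL ISTD spike level, ng/L.
#' @param spike_levels_ngL Spike levels cycled over the spiked samples, ng/L.
#' @param true_slope,true_intercept Parameters of the IE-RF law (artifact
#'   constants chosen so RF spans `rf_range` while logIE spans about 2.5
#'   decades).
#' @param sigma_ie SD of the log10 RF residuals around the IE law.
#' @param tp_logratio_mean,tp_logratio_sd Normal parameters of
#'   log10(RF_TP / RF_parent); a negative mean makes most TPs respond below
#'   their parent.
#' @param matrix_bias Log10 of the median matrix factor in samples (<= 0:
#'   net ionization suppression).
#' @param matrix_sigma SD (log10) of the compound-by-sample idiosyncratic
#'   matrix factor (not cancelled by ISTD correction).
#' @param matrix_sigma_run SD (log10) of the per-run shared matrix factor
#'   (cancelled by ISTD correction).
#' @param run_drift_sigma SD (log10) of per-standard-run instrument drift.
#' @param level_noise Relative (multiplicative) noise of peak areas.
#' @param loq_ngL Levels below this emit zero area (LOQ censoring).
#' @param sat_knee_ngL Levels above this respond sublinearly.
#' @param sat_fraction Fraction of the nominal response retained above the
#'   saturation knee.
#' @param compounds_per_sample_range Range of detected compounds per sample.
#' @return Object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_compounds = 341,
                             n_tp_pairs = 60,
                             n_samples = 31,
                             n_spiked_samples = 6,
                             n_istds = 224,
                             seed = 1,
                             rt_range_min = c(3.2, 22.1),
                             rf_range = c(1.5e18, 5.3e20),
                             conc_range_M = c(5e-13, 1e-8),
                             calib_levels_ngL = 10^seq(log10(0.1), log10(1000),
                                                       length.out = 22),
                             istd_spike_ngL = 100,
                             spike_levels_ngL = c(10, 100),
                             true_slope = 1,
                             true_intercept = 16.7,
                             sigma_ie = 0.15,
                             tp_logratio_mean = -0.3,
                             tp_logratio_sd = 0.5,
                             matrix_bias = -0.1,
                             matrix_sigma = 0.1,
                             matrix_sigma_run = 0.1,
                             run_drift_sigma = 0.05,
                             level_noise = 0.05,
                             loq_ngL = 0.2,
                             sat_knee_ngL = 600,
                             sat_fraction = 0.3,
                             compounds_per_sample_range = c(4, 44)) {
  cfg <- as.list(environment())
  # small pools cap how many compounds a sample can contain
  cfg$compounds_per_sample_range[[2]] <-
    min(cfg$compounds_per_sample_range[[2]], cfg$n_compounds)
  cfg$compounds_per_sample_range[[1]] <-
    min(cfg$compounds_per_sample_range[[1]], cfg$compounds_per_sample_range[[2]])
  stopifnot(
    cfg$n_compounds >= 2, cfg$n_compounds >= 2 * cfg$n_tp_pairs,
    cfg$n_samples >= 0, cfg$n_istds >= 1,
    diff(cfg$rt_range_min) >= 0, diff(cfg$rf_range) > 0,
    diff(cfg$conc_range_M) >= 0, all(cfg$calib_levels_ngL > 0),
    cfg$true_slope != 0,
    cfg$sigma_ie >= 0, cfg$tp_logratio_sd >= 0,
    cfg$matrix_sigma >= 0, cfg$matrix_sigma_run >= 0,
    cfg$run_drift_sigma >= 0, cfg$level_noise >= 0,
    cfg$loq_ngL >= 0, cfg$sat_knee_ngL > 0,
    cfg$sat_fraction > 0, cfg$sat_fraction <= 1,
    diff(cfg$compounds_per_sample_range) >= 0,
    cfg$compounds_per_sample_range[[1]] >= 1,
    cfg$compounds_per_sample_range[[2]] <= cfg$n_compounds
  )
  structure(cfg, class = "synthetic_config")
}

#' Noise-free variant of a synthetic configuration
#'
#' Convenience wrapper zeroing every stochastic disturbance (IE-law
#' residuals, matrix effects, drift, area noise, LOQ censoring, saturation).
#' In this limit the pipeline must recover concentrations exactly, which the
#' test suite exploits.
#'
#' @param ... Overrides passed on to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
noiseless_config <- function(...) {
  defaults <- list(sigma_ie = 0, matrix_bias = 0, matrix_sigma = 0,
                   matrix_sigma_run = 0, run_drift_sigma = 0,
                   level_noise = 0, loq_ngL = 0, sat_knee_ngL = Inf)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

#' Generate the compound pool and its hidden truth table
#'
#' Retention times are uniform over `rt_range_min`. True logIE values are
#' uniform over the span that maps onto `rf_range` through the IE-RF law;
#' true response factors are `10^(true_slope * logIE + true_intercept +
#' N(0, sigma_ie))`, clamped to `rf_range`. Each compound is assigned the
#' internal standard eluting nearest to it from a generated ISTD pool.
#'
#' @param config A [synthetic_config()].
#' @return List with `compounds` (visible table), `truth` (hidden per-compound
#'   `true_rf`, `true_log_ie`, `tp_rf_ratio`), and `istds` (ISTD pool with
#'   retention time, response factor, and molar spike concentration).
#' @export
generate_compounds <- function(config) {
  with_seed(config$seed + 101L, {
    n <- config$n_compounds
    ids <- sprintf("cmp_%04d", seq_len(n))
    rt <- stats::runif(n, config$rt_range_min[[1]], config$rt_range_min[[2]])
    lrf_lo <- log10(config$rf_range[[1]])
    lrf_hi <- log10(config$rf_range[[2]])
    ie_bounds <- sort((c(lrf_lo, lrf_hi) - config$true_intercept) /
                        config$true_slope)
    log_ie <- stats::runif(n, ie_bounds[[1]], ie_bounds[[2]])
    log_rf <- config$true_slope * log_ie + config$true_intercept +
      stats::rnorm(n, 0, config$sigma_ie)
    log_rf <- pmin(pmax(log_rf, lrf_lo), lrf_hi)
    formula <- sample(formula_templates, n, replace = TRUE)

    m <- config$n_istds
    istd_ids <- sprintf("istd_%03d", seq_len(m))
    istd_rt <- stats::runif(m, config$rt_range_min[[1]], config$rt_range_min[[2]])
    istd_rf <- 10^stats::runif(m, lrf_lo, lrf_hi)
    istd_formula <- sample(formula_templates, m, replace = TRUE)
    istd_conc <- vapply(seq_len(m), function(i) {
      ng_per_l_to_molar(config$istd_spike_ngL, istd_formula[[i]])
    }, numeric(1))
    istds <- data.frame(istd_id = istd_ids, rt_min = istd_rt,
                        true_rf = istd_rf, formula = istd_formula,
                        conc_M = istd_conc, stringsAsFactors = FALSE)

    assigned <- istd_ids[vapply(rt, function(r) which.min(abs(istd_rt - r)),
                                integer(1))]
    compounds <- data.frame(
      compound_id = ids, name = ids, formula = formula, rt_min = rt,
      role = "other", parent_id = NA_character_, log_ie_pred = log_ie,
      istd_id = assigned, is_calibrant = FALSE, stringsAsFactors = FALSE
    )
    truth <- data.frame(compound_id = ids, true_rf = 10^log_rf,
                        true_log_ie = log_ie, tp_rf_ratio = NA_real_,
                        stringsAsFactors = FALSE)
    list(compounds = compounds, truth = truth, istds = istds)
  })
}

#' Carve parent/TP pairs out of the compound pool
#'
#' Reassigns `2 * n_tp_pairs` compounds as parent/TP pairs. Each TP's true
#' response factor is its parent's times `10^N(tp_logratio_mean,
#' tp_logratio_sd)` (mostly below 1 with the default negative mean, as
#' observed for environmental TPs, with extreme draws reaching ratios around
#' 1/17); its logIE is then back-computed from the IE law with a fresh
#' `N(0, sigma_ie)` residual so TPs remain ordinary citizens of the IE-RF
#' relationship.
#'
#' @param config A [synthetic_config()].
#' @param dataset Output of [generate_compounds()].
#' @return `dataset` with roles, `parent_id`, TP response factors, logIE and
#'   `tp_rf_ratio` updated.
#' @export
generate_tp_pairs <- function(config, dataset) {
  k <- config$n_tp_pairs
  if (k == 0) return(dataset)
  with_seed(config$seed + 202L, {
    n <- nrow(dataset$compounds)
    picks <- sample(n, 2 * k)
    parents <- picks[seq_len(k)]
    tps <- picks[k + seq_len(k)]
    cmp <- dataset$compounds
    tr <- dataset$truth
    cmp$role[parents] <- "parent"
    cmp$role[tps] <- "tp"
    cmp$parent_id[tps] <- cmp$compound_id[parents]
    ratio <- 10^stats::rnorm(k, config$tp_logratio_mean, config$tp_logratio_sd)
    tr$true_rf[tps] <- tr$true_rf[parents] * ratio
    tr$tp_rf_ratio[tps] <- ratio
    resid <- stats::rnorm(k, 0, config$sigma_ie)
    tr$true_log_ie[tps] <- (log10(tr$true_rf[tps]) - config$true_intercept -
                              resid) / config$true_slope
    cmp$log_ie_pred[tps] <- tr$true_log_ie[tps]
    dataset$compounds <- cmp
    dataset$truth <- tr
    dataset
  })
}

# saturation: above the knee only a fraction of the added analyte converts
# into signal (detector/ionization saturation)
effective_level <- function(level_ngL, knee, fraction) {
  ifelse(level_ngL <= knee, level_ngL, knee + (level_ngL - knee) * fraction)
}

#' Generate the calibration-standard measurement rows
#'
#' One run per calibration level, every compound measured in every run.
#' Observed (monoisotopic) area is `true_rf * c_eff * drift * (1 + noise) /
#' isotope_correction_factor(formula)`, so the pipeline's isotopologue
#' correction is exercised; levels below `loq_ngL` are censored to zero area
#' and levels above `sat_knee_ngL` respond sublinearly, giving the
#' linear-range filter real work. ISTD areas share the per-run drift, which
#' the ISTD correction cancels.
#'
#' @inheritParams generate_tp_pairs
#' @return Measurement `data.frame` of `standard` rows.
#' @export
generate_calibration_series <- function(config, dataset) {
  with_seed(config$seed + 303L, {
    cmp <- dataset$compounds
    tr <- dataset$truth
    istds <- dataset$istds
    levels <- config$calib_levels_ngL
    n_runs <- length(levels)
    n <- nrow(cmp)
    mw <- vapply(cmp$formula, molar_mass, numeric(1))
    icf <- vapply(cmp$formula, isotope_correction_factor, numeric(1))
    drift <- 10^stats::rnorm(n_runs, 0, config$run_drift_sigma)
    ii <- match(cmp$istd_id, istds$istd_id)
    istd_base <- istds$true_rf[ii] * istds$conc_M[ii]

    rows <- lapply(seq_len(n_runs), function(r) {
      lvl <- levels[[r]]
      conc <- lvl * 1e-9 / mw
      eff <- effective_level(lvl, config$sat_knee_ngL, config$sat_fraction) *
        1e-9 / mw
      noise <- 1 + stats::rnorm(n, 0, config$level_noise)
      area <- tr$true_rf * eff * drift[[r]] * pmax(noise, 0) / icf
      if (lvl < config$loq_ngL) area <- rep(0, n)
      istd_noise <- 1 + stats::rnorm(n, 0, config$level_noise)
      data.frame(
        run_id = sprintf("std_L%02d", r), run_type = "standard",
        compound_id = cmp$compound_id, peak_area = area,
        istd_area = istd_base * drift[[r]] * pmax(istd_noise, 0),
        nominal_conc_M = conc, stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate sample and spiked-sample measurement rows
#'
#' Each of the `n_samples` sample runs contains a uniform-random number of
#' compounds (within `compounds_per_sample_range`) at log-uniform molar
#' concentrations over `conc_range_M`. Spiked samples contain every compound
#' at the cycled spike level. Observed areas are multiplied by a lognormal
#' matrix factor `10^(matrix_bias + a_run + b)` where `a_run` is shared by
#' all peaks of a run (including ISTDs, so ISTD correction cancels it) and
#' `b` is idiosyncratic per compound and per ISTD.
#'
#' @inheritParams generate_tp_pairs
#' @return List with `measurements` (`sample` and `spiked_sample` rows) and
#'   `references` (`run_id, compound_id, reference_conc_M` ground truth).
#' @export
generate_samples <- function(config, dataset) {
  with_seed(config$seed + 404L, {
    cmp <- dataset$compounds
    tr <- dataset$truth
    istds <- dataset$istds
    n <- nrow(cmp)
    mw <- vapply(cmp$formula, molar_mass, numeric(1))
    icf <- vapply(cmp$formula, isotope_correction_factor, numeric(1))
    ii <- match(cmp$istd_id, istds$istd_id)
    istd_base <- istds$true_rf[ii] * istds$conc_M[ii]

    one_run <- function(run_id, run_type, idx, conc, nominal) {
      a_run <- stats::rnorm(1, 0, config$matrix_sigma_run)
      b <- stats::rnorm(length(idx), 0, config$matrix_sigma)
      b_istd <- stats::rnorm(nrow(istds), 0, config$matrix_sigma)
      noise <- 1 + stats::rnorm(length(idx), 0, config$level_noise)
      mfac <- 10^(config$matrix_bias + a_run + b)
      ifac <- 10^(config$matrix_bias + a_run + b_istd[ii[idx]])
      data.frame(
        run_id = run_id, run_type = run_type,
        compound_id = cmp$compound_id[idx],
        peak_area = tr$true_rf[idx] * conc * mfac * pmax(noise, 0) / icf[idx],
        istd_area = istd_base[idx] * ifac,
        nominal_conc_M = nominal, stringsAsFactors = FALSE
      )
    }

    meas <- list()
    refs <- list()
    rng <- config$compounds_per_sample_range
    for (s in seq_len(config$n_samples)) {
      run_id <- sprintf("sample_S%02d", s)
      k <- if (rng[[1]] == rng[[2]]) rng[[1]] else sample(rng[[1]]:rng[[2]], 1)
      idx <- sort(sample(n, k))
      conc <- 10^stats::runif(k, log10(config$conc_range_M[[1]]),
                              log10(config$conc_range_M[[2]]))
      meas[[run_id]] <- one_run(run_id, "sample", idx, conc, NA_real_)
      refs[[run_id]] <- data.frame(run_id = run_id,
                                   compound_id = cmp$compound_id[idx],
                                   reference_conc_M = conc,
                                   stringsAsFactors = FALSE)
    }
    spike_lvls <- rep_len(config$spike_levels_ngL,
                          max(config$n_spiked_samples, 1))
    for (q in seq_len(config$n_spiked_samples)) {
      run_id <- sprintf("spiked_Q%02d", q)
      idx <- seq_len(n)
      conc <- spike_lvls[[q]] * 1e-9 / mw
      meas[[run_id]] <- one_run(run_id, "spiked_sample", idx, conc, conc)
    }
    out_m <- do.call(rbind, meas)
    rownames(out_m) <- NULL
    out_r <- if (length(refs) > 0) do.call(rbind, refs) else
      data.frame(run_id = character(), compound_id = character(),
                 reference_conc_M = numeric(), stringsAsFactors = FALSE)
    rownames(out_r) <- NULL
    list(measurements = out_m, references = out_r)
  })
}

#' Generate per-compound recovery validation records
#'
#' Relative recoveries cluster near 100% with moderate spread, emulating a
#' validated enrichment workflow; the compound filter therefore passes almost
#' everything by default, and filter behaviour is exercised with constructed
#' violations in tests.
#'
#' @inheritParams generate_tp_pairs
#' @return `data.frame` `compound_id, relative_recovery_pct, rsd_pct`.
#' @export
generate_recoveries <- function(config, dataset) {
  with_seed(config$seed + 505L, {
    n <- nrow(dataset$compounds)
    data.frame(
      compound_id = dataset$compounds$compound_id,
      relative_recovery_pct = stats::rnorm(n, 100, 7),
      rsd_pct = abs(stats::rnorm(n, 8, 3)),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a complete synthetic dataset
#'
#' Runs the full generator chain (compounds, parent/TP pairs, calibration
#' series, samples and spiked samples, recoveries). Byte-identical for a
#' given config and seed.
#'
#' @param config A [synthetic_config()].
#' @return List with `compounds`, `truth`, `istds`, `measurements`,
#'   `references`, `recoveries` and the `config`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  ds <- generate_compounds(config)
  ds <- generate_tp_pairs(config, ds)
  standards <- generate_calibration_series(config, ds)
  field <- generate_samples(config, ds)
  ds$measurements <- rbind(standards, field$measurements)
  rownames(ds$measurements) <- NULL
  ds$references <- field$references
  ds$recoveries <- generate_recoveries(config, ds)
  ds$config <- config
  ds
}
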
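small_cfg <- function(seed = 5, ...) {
  synthetic_config(n_compounds = 40, n_tp_pairs = 8, n_samples = 6,
                   n_istds = 20, seed = seed, ...)
}

test_that("generation is deterministic and respects the configured marginals", {
  cfg <- small_cfg()
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a, b)

  cmp <- a$compounds
  expect_true(all(cmp$rt_min >= cfg$rt_range_min[1] &
                    cmp$rt_min <= cfg$rt_range_min[2]))
  base <- a$truth[cmp$role != "tp", ]
  expect_true(all(base$true_rf >= cfg$rf_range[1] &
                    base$true_rf <= cfg$rf_range[2]))

  other_seed <- generate_dataset(small_cfg(seed = 6))
  expect_false(identical(a$measurements, other_seed$measurements))
})

test_that("the default pool matches the emulated campaign dimensions", {
  cfg <- synthetic_config()
  ds <- generate_compounds(cfg)
  expect_equal(nrow(ds$compounds), 341)
  expect_equal(cfg$n_samples, 31)
  expect_equal(length(cfg$calib_levels_ngL), 22)
  expect_equal(range(cfg$calib_levels_ngL), c(0.1, 1000))
})

test_that("zero IE residuals put every response factor exactly on the law", {
  cfg <- small_cfg(sigma_ie = 0)
  ds <- generate_tp_pairs(cfg, generate_compounds(cfg))
  lhs <- log10(ds$truth$true_rf)
  rhs <- cfg$true_slope * ds$truth$true_log_ie + cfg$true_intercept
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("TP response ratios follow the configured lognormal law", {
  same <- small_cfg(tp_logratio_mean = 0, tp_logratio_sd = 0)
  ds <- generate_tp_pairs(same, generate_compounds(same))
  expect_equal(ds$truth$tp_rf_ratio[!is.na(ds$truth$tp_rf_ratio)],
               rep(1, same$n_tp_pairs))
  parent_of <- match(ds$compounds$parent_id, ds$compounds$compound_id)
  tp <- ds$compounds$role == "tp"
  expect_equal(ds$truth$true_rf[tp], ds$truth$true_rf[parent_of[tp]])

  # many pairs: sample median of the ratio near the analytic lognormal median
  big <- synthetic_config(n_compounds = 2000, n_tp_pairs = 900,
                          tp_logratio_mean = -0.5, tp_logratio_sd = 0.5,
                          compounds_per_sample_range = c(4, 44), seed = 2)
  ds2 <- generate_tp_pairs(big, generate_compounds(big))
  med <- median(ds2$truth$tp_rf_ratio, na.rm = TRUE)
  expect_equal(log10(med), -0.5, tolerance = 0.1)
})

test_that("noiseless calibration series lets compute_rf recover the true RF", {
  cfg <- noiseless_config(n_compounds = 15, n_tp_pairs = 2, n_samples = 2,
                          seed = 4)
  ds <- generate_compounds(cfg)
  ds <- generate_tp_pairs(cfg, ds)
  std <- generate_calibration_series(cfg, ds)
  ds$measurements <- std
  rf <- compute_rf_table(std, ds$compounds, istd = TRUE)
  truth <- ds$truth$true_rf[match(rf$compound_id, ds$truth$compound_id)]
  expect_lt(max(abs(rf$rf / truth - 1)), 1e-9)

  # censored low levels are excluded by the filter and the RF still recovered
  cens <- noiseless_config(n_compounds = 15, n_tp_pairs = 2, n_samples = 2,
                           seed = 4, loq_ngL = 0.3)
  std_c <- generate_calibration_series(cens, ds)
  expect_true(any(std_c$peak_area == 0))
  rf_c <- compute_rf_table(std_c, ds$compounds, istd = TRUE)
  truth_c <- ds$truth$true_rf[match(rf_c$compound_id, ds$truth$compound_id)]
  expect_lt(max(abs(rf_c$rf / truth_c - 1)), 1e-9)

  # saturated top levels are trimmed from the high end
  sat <- noiseless_config(n_compounds = 15, n_tp_pairs = 2, n_samples = 2,
                          seed = 4, sat_knee_ngL = 300, sat_fraction = 0.05)
  std_s <- generate_calibration_series(sat, ds)
  rf_s <- compute_rf_table(std_s, ds$compounds, istd = TRUE,
                           tol_fraction = 0.10)
  expect_true(all(grepl("above linear range", rf_s$levels_excluded)))
  truth_s <- ds$truth$true_rf[match(rf_s$compound_id, ds$truth$compound_id)]
  expect_lt(max(abs(rf_s$rf / truth_s - 1)), 1e-9)
})

test_that("sample runs have the configured size, count and concentration range", {
  cfg <- small_cfg()
  ds <- generate_dataset(cfg)
  samples <- ds$measurements[ds$measurements$run_type == "sample", ]
  per_run <- table(samples$run_id)
  expect_length(per_run, cfg$n_samples)
  expect_true(all(per_run >= cfg$compounds_per_sample_range[1] &
                    per_run <= cfg$compounds_per_sample_range[2]))
  expect_true(all(ds$references$reference_conc_M >= cfg$conc_range_M[1] &
                    ds$references$reference_conc_M <= cfg$conc_range_M[2]))
  spiked <- ds$measurements[ds$measurements$run_type == "spiked_sample", ]
  expect_length(unique(spiked$run_id), cfg$n_spiked_samples)
  expect_true(all(!is.na(spiked$nominal_conc_M)))
})

test_that("net ionization suppression biases uncorrected predictions low", {
  cfg <- small_cfg(matrix_bias = -0.3, matrix_sigma = 0.05,
                   matrix_sigma_run = 0, level_noise = 0, sigma_ie = 0,
                   loq_ngL = 0, sat_knee_ngL = Inf, run_drift_sigma = 0)
  bench <- run_benchmark(cfg, istd_modes = FALSE, approaches = "ie", k = 10)
  res <- bench$results[bench$results$run_type == "sample", ]
  ratio <- res$predicted_conc_M / res$reference_conc_M
  expect_lt(median(ratio), 1)

  # with ISTD correction the shared suppression cancels
  bench2 <- run_benchmark(cfg, istd_modes = TRUE, approaches = "ie", k = 10)
  res2 <- bench2$results[bench2$results$run_type == "sample", ]
  ratio2 <- res2$predicted_conc_M / res2$reference_conc_M
  expect_gt(median(ratio2), 0.8)
  expect_lt(median(abs(log10(ratio2))), median(abs(log10(ratio))))
})
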
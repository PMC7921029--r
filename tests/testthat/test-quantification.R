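test_that("surrogate quantification divides corrected signal by the surrogate RF", {
  expect_equal(quantify_parent(2e9, 1e19), 2e-10)
  expect_equal(quantify_closest(2e9, 1e19), 2e-10)
  expect_equal(quantify_ie(2e9, 1e19), 2e-10)
  expect_equal(quantify_ie(0, 1e19), 0)
  expect_error(quantify_parent(1, 0), "positive")

  # all three are homogeneous in the signal
  set.seed(2)
  s <- runif(20, 1e6, 1e10)
  expect_equal(quantify_parent(2 * s, 3e19), 2 * quantify_parent(s, 3e19))

  # a TP responding 17x below its parent is underestimated 17-fold
  true_c <- 4e-10
  parent_rf <- 1e19
  tp_signal <- (parent_rf / 17) * true_c
  pred <- quantify_parent(tp_signal, parent_rf)
  expect_equal(fold_error(pred, true_c), 17)
})

test_that("closest calibrant is the retention-time argmin with stated tie-breaks", {
  cal <- data.frame(compound_id = c("disopyramide", "primidone"),
                    rt_min = c(12.7, 14.5), stringsAsFactors = FALSE)
  expect_equal(closest_calibrant(12.7, cal), "disopyramide")
  expect_equal(closest_calibrant(13.5, cal), "disopyramide")
  expect_equal(closest_calibrant(14.0, cal), "primidone")
  # exact midpoint -> earlier-eluting calibrant
  expect_equal(closest_calibrant(13.6, cal), "disopyramide")

  # identical retention times -> lexicographic id
  tied <- data.frame(compound_id = c("zeta", "alpha"), rt_min = c(10, 10),
                     stringsAsFactors = FALSE)
  expect_equal(closest_calibrant(10, tied), "alpha")

  # agreement with an exhaustive scan on random configurations
  set.seed(31)
  for (i in 1:50) {
    cal <- data.frame(compound_id = sprintf("k%02d", 1:8),
                      rt_min = round(runif(8, 3, 22), 1),
                      stringsAsFactors = FALSE)
    rt <- runif(1, 3, 22)
    d <- abs(cal$rt_min - rt)
    brute <- cal$compound_id[order(d, cal$rt_min, cal$compound_id)][1]
    expect_equal(closest_calibrant(rt, cal), brute)
  }
})

test_that("IE transfer fit matches exact lines and the normal-equations oracle", {
  x <- c(1, 2, 3, 4)
  fit <- fit_ie_transfer(x, 10^(1 * x + 2))
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 2)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-10)

  two <- fit_ie_transfer(c(10, 12), c(1e19, 1e21))
  expect_equal(two$slope, 1)
  expect_equal(two$intercept, 9)
  expect_equal(two$residual_sd, 0)

  expect_error(fit_ie_transfer(c(2, 2, 2), c(1e19, 1e20, 1e21)), "degenerate")
  expect_error(fit_ie_transfer(3, 1e19), "at least 2")

  set.seed(13)
  for (i in 1:10) {
    x <- runif(20, 1, 5)
    y <- 1.3 * x + 15 + rnorm(20, 0, 0.2)
    fit <- fit_ie_transfer(x, 10^y)
    oracle <- normal_equations_fit(x, y)
    expect_equal(fit$slope, oracle$slope, tolerance = 1e-9)
    expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-9)
  }
})

test_that("RF prediction inverts the transfer line", {
  m <- structure(list(slope = 1, intercept = 0), class = "ie_transfer")
  expect_equal(predict_rf_from_ie(19, m), 1e19)
  m0 <- structure(list(slope = 0, intercept = 18.5), class = "ie_transfer")
  expect_equal(predict_rf_from_ie(c(1, 5, 9), m0), rep(10^18.5, 3))
  two <- fit_ie_transfer(c(10, 12), c(1e19, 1e21))
  expect_equal(predict_rf_from_ie(11, two), 1e20)
})

test_that("dataset quantification emits parent rows only for TPs and flags gaps", {
  cfg <- noiseless_config(n_compounds = 30, n_tp_pairs = 5, n_samples = 4,
                          seed = 8)
  ds <- generate_dataset(cfg)
  rf <- compute_rf_table(ds$measurements, ds$compounds)
  cal <- select_calibrants(
    merge(rf[, c("compound_id", "rf")],
          ds$compounds[, c("compound_id", "rt_min")], by = "compound_id"),
    k = 8, n_repeats = 3, seed = 2
  )
  res <- quantify_dataset(ds$measurements, ds$compounds, rf, cal$compound_ids,
                          references = ds$references)
  tp_ids <- ds$compounds$compound_id[ds$compounds$role == "tp"]
  expect_setequal(unique(res$compound_id[res$approach == "parent"]), tp_ids)

  # a TP whose parent has no RF becomes an explicit not-applicable record
  rf_gap <- rf[rf$compound_id != ds$compounds$parent_id[
    match(tp_ids[1], ds$compounds$compound_id)], ]
  res_gap <- quantify_dataset(ds$measurements, ds$compounds, rf_gap,
                              cal$compound_ids, references = ds$references)
  gap_rows <- res_gap[res_gap$approach == "parent" &
                        res_gap$compound_id == tp_ids[1], ]
  expect_gt(nrow(gap_rows), 0)
  expect_true(all(is.na(gap_rows$predicted_conc_M)))
  expect_true(all(is.na(gap_rows$fold_error)))

  # a calibrant quantifying itself via the closest-eluting rule is exact
  self <- res[res$approach == "closest" &
                res$compound_id %in% cal$compound_ids &
                res$run_type == "standard", ]
  expect_gt(nrow(self), 0)
  expect_lt(max(abs(self$fold_error - 1)), 1e-9)
})
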
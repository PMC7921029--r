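test_that("ISTD correction rescales by the standards-anchored ISTD ratio", {
  expect_equal(istd_correct(1000, 100, 100), 1000)
  expect_equal(istd_correct(1000, 50, 100), 2000)
  expect_equal(istd_correct(0, 80, 100), 0)
  expect_error(istd_correct(100, 0, 100), "unusable")

  # homogeneous of degree 1 in the analyte area, identity at the ISTD mean
  set.seed(11)
  a <- runif(50, 0, 1e6)
  i <- runif(50, 10, 1e4)
  m <- runif(50, 10, 1e4)
  expect_equal(istd_correct(3.7 * a, i, m), 3.7 * istd_correct(a, i, m))
  expect_equal(istd_correct(a, m, m), a)
})

test_that("formula parsing handles counts, repeats, and bad symbols", {
  expect_equal(parse_formula("C10H13N5O"),
               c(C = 10L, H = 13L, N = 5L, O = 1L))
  expect_equal(parse_formula("CH4"), c(C = 1L, H = 4L))
  expect_equal(parse_formula("CH3COOH"), c(C = 2L, H = 4L, O = 2L))
  expect_error(parse_formula("C2Xx3"), "Xx")
  expect_error(parse_formula(""), "non-empty")
})

test_that("isotopologue correction matches brute-force expansion and is >= 1", {
  # mononuclidic elements carry no isotope envelope
  expect_identical(isotope_correction_factor("PF3"), 1)
  expect_equal(isotope_correction_factor("C1"), 1 / 0.9893)

  expect_equal(isotope_correction_factor("C10H12N2O"),
               brute_force_icf("C10H12N2O"), tolerance = 1e-9)

  set.seed(7)
  for (i in 1:30) {
    f <- random_formula(40)
    icf <- isotope_correction_factor(f)
    expect_gte(icf, 1)
    expect_equal(icf, brute_force_icf(f), tolerance = 1e-9)
  }
  expect_error(
    isotope_correction_factor("CHe", abundances = list(C = c(0.99, 0.01))),
    "He|unknown"
  )
})

test_that("signal correction table applies ISTD and isotope factors", {
  cmp <- make_compounds(2)
  m <- data.frame(
    run_id = c("std_1", "std_2", "s1"),
    run_type = c("standard", "standard", "sample"),
    compound_id = cmp$compound_id[1],
    peak_area = c(100, 100, 300),
    istd_area = c(80, 120, 50),
    nominal_conc_M = c(1e-10, 1e-10, NA),
    stringsAsFactors = FALSE
  )
  got <- correct_signals(m, cmp, istd = TRUE, isotope = FALSE)
  expect_equal(got$corrected_area[3], 300 * 100 / 50)

  got2 <- correct_signals(m, cmp, istd = FALSE, isotope = TRUE)
  icf <- isotope_correction_factor(cmp$formula[1])
  expect_equal(got2$corrected_area, m$peak_area * icf)
})

test_that("recovery/adduct filter removes exactly the stated violations", {
  cmp <- data.frame(compound_id = sprintf("c%02d", 1:10),
                    stringsAsFactors = FALSE)
  rec <- data.frame(
    compound_id = cmp$compound_id,
    relative_recovery_pct = c(49, 151, 100, 100, 100, 100, 50, 150, 100, 100),
    rsd_pct = c(10, 10, 51, 10, 10, 10, 10, 10, 50, 10),
    stringsAsFactors = FALSE
  )
  out <- filter_compounds(cmp, rec, adduct_compounds = "c04")
  expect_equal(nrow(out$retained), 6)
  expect_setequal(out$retained$compound_id,
                  c("c05", "c06", "c07", "c08", "c09", "c10"))
  reasons <- setNames(out$removed$reason, out$removed$compound_id)
  expect_equal(reasons[["c01"]], "recovery<50%")
  expect_equal(reasons[["c02"]], "recovery>150%")
  expect_equal(reasons[["c03"]], "recovery RSD>50%")
  expect_equal(reasons[["c04"]], "adduct-quantified")
})

test_that("filter keeps boundary values and never removes compliant compounds", {
  cmp <- data.frame(compound_id = sprintf("c%02d", 1:50),
                    stringsAsFactors = FALSE)
  set.seed(3)
  rec <- data.frame(
    compound_id = cmp$compound_id,
    relative_recovery_pct = runif(50, 50, 150),
    rsd_pct = runif(50, 0, 50),
    stringsAsFactors = FALSE
  )
  out <- filter_compounds(cmp, rec)
  expect_equal(nrow(out$retained), 50)
  expect_equal(nrow(out$removed), 0)

  expect_warning(out2 <- filter_compounds(cmp, rec[-1, ]), "without recovery")
  expect_equal(out2$unchecked, "c01")
  expect_equal(nrow(out2$retained), 50)
})

test_that("ISTD assignment prefers structural matches then best coeluting recovery", {
  istds <- data.frame(istd_id = c("istd_a", "istd_b", "istd_c"),
                      rt_min = c(5.0, 5.5, 20.0), stringsAsFactors = FALSE)
  rec <- data.frame(istd_id = c("istd_a", "istd_b", "istd_c"),
                    relative_recovery_pct = c(95, 130, 100),
                    rsd_pct = c(8, 5, 5), stringsAsFactors = FALSE)

  # structurally identical ISTD wins at any retention-time distance
  got <- assign_istd(5.2, istds, rec, structural_istd_id = "istd_c")
  expect_equal(got$istd_id, "istd_c")
  expect_equal(got$reason, "structural")

  # |95-100| + max(0, 8-10) = 5 beats |130-100| + 0 = 30
  got2 <- assign_istd(5.2, istds, rec)
  expect_equal(got2$istd_id, "istd_a")

  # nothing within +/- 2 min -> explicit no-assignment
  got3 <- assign_istd(12.0, istds, rec)
  expect_true(is.na(got3$istd_id))
  expect_equal(got3$reason, "none within rt window")

  # equal scores break on retention-time distance
  rec_tied <- transform(rec, relative_recovery_pct = 100, rsd_pct = 5)
  got4 <- assign_istd(5.1, istds, rec_tied)
  expect_equal(got4$istd_id, "istd_a")
})
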
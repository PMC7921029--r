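# Small in-code fixtures shared across test files.

make_compounds <- function(n = 4) {
  ids <- c("atrazine", "atrazine_desethyl", "carbamazepine", "primidone",
           sprintf("cmp_extra_%02d", seq_len(max(0, n - 4))))[seq_len(n)]
  df <- data.frame(
    compound_id = ids,
    name = ids,
    formula = rep(c("C8H14ClN5", "C6H10ClN5", "C15H12N2O", "C12H14N2O2"),
                  length.out = n),
    rt_min = seq(4, 18, length.out = n),
    role = "other",
    parent_id = NA_character_,
    log_ie_pred = seq(2, 4, length.out = n),
    istd_id = "istd_001",
    is_calibrant = FALSE,
    stringsAsFactors = FALSE
  )
  if (n >= 2) {
    df$role[1] <- "parent"
    df$role[2] <- "tp"
    df$parent_id[2] <- df$compound_id[1]
  }
  df
}

write_tmp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

make_results <- function(fold_errors, approach = "ie", kind = "sample") {
  n <- length(fold_errors)
  data.frame(
    compound_id = sprintf("c%02d", seq_len(n)),
    sample_id = rep("s1", n),
    approach = rep(approach, n),
    istd_corrected = rep(TRUE, n),
    predicted_conc_M = fold_errors * 1e-10,
    reference_conc_M = rep(1e-10, n),
    fold_error = fold_errors,
    run_type = rep(kind, n),
    stringsAsFactors = FALSE
  )
}
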
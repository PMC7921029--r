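# Tabular I/O for the three interchange tables: compounds, measurements and
# quantification results. All files are comma-separated UTF-8 with a single
# header row and "." as decimal separator; missing optional fields are empty
# cells. Concentrations are molar (mol/L) throughout.

compound_roles <- c("parent", "tp", "other")
run_types <- c("standard", "spiked_sample", "sample")
result_columns <- c("compound_id", "sample_id", "approach", "istd_corrected",
                    "predicted_conc_M", "reference_conc_M", "fold_error")

read_table_checked <- function(path, required) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = c("", "NA"))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_fmt("%s: missing required column(s): %s", path,
             paste(missing, collapse = ", "))
  }
  df
}

as_num_col <- function(x, col, path) {
  if (is.numeric(x)) return(as.numeric(x))
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    stop_fmt("%s: malformed numeric value '%s' in column '%s' (row %d)",
             path, x[bad[[1]]], col, bad[[1]])
  }
  out
}

as_flag_col <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' Read a compound table
#'
#' Reads `compounds.csv` (columns `compound_id,name,formula,rt_min,role,
#' parent_id,log_ie_pred,istd_id,is_calibrant`; extra columns are preserved).
#' `role` is one of `parent`, `tp`, `other`; `parent_id` links a
#' transformation product (TP) to its parent compound and must resolve to a
#' row with `role = "parent"`. `log_ie_pred` is the externally predicted
#' log10 electrospray ionization efficiency.
#'
#' @param path Path to a CSV file.
#' @return A `data.frame`, one row per compound, in file order.
#' @export
read_compound_table <- function(path) {
  df <- read_table_checked(path, c("compound_id", "formula", "rt_min", "role"))
  df$compound_id <- as.character(df$compound_id)
  dup <- df$compound_id[duplicated(df$compound_id)]
  if (length(dup) > 0) {
    stop_fmt("%s: duplicate compound_id '%s'", path, dup[[1]])
  }
  df$rt_min <- as_num_col(df$rt_min, "rt_min", path)
  bad_rt <- which(is.na(df$rt_min) | df$rt_min <= 0)
  if (length(bad_rt) > 0) {
    stop_fmt("%s: rt_min must be a positive number (row %d)", path, bad_rt[[1]])
  }
  check_choice(df$role, compound_roles, "role")
  if (is.null(df$name)) df$name <- df$compound_id
  if (is.null(df$parent_id)) df$parent_id <- NA_character_
  df$parent_id <- as.character(df$parent_id)
  if (is.null(df$log_ie_pred)) df$log_ie_pred <- NA_real_
  df$log_ie_pred <- as_num_col(df$log_ie_pred, "log_ie_pred", path)
  if (is.null(df$istd_id)) df$istd_id <- NA_character_
  df$istd_id <- as.character(df$istd_id)
  if (is.null(df$is_calibrant)) df$is_calibrant <- FALSE
  df$is_calibrant <- as_flag_col(df$is_calibrant)
  validate_compounds(df, where = path)
  df
}

# shared invariant checks, used by the reader and by in-memory constructors
validate_compounds <- function(compounds, where = "compound table") {
  has_parent <- !is.na(compounds$parent_id)
  if (any(has_parent & compounds$parent_id == compounds$compound_id)) {
    bad <- compounds$compound_id[has_parent &
                                   compounds$parent_id == compounds$compound_id][[1]]
    stop_fmt("%s: compound '%s' lists itself as its own parent", where, bad)
  }
  parents <- compounds$compound_id[compounds$role == "parent"]
  unresolved <- setdiff(compounds$parent_id[has_parent], parents)
  if (length(unresolved) > 0) {
    stop_fmt("%s: parent_id '%s' does not resolve to a compound with role 'parent'",
             where, unresolved[[1]])
  }
  invisible(compounds)
}

#' Read a measurement table
#'
#' Reads `measurements.csv` (columns `run_id,run_type,compound_id,peak_area,
#' istd_area,nominal_conc_M`). One row is one integrated peak area of one
#' compound in one run, together with the peak area of its assigned internal
#' standard (ISTD) in the same run. `nominal_conc_M` is required for
#' calibration standards, carries the spike level for spiked samples, and is
#' empty for real samples.
#'
#' @param path Path to a CSV file.
#' @return A `data.frame`, one row per measurement.
#' @export
read_measurement_table <- function(path) {
  df <- read_table_checked(path, c("run_id", "run_type", "compound_id",
                                   "peak_area", "istd_area"))
  df$run_id <- as.character(df$run_id)
  df$compound_id <- as.character(df$compound_id)
  check_choice(df$run_type, run_types, "run_type")
  df$peak_area <- as_num_col(df$peak_area, "peak_area", path)
  df$istd_area <- as_num_col(df$istd_area, "istd_area", path)
  neg <- which(df$peak_area < 0 | df$istd_area < 0)
  if (length(neg) > 0) {
    stop_fmt("%s: negative peak or ISTD area (row %d)", path, neg[[1]])
  }
  if (is.null(df$nominal_conc_M)) df$nominal_conc_M <- NA_real_
  df$nominal_conc_M <- as_num_col(df$nominal_conc_M, "nominal_conc_M", path)
  no_conc <- which(df$run_type == "standard" & is.na(df$nominal_conc_M))
  if (length(no_conc) > 0) {
    stop_fmt("%s: standard row lacking nominal_conc_M (row %d)", path, no_conc[[1]])
  }
  bad_conc <- which(!is.na(df$nominal_conc_M) & df$nominal_conc_M <= 0)
  if (length(bad_conc) > 0) {
    stop_fmt("%s: nominal_conc_M must be positive when present (row %d)",
             path, bad_conc[[1]])
  }
  df
}

#' Write and read quantification results
#'
#' `write_results()` writes one row per quantification result with a
#' deterministic column order (`compound_id,sample_id,approach,istd_corrected,
#' predicted_conc_M,reference_conc_M,fold_error`, then any extra columns).
#' Numeric fields round-trip through `read_results()` to at least 12
#' significant digits; infinite fold errors are written as `Inf`.
#'
#' @param results `data.frame` of quantification results.
#' @param path Output resp. input CSV path.
#' @return `write_results()` returns `path` invisibly; `read_results()`
#'   returns the results `data.frame`.
#' @export
write_results <- function(results, path) {
  missing <- setdiff(result_columns, names(results))
  if (length(missing) > 0) {
    stop_fmt("results are missing column(s): %s", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(results), result_columns)
  out <- results[, c(result_columns, extra), drop = FALSE]
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
      out[[col]] <- sprintf("%.15g", out[[col]])
      out[[col]][out[[col]] %in% c("NA", "nan")] <- NA_character_
    }
  }
  tryCatch(
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = ""),
    error = function(e) stop_fmt("cannot write results to '%s': %s",
                                 path, conditionMessage(e))
  )
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  df <- read_table_checked(path, result_columns)
  df$istd_corrected <- as_flag_col(df$istd_corrected)
  for (col in c("predicted_conc_M", "reference_conc_M", "fold_error")) {
    df[[col]] <- as_num_col(df[[col]], col, path)
  }
  df
}
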
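# Molecular formula handling: parsing, molar mass, and the isotopologue
# correction factor that converts a monoisotopic peak area into the total
# signal of all isotopologues of the ion.

#' Representative terrestrial isotope abundances
#'
#' A fixed, versioned table of isotopic abundances (CIAAW-style representative
#' values) used by [isotope_correction_factor()]. Each entry is a numeric
#' vector of abundances ordered by increasing isotope mass and summing to 1;
#' the first element is the lightest (monoisotopic) isotope. Shipping the
#' constants with the package keeps results bit-reproducible across installs;
#' pass your own table to [isotope_correction_factor()] to override.
#'
#' @format Named list of numeric vectors, one per element symbol.
#' @export
isotope_abundances <- list(
  H  = c(0.999885, 0.000115),
  C  = c(0.9893, 0.0107),
  N  = c(0.99636, 0.00364),
  O  = c(0.99757, 0.00038, 0.00205),
  S  = c(0.9499, 0.0075, 0.0425, 0.0001),
  P  = 1,
  F  = 1,
  I  = 1,
  Cl = c(0.7576, 0.2424),
  Br = c(0.5069, 0.4931),
  Si = c(0.92223, 0.04685, 0.03092),
  Na = 1,
  K  = c(0.932581, 0.000117, 0.067302)
)

# Conventional standard atomic weights (g/mol), used only for the ng/L <-> M
# unit conversion at the I/O boundary.
atomic_weights <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.973762, F = 18.998403, I = 126.90447, Cl = 35.45,
  Br = 79.904, Si = 28.085, Na = 22.98977, K = 39.0983
)

#' Parse a molecular formula
#'
#' Parses a Hill-notation molecular formula (e.g. `"C10H13N5O"`) into element
#' counts. Counts may be multi-digit; a missing count means 1. Repeated
#' element symbols are summed.
#'
#' @param formula Single formula string.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C10H13N5O")
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1 || is.na(formula) ||
      !nzchar(formula)) {
    stop_fmt("formula must be a single non-empty string")
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    stop_fmt("unparseable formula '%s'", formula)
  }
  elements <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  unknown <- setdiff(elements, names(atomic_weights))
  if (length(unknown) > 0) {
    stop_fmt("unknown element symbol '%s' in formula '%s'",
             unknown[[1]], formula)
  }
  out <- tapply(counts, elements, sum)
  counts <- as.integer(out)
  names(counts) <- names(out)
  counts
}

#' Isotopologue correction factor for a molecular formula
#'
#' Electrospray ionization-efficiency predictions refer to the summed signal
#' of all gas-phase isotopologues of an ion, while peak integration typically
#' reports only the monoisotopic peak. The correction factor is the total
#' isotopologue abundance divided by the abundance of the all-lightest-isotope
#' (monoisotopic) species:
#' \deqn{f = 1 / \prod_e a_e^{n_e}}
#' where \eqn{a_e} is the lightest-isotope abundance of element \eqn{e} and
#' \eqn{n_e} its count in the formula. Multiply a monoisotopic peak area by
#' this factor (always \eqn{\ge 1}) to obtain the total isotopologue signal.
#'
#' @param formula Molecular formula string (see [parse_formula()]).
#' @param abundances Isotope abundance table; defaults to the shipped
#'   [isotope_abundances].
#' @return Correction factor, a number \eqn{\ge 1}.
#' @examples
#' isotope_correction_factor("C10H13N5O")
#' isotope_correction_factor("PF3") # mononuclidic elements only -> exactly 1
#' @export
isotope_correction_factor <- function(formula, abundances = isotope_abundances) {
  counts <- parse_formula(formula)
  missing <- setdiff(names(counts), names(abundances))
  if (length(missing) > 0) {
    stop_fmt("element '%s' missing from the isotope abundance table",
             missing[[1]])
  }
  log_mono <- 0
  for (el in names(counts)) {
    a <- abundances[[el]]
    if (abs(sum(a) - 1) > 1e-9) {
      stop_fmt("abundances for element '%s' do not sum to 1", el)
    }
    if (a[[1]] <= 0) stop_fmt("element '%s' has non-positive lightest-isotope abundance", el)
    log_mono <- log_mono + counts[[el]] * log(a[[1]])
  }
  exp(-log_mono)
}

#' Molar mass of a molecular formula
#'
#' Conventional molar mass (standard atomic weights, g/mol), used to convert
#' between mass concentrations (ng/L) and molar concentrations.
#'
#' @inheritParams isotope_correction_factor
#' @return Molar mass in g/mol.
#' @export
molar_mass <- function(formula) {
  counts <- parse_formula(formula)
  sum(atomic_weights[names(counts)] * counts)
}

#' Convert between ng/L and molar concentration
#'
#' Concentrations are carried internally in mol/L; mass concentrations only
#' appear at the I/O boundary (spike and calibration levels quoted in ng/L).
#'
#' @param ng_l,conc_m Concentration in ng/L resp. mol/L (vectorised).
#' @param formula Molecular formula giving the molar mass.
#' @return Numeric vector of converted concentrations.
#' @export
ng_per_l_to_molar <- function(ng_l, formula) {
  ng_l * 1e-9 / molar_mass(formula)
}

#' @rdname ng_per_l_to_molar
#' @export
molar_to_ng_per_l <- function(conc_m, formula) {
  conc_m * molar_mass(formula) * 1e9
}
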
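# Independent oracles used to cross-check the implementation.

# All compositions of n into k non-negative parts (k small), as a matrix with
# one composition per row.
compositions <- function(n, k) {
  if (k == 1) return(matrix(n, ncol = 1))
  out <- list()
  for (i in 0:n) {
    rest <- compositions(n - i, k - 1)
    out[[i + 1]] <- cbind(i, rest)
  }
  do.call(rbind, out)
}

# Brute-force isotopologue expansion: for each element, enumerate every
# distribution of its atoms over its isotopes and sum the multinomial
# probabilities; the correction factor is the summed abundance of all
# isotopologues divided by the all-lightest-isotope term.
brute_force_icf <- function(formula, abundances = semiquant::isotope_abundances) {
  counts <- semiquant::parse_formula(formula)
  total <- 1
  mono <- 1
  for (el in names(counts)) {
    a <- abundances[[el]]
    n <- counts[[el]]
    k <- length(a)
    el_total <- 0
    if (k == 1) {
      el_total <- a^n
    } else {
      comp <- compositions(n, k)
      for (r in seq_len(nrow(comp))) {
        m <- comp[r, ]
        el_total <- el_total +
          exp(lgamma(n + 1) - sum(lgamma(m + 1)) + sum(m * log(a)))
      }
    }
    total <- total * el_total
    mono <- mono * a[[1]]^n
  }
  total / mono
}

# Closed-form ordinary least squares through the normal equations.
normal_equations_fit <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- (sy - slope * sx) / n
  list(slope = slope, intercept = intercept)
}

# Random molecular formula over CHNOS + P, Cl, Br, F with at most
# `max_atoms` atoms in total.
random_formula <- function(max_atoms = 40) {
  pool <- c("C", "H", "N", "O", "S", "P", "Cl", "Br", "F")
  n_el <- sample(2:5, 1)
  els <- sample(pool, n_el)
  total <- sample(n_el:max_atoms, 1)
  counts <- as.vector(stats::rmultinom(1, total - n_el, rep(1, n_el))) + 1
  paste0(els, ifelse(counts > 1, counts, ""), collapse = "")
}
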
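---
title: "Standard-free semi-quantification for non-target screening: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standard-free semi-quantification for non-target screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semiquant)
```

## The problem

Non-target screening by LC/ESI/HRMS routinely detects hundreds of
micropollutants — pesticides, pharmaceuticals, and especially their
transformation products (TPs) — for which no analytical standard can be
bought. Without a standard there is no calibration graph, and electrospray
response factors vary between compounds by up to six orders of magnitude, so
a peak area alone says almost nothing about concentration. `semiquant`
implements and benchmarks the three surrogate strategies practitioners use
in this situation:

* **Approach I (parent)** — quantify a TP with its parent compound's
  response factor, assuming the transformation left the ionization-relevant
  parts of the structure intact. Only applicable to TPs with a measurable
  parent.
* **Approach II (closest)** — use the response factor of the calibration
  compound eluting nearest in retention time, assuming ionization efficiency
  varies smoothly along the chromatographic gradient.
* **Approach III (ie)** — predict each compound's electrospray ionization
  efficiency from structure (externally, e.g. with a machine-learned
  predictor; `log_ie_pred` is an input column here), then transfer those
  universal values to instrument-specific response factors via a regression
  over a small set of calibration compounds.

All three divide a *corrected* signal by a surrogate response factor, so the
package factors the problem into: signal correction, response-factor
calibration, surrogate selection, and error evaluation.

## Signal corrections

**Internal-standard correction.** Each analyte is paired with an
isotope-labelled internal standard (ISTD) spiked at a fixed level into every
run. The correction rescales the analyte area by the ratio of the ISTD's
mean area over all calibration standards to its area in the current run:

$$\mathrm{Signal}^{corr} = \mathrm{Signal} \cdot
  \frac{\overline{\mathrm{Signal}}^{ISTD}_{standards}}
       {\mathrm{Signal}^{ISTD}_{run}}$$

This cancels run-to-run drift and the part of matrix suppression shared
between analyte and ISTD. `istd_correct()` implements the scalar operation;
`correct_signals()` applies it table-wide, computing the per-ISTD anchor
mean from the table's own standard runs.

**Isotopologue correction.** Ionization-efficiency predictions refer to all
gas-phase ions formed from the protonated molecule, while peak integration
usually reports the monoisotopic peak only. `isotope_correction_factor()`
multiplies the monoisotopic area by the total-to-monoisotopic abundance
ratio, which for a formula with element counts $n_e$ and lightest-isotope
abundances $a_e$ is exactly $1/\prod_e a_e^{n_e}$ (the full isotopologue
polynomial sums to 1). The abundance table is a fixed CIAAW-style snapshot
shipped in code (`isotope_abundances`) so results are bit-reproducible; it
can be overridden. In-source fragments would in principle also need summing;
they are assumed pre-summed upstream by the peak integration software — a
known limitation.

## Response-factor calibration

For each compound the standards give per-level response factors
$RF_{level} = \mathrm{Signal}^{corr}/c$, and the compound's RF is their
arithmetic mean under a negligible-intercept assumption (`compute_rf()`).
Averaging level-wise RFs rather than fitting a zero-intercept regression
slope keeps every retained level equally weighted across four decades of
concentration; a least-squares slope would be dominated by the top levels.

**Linear-range filter.** Levels below the quantification limit or above the
upper limit of linearity would bias the mean, so `linear_range_filter()`
trims them — from the endpoints of the concentration-sorted series only,
because LOQ censoring attacks the low end and saturation the high end.
Iteratively, the endpoint whose $RF_{level}$ deviates most from the current
median is dropped if its relative deviation exceeds `tol_fraction`
(default 0.30, an artifact parameter: large enough to keep honestly noisy
levels, small enough to catch censoring and saturation), down to
`min_levels` (default 3). Interior levels are never dropped, ties between
endpoints drop the low-concentration side, and series with at most
`min_levels` levels pass untrimmed (a single-level series is a legitimate,
if fragile, calibration).

**Calibrant selection.** Approaches II and III are anchored by a small set
of calibration compounds (default $k = 20$). `select_calibrants()` draws
`n_repeats` (default 3) random $k$-subsets and keeps the one with the widest
joint coverage, scored as the sum of the subset's fractional retention-time
span and fractional log10-RF span. The additive score is a deterministic
scalarization of "widest range of retention time and response factors";
whether the two spans should instead be ranked lexicographically is
genuinely open, but the additive form is symmetric, bounded in $(0, 2]$, and
equal to 2 exactly when both spans are fully covered. Candidates are
canonically ordered by id before seeded sampling so the selection is
independent of input row order. A known calibrant list can bypass sampling
(`run_benchmark(calibrant_ids = ...)`).

## The transfer model and quantification

`fit_ie_transfer()` regresses $\log_{10} RF$ on $\log_{10} IE_{pred}$ over
the calibrants by unweighted ordinary least squares — base-10 logs give even
weight to points spanning several orders of magnitude. All supplied
calibrants enter the fit; no outlier rejection is attempted. The fitted line
converts any compound's predicted ionization efficiency into a response
factor (`predict_rf_from_ie()`), and all three approaches then share the
same final division, `concentration = corrected signal / surrogate RF`.
Zero signal maps to zero concentration by convention; negative
concentrations cannot arise. `quantify_dataset()` runs the approaches over a
whole measurement table: approach I rows are emitted only for TPs, and a TP
whose parent lacks a response factor yields an explicit not-applicable
record rather than silently falling back to another approach. Rows with zero
peak area are treated as non-detects and not quantified.

## Accuracy evaluation

The symmetric fold error
$$\mathrm{error} = \max\!\left(\frac{c_{pred}}{c_{ref}},
                               \frac{c_{ref}}{c_{pred}}\right) \ge 1$$
treats over- and underestimation equally and is comparable across
concentrations (`fold_error()`). `summarize_benchmark()` reports, per
approach × dataset kind (standards / spiked samples / samples) ×
ISTD-correction mode: the arithmetic mean fold error, the maximum, and the
percentage of data points with error below 10-fold. The arithmetic mean is
the headline statistic; because fold errors are heavy-tailed, the geometric
mean is emitted as an auxiliary column. One data point is one compound in
one run; the number of distinct compounds is reported alongside to keep the
two denominators explicit. Infinite errors (zero predictions) are excluded
from the mean and max but stay in the within-10× denominator and are counted
separately. Fold errors are computed on molar concentrations; mass-based
concentrations give identical values since the units cancel (asserted by
test).

## What the synthetic generator emulates

`generate_dataset()` produces a campaign with the structure of a large
groundwater monitoring study:

| Parameter | Default | Meaning |
|---|---|---|
| `n_compounds` | 341 | analyte pool |
| `rt_range_min` | 3.2–22.1 min | retention-time span |
| `rf_range` | 1.5e18–5.3e20 1/M | response-factor span |
| `calib_levels_ngL` | 22 levels, 0.1–1000 ng/L | geometric calibration series |
| `conc_range_M` | 5e-13–1e-8 M | sample concentrations (log-uniform) |
| `n_samples`, `compounds_per_sample_range` | 31, 4–44 | sample runs and their occupancy |
| `n_spiked_samples`, `spike_levels_ngL` | 6, 10/100 ng/L | spiked validation runs |
| `n_istds`, `istd_spike_ngL` | 224, 100 ng/L | ISTD pool, nearest-RT assignment |
| `n_tp_pairs`, `tp_logratio_mean`, `tp_logratio_sd` | 60, −0.3, 0.5 | parent/TP pairs; log10 RF ratio |
| `true_slope`, `true_intercept`, `sigma_ie` | 1, 16.7, 0.15 | IE–RF law and its scatter |

True response factors follow
$\log_{10} RF = slope \cdot \log IE + intercept + N(0, \sigma_{IE})$,
clamped to `rf_range`; logIE is uniform over the ~2.5 decades that map onto
that range (the law's slope/intercept are artifact constants, and the
uniform logIE marginal is a design choice — no distribution is available
for the real data). The generator plays the role of the external IE
predictor, so `log_ie_pred` equals the true logIE and $\sigma_{IE}$ is the
*combined* predictor-plus-transfer scatter; 0.15 log units keeps most
IE-based predictions within a factor of ~2, matching the accuracy regime a
well-trained predictor achieves. TP response factors are the parent's times
a lognormal ratio (median $10^{-0.3} \approx 0.5$ with sd 0.5: most TPs
respond below their parent, with extreme draws reaching ratios around 1/17);
each TP's logIE is then back-computed through the law with a fresh residual,
so TPs remain ordinary members of the IE–RF relationship.

Calibration standards carry multiplicative area noise (`level_noise`, 5%), a
shared per-run drift (`run_drift_sigma`, 0.05 log10 units) that the ISTD
correction cancels, LOQ censoring (levels below `loq_ngL = 0.2` emit zero
area) and a saturation knee (`sat_knee_ngL = 600`, above which only
`sat_fraction = 0.3` of additional analyte converts to signal) — so the
linear-range filter has real work at the defaults. Sample matrix effects are
multiplicative lognormal factors $10^{bias + a_{run} + b}$ with a net
suppression bias (`matrix_bias = -0.1`), a per-run component
(`matrix_sigma_run = 0.1`) shared with the ISTDs — the part ISTD correction
cancels — and an idiosyncratic per-compound component
(`matrix_sigma = 0.1`) it cannot cancel. Observed areas are divided by each
compound's isotopologue factor so the pipeline's isotope correction is
genuinely exercised.

**What it does not emulate.** Retention time and response factor are
independent in the generator; in real reversed-phase data the two are weakly
coupled through hydrophobicity, which is precisely what approach II relies
on. Synthetic benchmarks therefore *understate* approach II relative to real
campaigns (its errors here reflect the full RF spread, not the
local-smoothness residual), while the qualitative ranking — IE-based
transfer most accurate, parent-based intermediate and TP-limited — is
preserved. Chromatographic peak shapes, in-source fragmentation, adducts,
co-elution interferences and enrichment-recovery chemistry are not
modelled, and reference concentrations are exact truths rather than
standard-based measurements with their own uncertainty. Passing tests on
synthetic data validate the computational chain, not the field accuracy of
any approach.

## Numerical and design choices

* **ISTD assignment score** (`assign_istd()`): structurally identical ISTDs
  win outright; otherwise candidates within ±2 min are ranked by
  $|RR - 100| + \max(0, RSD - 10)$ — recovery distance from 100% plus excess
  spread above a 10% floor — with ties broken by retention-time distance,
  then id. "Best relative recovery, ideally close to 100% with low
  deviation" needs a single deterministic scalarization; this one is the
  simplest that penalises both failure modes and ignores immaterial RSD
  differences below 10%.
* **Boundary semantics:** recovery filters use strict inequalities
  (RR = 50%, RR = 150%, RSD = 50% are retained); compounds without recovery
  evidence pass with a warning, since filtering is only justified by
  evidence of poor recovery.
* **Determinism:** every stochastic step (generation, calibrant sampling)
  runs under a locally seeded RNG derived from the config seed by fixed
  offsets, restoring the caller's RNG state; identical config + seed gives
  byte-identical tables.
* **Degenerate inputs:** all-identical calibrant logIE values are a hard
  "degenerate fit" error; an all-censored calibration series is a hard
  "no linear range" error; a zero ISTD area in a run is a hard error naming
  the unusable run; an empty ISTD catalogue is an error while "no ISTD
  within ±2 min" is an explicit no-assignment result the caller decides on.
* **Problem sizes in the test suite:** unit tests run pools of 15–80
  compounds; the end-to-end exactness and ranking checks run the full
  341-compound campaign (a few seconds each). The brute-force isotopologue
  oracle expands the complete multinomial polynomial for formulas up to 40
  atoms; the OLS oracle is the closed-form normal equations.

## A worked run

```{r example}
bench <- run_benchmark(synthetic_config(seed = 1))
subset(bench$summary, dataset_kind == "samples" & istd_corrected,
       select = c(approach, n_compounds, n_datapoints, mean_error,
                  max_error, pct_within_10x))
bench$transfer_models$istd_corrected
```

The IE-transfer approach achieves the lowest mean fold error and keeps all
sample data points within 10-fold; the parent approach is intermediate but
covers only TPs; the closest-eluting approach suffers from the generator's
independent RT–RF structure, as discussed above.

## Limitations

* The IE predictor itself is out of scope: `log_ie_pred` is an input, and
  prediction failures for under-represented substructures (the dominant
  error source in practice) enter only through $\sigma_{IE}$.
* Negative ionization mode and adduct-based quantification are not covered.
* In-source fragment summation is assumed done upstream.
* The mean/max/within-10× summary mirrors the common benchmark layout; no
  significance testing between approaches is attempted.
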
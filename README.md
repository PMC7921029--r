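# semiquant

Standard-free semi-quantification for LC/ESI/HRMS non-target screening of
micropollutants and their transformation products.

## The problem

Non-target screening detects far more water contaminants — pesticides,
pharmaceuticals, and especially their transformation products (TPs) — than
analytical standards exist for. Electrospray response factors differ between
compounds by orders of magnitude, so concentrations must be estimated with a
surrogate response factor. `semiquant` implements the three established
strategies on a common corrected-signal basis and benchmarks them against
each other:

| Approach | Surrogate RF | Applicability |
|---|---|---|
| `parent` | the TP's parent compound: `c = Signal / RF_parent` | TPs with a measurable parent |
| `closest` | the calibration compound eluting nearest in retention time | any compound |
| `ie` | transfer of predicted ionization efficiency: `log10 RF = slope * logIE_pred + intercept`, fitted over ~20 calibration compounds, then `c = Signal / RF_predicted` | any compound with a predicted logIE |

Signals are first corrected with the internal-standard (ISTD) ratio
`Signal * mean(Signal_ISTD in standards) / Signal_ISTD(run)` and the
isotopologue factor `1 / prod(a_e^n_e)` that converts a monoisotopic peak
area into the summed isotopologue signal. Response factors come from
zero-intercept calibration, `RF = mean(Signal_corr / c)` over the levels
retained by an endpoint-trimming linear-range filter. Accuracy is measured
with the symmetric fold error `max(pred/ref, ref/pred) >= 1` and summarised
as mean error, max error and % of data points within 10-fold.

A seeded synthetic generator emulates a groundwater monitoring campaign (341
compounds, retention times 3.2–22.1 min, response factors 1.5e18–5.3e20 1/M,
a 22-level 0.1–1000 ng/L calibration series, 31 samples containing 4–44
compounds, 6 spiked samples, ISTDs at 100 ng/L, 60 parent/TP pairs with TP
response mostly below the parent's) together with a hidden truth table, so
the entire pipeline is verifiable without proprietary data. See the methods
vignette (`vignettes/semiquantification-methods.Rmd`) for the model details
and design decisions.

## Worked example

```r
library(semiquant)

bench <- run_benchmark(synthetic_config(seed = 1))
subset(bench$summary, dataset_kind == "samples" & istd_corrected,
       select = c(approach, n_compounds, n_datapoints, mean_error,
                  max_error, pct_within_10x))
#>    approach n_compounds n_datapoints mean_error max_error pct_within_10x
#> 5    parent          54          133        4.6     27.95           87.2
#> 11  closest         311          790       25.6   1545.76           63.0
#> 17       ie         311          790        1.5      4.07          100.0

bench$transfer_models$istd_corrected
#> IE->RF calibration transfer: log10(RF) = 0.9836 * logIE + 16.7319
#>   20 calibrants, residual sd 0.1227 log10 units
```

Reading: across the 31 synthetic groundwater samples, ionization-efficiency
transfer predicts concentrations with a mean fold error of 1.5 and keeps
every data point within a factor of 10; the parent-compound approach is
intermediate (mean 4.6×) and only covers TPs; the closest-eluting approach
fares worst here because the generator draws retention time and response
factor independently, so elution proximity carries no response information —
on real reversed-phase data the two are correlated and approach II performs
considerably better (see the vignette). The fitted transfer line recovers
the generator's IE–RF law (slope 1, intercept 16.7).

Individual stages are available as plain functions: `correct_signals()`,
`compute_rf_table()`, `select_calibrants()`, `fit_ie_transfer()`,
`quantify_dataset()`, `summarize_benchmark()`, plus CSV readers/writers for
the compound, measurement and result tables. A thin command-line wrapper for
the synthetic workflow lives at `inst/scripts/semiquant.R`
(`simulate` / `run-all`).

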
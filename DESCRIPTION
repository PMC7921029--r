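Package: semiquant
Title: Standard-Free Semi-Quantification for LC-HRMS Non-Target Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to benchmark quantification of micropollutants and their
    transformation products detected by LC/ESI/HRMS non-target screening when
    no analytical standards are available. Implements internal-standard and
    isotopologue signal corrections, zero-intercept response-factor
    calibration with a linear-range filter, random selection of calibration
    compounds, and three surrogate quantification approaches: the parent
    compound's response factor for transformation products, the closest
    eluting calibration compound, and calibration transfer of predicted
    electrospray ionization efficiencies. Includes a symmetric fold-error
    accuracy metric, benchmark summaries, and a seeded synthetic-data
    generator emulating a groundwater monitoring campaign so the whole
    pipeline can be exercised and validated without proprietary data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
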
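Package: icscore
Title: Interval Coded Scoring for Interpretable Clinical Risk Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Learns clinical risk score charts from labelled tabular data.
    Each covariate effect is a step function whose intervals are selected
    automatically by minimizing a hinge loss with a (reweighted)
    total-variation penalty on adjacent interval coefficients, solved as an
    exact linear program.  Fitted coefficients are normalized and rounded to
    an integer point chart, and a monotone link maps the total score to an
    event risk.  Includes cross-validated tuning, bootstrap and calibration
    diagnostics, diagnostic-test metrics, a classical Sullivan-style score
    system for comparison, questionnaire and bar-chart rendering, and a
    synthetic data generator with known piecewise-constant log-odds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, graphics, grDevices, tools, jsonlite
Suggests: testthat (>= 3.0.0), boot, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
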
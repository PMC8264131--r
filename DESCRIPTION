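Package: dialysim
Title: In Vitro Hemodialysis Circuit Simulation, Clearance Estimation and
    In Vitro-In Vivo Correlation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for bench-scale hemodialysis pharmacokinetics: a
    closed-loop dialysis-circuit simulator (well-mixed blood reservoir,
    countercurrent dialyzer with fixed or K0A-based membrane clearance,
    optional saturable membrane adsorption, multiplicative measurement
    noise), hematocrit-corrected clearance estimators with per-condition
    summaries and noncompartmental summaries (trapezoidal AUC, log-linear
    elimination fit), plasma protein binding from ultrafiltration data,
    and an in vitro/in vivo correlation layer (straight-line clearance
    correlation, volume-of-distribution time scaling, membrane-area
    extrapolation). Includes CSV/YAML pipeline glue and a command-line
    entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
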
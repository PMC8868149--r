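Package: deadspacePK
Title: Microdialysis Pharmacokinetics and Target Attainment in a Surgical Deadspace
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-compartment microdialysis antibiotic
    studies: internal-standard (retrodialysis) relative-recovery calibration,
    recovery-corrected concentration-time profiles, non-compartmental
    pharmacokinetic metrics (linear-up/log-down trapezoidal AUC, Cmax, Tmax,
    terminal elimination rate and half-life, tissue penetration ratios),
    pharmacodynamic target attainment (fT>MIC, %fT>MIC, time to threshold
    concentration), and cohort-level summary tables over repeated dosing
    intervals. Includes a compartmental simulator of a porcine shoulder
    deadspace study (plasma, cancellous bone, and a consolidating surgical
    deadspace sampled by microdialysis) with dense-grid ground truth for
    every downstream metric.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    deSolve,
    jsonlite,
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
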
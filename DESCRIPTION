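Package: hfscreen
Title: Markov Cohort Cost-Effectiveness Model for Heart Failure Screening
    in Type 2 Diabetes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Lifetime Markov cohort simulation of heart-failure detection
    and progression in patients with type 2 diabetes aged 60 or over.
    Compares screening strategies (electronic-medical-record and symptom
    checks, physical examination, natriuretic peptide, ECG, direct
    echocardiography) against no screening on discounted quality-adjusted
    life-years and costs. Includes incremental cost-effectiveness analysis
    with strong and extended dominance, probabilistic sensitivity analysis
    with Beta/Gamma/Dirichlet parameter sampling, cost-effectiveness
    acceptability curves, scenario grids for the effectiveness of treatment
    in heart failure with preserved ejection fraction, and seeded
    generators for model inputs that are not published (NYHA transition
    matrices, life tables, patient-level utility and cost samples).
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
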
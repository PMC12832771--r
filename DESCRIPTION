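Package: psmcea
Title: Partitioned Survival Cost-Effectiveness Modelling from Digitized
    Kaplan-Meier Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for trial-based cost-effectiveness analysis of
    first-line regimens in unresectable hepatocellular carcinoma: validation of
    digitized Kaplan-Meier coordinates, reconstruction of pseudo
    individual-patient data constrained by number-at-risk tables, censored
    maximum-likelihood fitting of five parametric survival families with
    Akaike-weight model averaging, a four-state partitioned survival model
    (progression-free, second progression-free, progressive disease, death),
    discounted cost and QALY accrual, incremental cost-effectiveness ratios and
    net monetary benefit, and one-way, two-way, probabilistic, price-threshold
    and scenario analyses. A synthetic-trial generator with known ground truth
    makes every stage testable without access to published trial figures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
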
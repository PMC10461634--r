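Package: isletsim
Title: Paracrine Simulation of Glucose-Stimulated Insulin and Glucagon Secretion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the coupled glucose-driven secretion of insulin by
    pancreatic beta-cells and glucagon by alpha-cells, including the paracrine
    crosstalk between the two hormones. Secretion is driven by dimensionless
    net signals built from basal-normalized glucose and hormone concentrations
    through Hill functions, hormone export follows a three-pool exocytosis
    model, and islets are coupled to well-mixed chamber mass balances for
    batch (static) and perifusion (continuous-flow) experiments. Includes
    scenario runners (whole-pancreas, type 1 diabetes, cell-type elimination,
    exogenous hormone infusion), constrained multistart least-squares
    parameter estimation, one-at-a-time sensitivity analysis, and a synthetic
    secretion-dataset generator for testing estimation workflows.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
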
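Package: imatpbpk
Title: Physiologically Based Pharmacokinetic Simulation of Imatinib Exposure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A minimal physiologically based pharmacokinetic (PBPK) simulator
    for steady-state imatinib exposure in virtual adult populations. Implements
    saturable alpha-1-acid-glycoprotein plasma protein binding, enzyme-abundance
    scaled hepatic intrinsic clearance (CYP3A4, CYP2C8, biliary efflux), CYP3A4
    autoinhibition via an enzyme turnover model, virtual population and
    virtual-twin generation, one-at-a-time parameter sensitivity sweeps, and
    drug-drug interaction simulations with CYP modulators reported as geometric
    mean ratios. A synthetic patient-cohort generator links simulated exposure
    to clinical outcome labels so the complete analysis pipeline runs without
    external data.
License: MIT + file LICENSE
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
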
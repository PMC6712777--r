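Package: prevadjust
Title: Selection-Bias Adjusted Regional Prevalence Estimation from
    Health-Insurance Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates regional disease prevalence from the member records of
    a single health-insurance fund while adjusting for fund-specific
    selectivity, i.e. systematic morbidity differences between the fund's
    member population and the national population. Region-wise linear mixed
    models with district-level random effects are fitted on aggregated member
    cells by restricted maximum likelihood, and the fitted conditional
    expectation is extrapolated to the national population using national
    auxiliary inpatient-diagnosis frequencies as benchmarks. Includes a
    synthetic-population generator with a controllable membership-selectivity
    mechanism, correlation-based region-wise variable selection, a
    semiparametric bootstrap for confidence intervals, and Monte-Carlo and
    proxy cross-validation harnesses for checking the identifying assumption.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
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
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
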
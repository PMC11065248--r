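Package: ncdsim
Title: Microsimulation of Non-Communicable Disease Burden and Intervention
    Cost-Effectiveness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-level microsimulation of non-communicable disease
    (NCD) burden and intervention cost-effectiveness for the adult (40+)
    population of Gaza. Generates survey-like synthetic populations from
    published sex-stratified marginals, maps individual risk profiles to
    annual incidence hazards for five major NCDs (cardiovascular disease,
    type 2 diabetes, asthma/COPD, breast cancer, colorectal cancer) via
    published risk-score families, calibrates hazards to target ten-year
    incidence and mortality per 10,000, simulates annual cycles with
    competing risks, and accounts discounted disability-adjusted life-years
    (DALYs), intervention costs, incremental cost-effectiveness ratios
    (ICERs) against GDP-based willingness-to-pay thresholds, and
    probabilistic sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rpart,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
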
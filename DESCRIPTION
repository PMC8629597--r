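Package: bmisim
Title: Microsimulation of Fiscal Benefit Policies and Childhood Overweight
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-stage microsimulation linking fiscal benefit policies to
    childhood overweight and obesity. A rule-based benefit engine computes
    counterfactual household disposable incomes on survey-like microdata; a
    chain of seven concatenated linear regressions (gestational age, birth
    weight, infant weights, and BMI at 4, 7 and 10 years) propagates
    log equivalised income through child growth; and a Monte Carlo module with
    parameter and residual uncertainty projects overweight and obesity
    prevalence under counterfactual scenarios using IOTF cut-offs, with
    prevalence ratios, percentile intervals, and cost per percentage-point
    prevalence reduction.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
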
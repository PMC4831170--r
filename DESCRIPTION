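Package: dmecea
Title: Markov Cohort Cost-Utility Modelling of Anti-VEGF Therapy for
    Diabetic Macular Edema
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cohort state-transition (Markov) model for cost-utility
    analysis of intravitreal anti-VEGF regimens in visual impairment due
    to diabetic macular edema, from a third-party payer perspective.
    Health states are two-line bands of best corrected visual acuity
    (ETDRS letters) plus an absorbing death state; the cohort is advanced
    on a 3-month cycle with age-specific background mortality scaled by a
    disease-related relative risk.  The package accumulates discounted
    costs, QALYs and years without visual impairment with a trapezoidal
    half-cycle correction, computes incremental economics (ICER,
    dominance, net monetary benefit), and provides one-way sensitivity
    analysis (tornado), probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, and break-even price search.
    A seeded synthetic-scenario generator supplies internally consistent
    transition schedules, utilities and life tables where published
    sources provide only summary inputs.
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
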
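Package: smartinhale
Title: Budget-Impact and Carbon-Cost Simulation of Smart Reusable Inhalers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for assessing the economic and environmental
    budget impact of sensor-equipped ("smart") reusable soft mist inhalers in
    the treatment of chronic obstructive pulmonary disease (COPD).  Models
    patient inhalation profiles (flow from pressure drop, trapezoidal inhaled
    volume), runs Monte Carlo cohort simulations of inhalation-technique
    acquisition over multi-year training programmes, and projects cohort-level
    production costs and savings in EUR and in Social-Cost-of-Carbon EUR for
    five smart-inhaler deployment policies against a regular reusable-inhaler
    benchmark, including simplified incremental cost-effectiveness
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
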
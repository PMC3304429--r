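Package: axstage
Title: Markov Decision Model for Axillary Staging Strategies in Early Breast Cancer
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A Markov cohort state-transition model comparing a sentinel lymph
    node biopsy (SLNB) based axillary staging strategy against routine axillary
    lymph node dissection (ALND) for early breast cancer. The model follows a
    cohort of women (start age 58) over a 20-year horizon in 1-year cycles
    through disease-free, locoregional recurrence, distant metastasis and death
    states, with half-cycle correction and 5% annual discounting, and reports
    cumulative incidences, life years, quality-adjusted life years (QALYs) and
    Australian health-system costs per 1000 patients. Includes an upfront
    decision tree for staging pathways (true negative, false negative,
    positive-to-ALND, failed-to-ALND), one-way threshold and multiway
    sensitivity analyses, a tornado summary, and an independent patient-level
    microsimulation used to validate the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
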
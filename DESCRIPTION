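Package: mocapsci
Title: Demographically Adjusted MoCA Scores and Prediction of Post-Stroke
    Cognitive Impairment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating Montreal Cognitive Assessment (MoCA)
    performance in acute stroke. Converts raw MoCA totals into
    demographically adjusted scores under three Italian normative datasets
    (Conti, Santangelo, Aiello), classifies performances as impaired or
    normal at each dataset's equivalent-score-zero cut-off, adjudicates
    post-stroke cognitive impairment (PSCI) outcomes from follow-up
    neuropsychological and functional assessments, computes diagnostic
    accuracy of the normative thresholds against mid-term PSCI, fits
    per-point logistic risk models, and derives optimal predictive
    cut-offs by ROC analysis under a sensitivity/specificity adequacy
    rule. Includes a seeded synthetic stroke-cohort simulator with
    informative drop-out so the full pipeline is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
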
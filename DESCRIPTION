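Package: hipmorph
Title: Landmark-Based Hip Morphometry and Radiographic Osteoarthritis Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives alpha angle, lateral centre-edge angle and minimum joint
    space width from 85-point landmark outlines of the proximal femur and
    acetabulum; converts osteophyte areas and height-adjusted joint space
    measures into ordinal grades via ROC-calibrated thresholds; classifies cam,
    pincer and acetabular-dysplasia morphology and radiographic hip
    osteoarthritis; and fits the logistic association suite relating hip
    morphology to osteoarthritis features and hip pain, with repeatability
    statistics (Cohen's kappa, Lin's concordance) and descriptive prevalence
    tables. Includes a synthetic landmark-cohort generator with known geometric
    ground truth and configurable effect sizes so the whole pipeline is
    testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
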
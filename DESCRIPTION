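Package: mcir
Title: Personalized Digital-Twin Quantification of Vaccine Reactogenicity
    from Wearable Biosignals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds per-individual baseline models ("digital twins") of
    multichannel wearable biosignals (heart rate, heart rate variability,
    respiration rate, activity, skin temperature) by similarity-based
    modeling, fuses model residuals into a bounded 15-minute Multivariate
    Change Index of Reactogenicity (MCIR), and summarizes the post-dose
    physiologic response through a 72-hour AUC Total Response and a
    detectable-response classification.  Includes a synthetic-cohort
    generator with circadian, activity-coupled physiology and injectable
    post-dose perturbations, plus a statistical validation layer
    (bootstrap diagnostic performance, rank correlations, robust
    regression, population pre/post summaries).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
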
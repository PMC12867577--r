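Package: calokit
Title: Headless Analysis of Indirect Calorimetry Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for metabolic phenotyping by indirect calorimetry without a
    graphical interface: parsers for several documented text dialects of
    metabolic-cage exports (TSE LabMaster-, CLAMS Oxymax-, Sable-, COSMED-style
    and a CalR-compatible CSV), harmonization of per-animal metadata across
    cohorts, audited data curation (consistency checks, z-score outlier
    removal, trimming, complete-day selection, resampling), reconstruction of
    energy expenditure from respiratory gas exchange via caloric-equivalent
    equations, extraction of resting metabolic rate from low-variability
    segments, substrate oxidation estimates, circadian (zeitgeber-time)
    aggregation, assumption-checked group statistics (ANOVA, ANCOVA and
    generalized linear models with post-hoc correction), standardized export,
    and a seeded synthetic cohort generator with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    car
Suggests:
    testthat (>= 3.0.0),
    xml2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
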
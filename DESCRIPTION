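Package: semconf
Title: Conceptual Structure Statistics and Lesion-Symptom Mapping for
    Semantic Confusability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how damage to anterior temporal lobe
    substructures, in particular the perirhinal cortex, relates to the
    processing of semantically confusable concepts. Computes feature-based
    conceptual structure statistics (distinctiveness, correlational
    strength and the correlation-by-distinctiveness slope) from property
    norms, cosine semantic distance between concepts, per-region lesion
    damage from binary masks and a maximum-probability region atlas, and
    the behavioural statistics of a patient lesion study (mixed ANOVA,
    Welch and paired t tests, item-wise ANCOVA, Fisher-transformed
    per-participant correlations, one-tailed and partial Spearman
    lesion-behaviour correlations). Includes synthetic generators for
    property norms, lesion cohorts and behavioural responses with known
    ground truth, and per-patient summary tables packaged as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti,
    jsonlite
Config/testthat/edition: 3
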
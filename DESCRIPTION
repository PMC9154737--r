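Package: maheitrial
Title: Diet-Quality Scoring, Personalized-Nutrition Advice and Trial Analysis with the m-AHEI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for web-based personalized-nutrition trials built on the
    modified Alternative Healthy Eating Index (m-AHEI), an 11-component
    diet-quality score with each component scored 0-100 by linear
    interpolation between criterion thresholds. Provides criterion-driven
    scoring of food-frequency-questionnaire intake profiles, the
    personalized-advice decision engine (three lowest-scoring components,
    BMI feedback against the 18.5-25.0 kg/m2 healthy range, Baecke physical
    activity feedback), participant-level quality-control filters
    (energy-intake to basal-metabolic-rate plausibility cutoffs, energy
    discrepancy without weight change, unfeasible food-group intakes,
    endpoint-visit selection), baseline-adjusted ANCOVA treatment-effect
    estimation including matched-control subgroup analysis and design-stage
    power calculations, and a fully labelled synthetic-cohort generator for
    end-to-end testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
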
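Package: concussionprofiles
Title: Clinical Profiles, Severity, and Recovery After Sport-Related Concussion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing sport-related concussion in collegiate
    athletes from daily SCAT5 symptom-checklist evaluations. Provides
    severity scoring of the 22-item checklist, rule-based classification of
    six clinical profiles (vestibular, cognitive, fatigue, anxiety/mood,
    headache/migraine, ocular), cohort assembly with inclusion filtering and
    recovery / return-to-play outcome derivation, a synthetic longitudinal
    cohort generator with zero-inflated negative-binomial symptom dynamics
    and nested random effects, and a hierarchical modelling layer (via
    'glmmTMB') linking sex, injury severity, profile counts, and recovery,
    with conditional-effect prediction, variance decomposition, and
    standardized effect sizes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmmTMB,
    stats,
    splines,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    emmeans,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
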
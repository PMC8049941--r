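Package: apiat
Title: Adaptive Pitch Imagery Arrow Task Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and running the adaptive Pitch Imagery Arrow
    Task (aPIAT), an item-response-theory based test of auditory mental
    imagery. Provides automatic generation of pitch-imagery test items
    (tonal context, heard and imagined stepwise arrow walks, match/no-match
    probes), cognitive-model feature extraction, an explanatory
    four-parameter logistic (4PL) response model with difficulty predicted
    from item features, a calibration pipeline (asymptote-profiled mixed
    logistic fitting, random-forest predictor screening, exhaustive BIC
    subset search, cross-validated accuracy), a computerized adaptive
    testing engine (Bayes modal interim estimation, Urry's-rule item
    selection, Warm's weighted-likelihood final scoring), and a respondent
    simulator so that every stage can be exercised without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    ranger,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
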
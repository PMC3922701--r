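Package: toxitext
Title: Dose-Stratified Keyword Mining for Social-Media Toxicosurveillance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mining short free-text social-media comments for
    signs and symptoms of recreational drug exposure, built around the
    dextromethorphan (DXM) dose-plateau model. Provides reproducible keyed
    random sampling of JSON-lines comment corpora, text normalisation and
    stopword removal tuned to internet slang, extraction of dose mentions
    with unit conversion to milligrams, binning of comments into the four
    clinical DXM plateaus, tf-idf keyword extraction treating each plateau's
    pooled text as one document with a 75th-percentile score threshold,
    taxonomy-based path similarity against a clinical symptom lexicon with a
    Yes/Maybe/No medical-relatedness filter, and a two-tailed Mann-Whitney
    comparison against a size-matched control corpus. A synthetic comment
    generator with known ground truth makes every pipeline stage testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    stringr,
    stringi,
    jsonlite,
    igraph,
    ggplot2,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
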
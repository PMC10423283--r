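Package: dyadqc
Title: Quality Control and Agreement Analytics for Crowdsourced Emotion
    Dyad Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and auditing crowdsourced categorical
    annotation campaigns over the eight Plutchik emotion dyads: mapping of
    the 26 EMOTIC emotion labels onto the dyads, balanced image-subset
    selection by per-emotion vote percentage, attention-check session
    validation (control images and a repeated image), per-image
    Fleiss-style kappa with uniform chance agreement and Landis-Koch
    banding, a Z-score vote filter that retains only categories voted at
    or above the per-image mean, and a synthetic annotator simulator with
    wheel-distance projection noise for end-to-end testing and parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
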
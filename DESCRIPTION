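Package: tonetrace
Title: Phonetic and Phono-Lexical Scoring of Lexical Tone Production
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for lexical tone production experiments:
    ingestion and repair of time-normalized F0 trajectories (ProsodyPro-style
    tables, Praat PitchTier files), speaker pitch-range normalization to the
    0-5 T-value scale, discrete cosine transform (DCT) shape coefficients,
    Euclidean tonal distance to target-stimulus centroids, two-cluster
    disambiguation of level-tone contours, categorical scoring of
    picture-naming productions with a tone-only error taxonomy, and a
    seed-reproducible synthetic experiment generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
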
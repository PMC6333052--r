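Package: madsbox
Title: Two-Stage Classification of MIKC-Type MADS-Box Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies plant MADS-box transcription factors into the eight
    floral-organ-identity classes of the extended ABCDE model (A, B12, B34,
    BPI, C, D, E, AGL6). A first stage detects MIKC-type domain architecture
    (MADS, intervening, keratin-like and C-terminal regions) with
    PROSITE-style patterns and a coiled-coil profile; a second stage encodes
    per-class local-alignment similarity, DNA-binding propensity of the M
    domain and coiled-coil probability of the K domain, and routes each query
    to the support-vector model trained on the regions it actually contains.
    Includes a synthetic eight-class family generator, pairwise-distance
    conservation summaries, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    seqinr,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
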
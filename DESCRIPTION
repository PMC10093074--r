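Package: securecnn
Title: Ledger-Secured Layered Networks with Tamper Detection and
    Genetic-Algorithm Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Wraps small layered (convolutional) networks in a per-layer
    ledger: each layer receives a ledger block holding a keyed hash chained
    over parameter deltas, an asymmetric key pair, encrypted copies of layer
    parameters, and signed per-pass transactions stored in a randomized
    central ledger. Parameter or structural tampering is detected, localized
    to the exact layer, and reversed by decrypting the ledger copy. Includes
    a three-severity weight-tampering attack simulator, serial deep-feature
    fusion with mode-value ordering, genetic-algorithm feature selection
    with an entropy-gated Gaussian naive Bayes fitness, pluggable
    classifiers, and fully synthetic image/backbone/feature fixtures so the
    whole pipeline runs hermetically.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    openssl,
    jsonlite,
    png,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
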
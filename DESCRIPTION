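Package: eemdbci
Title: EEMD-Based Motor-Imagery EEG Decoding for Rehabilitation BCIs
Version: 0.1.0
Authors@R:
    person("BCI", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Signal-processing chain for motor-imagery brain-computer
    interfaces used in rehabilitation training: empirical mode
    decomposition (EMD) with the SD sifting-stop criterion, its
    noise-assisted ensemble extension (EEMD), wavelet-packet sub-band
    preprocessing with correlation-based intrinsic mode function
    selection, common spatial pattern (CSP) feature extraction, and a
    regularized quadratic discriminant whose decision threshold caps the
    relaxed-state false-positive rate. Includes seeded generators for
    synthetic two-class motor-imagery EEG with event-related
    desynchronization, plain-text trial readers/writers, and a
    command-line interface covering simulation, decomposition, training
    and classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
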
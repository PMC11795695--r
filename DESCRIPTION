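Package: diasis
Title: Spike-In SILAC Quantification for Data-Independent Acquisition Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of multiplexed DIA-NN precursor reports for
    spike-in SILAC (DIA-SiS) protein quantification. Implements channel
    q-value filtering with a "requantify" rescue rule that admits light
    precursors whenever their heavy spike-in partner is confidently
    identified, light/heavy precursor ratio computation and median rollup to
    protein level, reconstruction of light protein abundances from a global
    heavy reference intensity, anchor-species and run-median normalization,
    differential abundance testing with precision-recall evaluation, and a
    synthetic two-species ground-truth benchmark generator for validating
    the whole pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
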
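Package: hrmelt
Title: Short-Amplicon High-Resolution Melting Assays for DNA Barcode
    Species Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs and evaluates short-amplicon high-resolution melting
    (HRM) assays for distinguishing closely related species from
    mitochondrial mini-barcodes. Classifies alignment columns into fixed
    diagnostic and shared polymorphic sites, predicts amplicon melting
    temperatures by unified nearest-neighbor thermodynamics with salt
    correction, enumerates and ranks candidate primer assays by predicted
    between-species melting-temperature separation, simulates and
    interprets fluorescence melt curves (normalization, Savitzky-Golay
    derivative, peak calling, species assignment), and summarizes
    high-throughput runs as failure / ambiguity / discordance tables. A
    deterministic generator produces mini-barcode alignments and specimen
    cohorts with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
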
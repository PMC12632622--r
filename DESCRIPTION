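Package: poolcomp
Title: Pooled Barcode Competition Analysis for Experimental Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for long-term pooled competition experiments
    with barcoded yeast strains propagated under serial dilution. Simulates
    serial-transfer competitions with drift, adaptive mutation and
    negative-binomial amplicon sequencing noise; extracts, demultiplexes and
    counts strain barcodes from merged amplicon reads; infers per-strain
    selection coefficients and initial frequencies by maximum likelihood
    under a negative-binomial observation model anchored on neutral
    reference barcodes; summarises trajectory dynamics (diversity decay,
    dominant-strain frequency, replicate variability, finalist calling);
    classifies de novo mutations and loss-of-heterozygosity events in
    evolved clones against their ancestors; calls aneuploidies and large
    segmental amplifications from per-base read depth; and scores
    cytometry-based competition fitness, flocculation and ploidy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    readr,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
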
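Package: printmap
Title: Junction Mapping and Microhomology Analysis for R2-Mediated rDNA Transgene Insertion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising transgene-rDNA junctions produced by
    R2 retrotransposon protein mediated insertion (precise RNA-mediated
    insertion of transgenes, PRINT). Provides a target-site and template
    reference model for the 28S rDNA insertion locus, a ground-truth
    simulator of insertion alleles and paired-end reads, read hygiene
    (duplicate removal, quality trimming and filtering), a hierarchical
    local-alignment cascade for split-read mapping, 3' and 5' junction
    detection with mechanistic classification (anneal, join, snap-back,
    extra template, other), microhomology counting with a geometric
    chance model and resampling confidence intervals, join-position
    accounting relative to the first-strand nick, and droplet-digital-PCR
    style copy-number and productive-insertion (PI%) utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
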
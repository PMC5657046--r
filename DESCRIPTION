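Package: mitosplit
Title: Split-Read Detection and Quantification of Mitochondrial DNA
    Deletions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects large deletions in the circular human mitochondrial
    genome from high-throughput sequencing data by mining unaligned and
    clipped reads for recurrent deletion fusion points, and quantifies
    the heteroplasmy level of each call with an exact binomial
    (Clopper-Pearson) confidence interval.  Includes a theoretical
    sensitivity model for experiment design (minimum detectable
    heteroplasmy at a given read budget and mitochondrial enrichment),
    and a paired-end read simulator that mixes intact and deleted
    haplotypes at a chosen heteroplasmy for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rsamtools,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
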
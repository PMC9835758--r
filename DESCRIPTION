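Package: sexscan
Title: Sex-Chromosome Scaffold and Gene Assignment from Sexed Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies genome-assembly scaffolds and genes as X-linked,
    Y-linked or autosomal from male and female whole-genome sequencing
    libraries using the Chromosome Quotient (the female/male normalized
    coverage ratio) in non-overlapping 10 kb windows, and detects Y-linked
    material embedded in chromosome-scale scaffolds through male-unique
    canonical 25-mers merged into Y-unique regions. Includes a fully seeded
    synthetic-data generator that produces assemblies, gene models and sexed
    read sets with known compartment truth, so the entire pipeline is
    testable end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringi,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    seqinr,
    Biostrings,
    Rsamtools,
    rtracklayer,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
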
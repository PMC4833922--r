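Package: primercall
Title: Mapping-Free Primer-Directed Variant Calling for Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls single nucleotide variants and small indels from
    PCR-targeted massively parallel sequencing data with fully overlapping
    read pairs, without mapping reads to a reference genome. Reads are
    assigned to amplicon tiles by exact matching of their 5' gene-specific
    primer prefix against a hash of the panel's primers, compared against
    the expected reference insert by a linear scan with a gapped
    (Needleman-Wunsch style, affine gap) fallback, and variants are
    reported only when they occur identically on both reads of a pair and
    exceed absolute and proportional pair-count thresholds. Optional
    G-test genotyping of SNVs under a constant-error model, VCF and
    per-amplicon coverage output, and a self-contained panel/read
    simulator with truth sets are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    S4Vectors,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
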
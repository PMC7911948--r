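Package: mitograph
Title: Graph-Based Binary Interpretation of Mitochondrial DNA Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitation-free (binary) interpretation of mitochondrial DNA
    mixtures using epsilon-node variation graphs. A mixture profile given as
    EMPOP-style variant calls (with IUPAC ambiguity codes) is compiled into a
    directed acyclic graph whose source-to-sink paths spell exactly the
    haplotypes compatible with the mixture, in a way that is invariant to
    variant-calling and alignment conventions. Single-source haplotypes are
    tested for consistency (non-exclusion) by string-to-graph matching, and
    haplotype sets are tested for exact explanation (joint node and edge
    coverage), supporting the random-man-not-excluded statistic and
    likelihood-based match statistics over a population haplotype database,
    with exact Clopper-Pearson finite-database corrections. Includes a
    simulator for synthetic haplotype databases and in silico two-person
    mixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    readr,
    ggplot2,
    jsonlite,
    igraph,
    generics,
    stats,
    Biostrings,
    BiocGenerics,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
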
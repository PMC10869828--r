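Package: chemomine
Title: Chemoreceptor Gene Family Mining and Phylogenetic Loss Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines vertebrate genome assemblies for the six chemoreceptor
    G-protein-coupled receptor gene families (OR, TAAR, V1R, V2R, T1R and
    T2R) with dedicated single-exon and multi-exon procedures: translated
    homology search with Karlin-Altschul E-values, best-hit region merging
    and flank extension, ORF extraction, exon-count inference and spliced
    gene-model chaining, loss-of-function (premature stop and frameshift)
    detection, and five-way gene-status classification (complete,
    pseudogene, truncated, edge, ambiguous). Downstream comparative tools
    infer gene-loss branches on a phylogeny from shared loss-of-function
    mutations, count independent losses per branch category with an
    intact-branch correction, test associations with contingency tests and
    a sequential branch-drawing loss simulation, simulate shared missing
    genes, and fit phylogenetic generalized least squares regressions with
    Pagel's lambda. Synthetic-genome and synthetic-tree generators provide
    ground truth for benchmarking every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nlme,
    rtracklayer,
    MASS
Config/testthat/edition: 3
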
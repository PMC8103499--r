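Package: dupevol
Title: Duplicated-Gene Evolution Analysis for Allopolyploid Species Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, seed-reproducible pipeline for studying the evolution of
    whole-genome-duplication (WGD) and small-scale-duplication (SSD) derived
    gene duplicates in an allotetraploid species complex with a diploid
    outgroup. Chains homolog anchors into collinear synteny blocks, classifies
    genes into the duplicate-gene taxonomy (singleton/doublet/triplet
    orthogroups; tandem, proximal, transposed, dispersed and segmental SSD
    modes; conserved-eudicot and ancient-collinear genes; lineage-specific
    families), computes per-gene population-genetic statistics (nucleotide
    diversity, absolute divergence, Nei-Gojobori dN/dS, depth-based gene
    presence), quantifies gene-body cytosine methylation from per-cytosine
    bisulfite counts and calls differentially methylated genes with a
    stratified Cochran-Mantel-Haenszel procedure, and summarises class-wise
    contrasts, subgenome asymmetry and biased fractionation. A synthetic
    allopolyploid-complex data generator with full truth tables makes every
    stage verifiable at desk scale.
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
    readr,
    stringr,
    ggplot2,
    generics,
    yaml,
    igraph,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR,
    rtracklayer,
    Biostrings,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
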
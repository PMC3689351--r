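Package: mtprov
Title: Mitochondrial DNA Haplotype Analysis for Triangulating Wildlife Provenance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for inferring the geographic provenance of wildlife samples
    from mitochondrial DNA sequence alignments, motivated by forensic
    assignment of African elephant ivory. Collapses aligned mtDNA sequences
    into unique haplotypes, derives and applies hierarchical diagnostic-site
    keys for clade and subclade classification, computes geographic
    specificity statistics and locality haplotype-sharing matrices, estimates
    pairwise haplotype-frequency F_ST with permutation significance tests,
    builds median-joining haplotype networks, and combines nuclear assignment
    tables with mtDNA evidence to triangulate sample origins. Includes a
    simulator of matrilocal mtDNA datasets with planted clade/subclade
    structure and discordant nuclear assignments for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'alignment-io.R'
    'diagnostic-key.R'
    'differentiation.R'
    'geo-specificity.R'
    'haplotypes.R'
    'mj-network.R'
    'mtprov-package.R'
    'simulate.R'
    'triangulation.R'
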
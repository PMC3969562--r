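Package: popcontent
Title: Genome Content, Linkage Scaffolding, and Functional Variation in
    Yeast Populations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for population-scale analysis of budding yeast genome
    resequencing studies: ordering and orienting de novo assembly scaffolds
    into linkage groups from advanced-intercross segregant genotypes using
    linkage disequilibrium decay, detecting pairwise presence/absence genome
    content variation between assemblies, synteny-guided transfer of
    reference ORF annotation, windowed read-depth copy number analysis with
    gene-family aggregation and subtelomeric enrichment, classification of
    loss-of-function variants (premature stops and frameshifting indels)
    with equivalent-indel-region handling, derived-allele polarization and
    selection statistics, and copy-number-phenotype association. A fully
    specified synthetic-data generator produces phylogenetically structured
    strain populations, intercross segregants, coverage tracks and
    phenotypes with machine-readable ground truth so every stage can be
    exercised and scored without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    Biostrings,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer
Config/testthat/edition: 3
biocViews: Genetics, Sequencing, CopyNumberVariation, VariantAnnotation,
    Alignment
RoxygenNote: 7.3.3
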
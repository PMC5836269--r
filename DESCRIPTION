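Package: musselkit
Title: Genome Profiling, Assembly Statistics, Gene-Model Curation and
    Protein-Domain Expansion Analysis for Bivalve Genome Projects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable implementations of the downstream computations of a
    bivalve (golden mussel) genome project: k-mer-spectrum genome profiling
    (error threshold, heterozygous and homozygous coverage peaks, genome
    size, heterozygosity rate, ploidy call), assembly contiguity summaries
    (N50 and the usual scaffold statistics) and BUSCO percentage
    arithmetic, the four-filter curation cascade that distils
    transcript-based gene models into an ab initio training set, and a
    Poisson cumulative-tail test with Bonferroni control for protein-domain
    family expansion and contraction across genomes, with log2-ratio
    matrices and complete-linkage clustering. Includes synthetic-data
    generators with recorded ground truth so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Genetics, GenomeAssembly, Annotation, Clustering, StatisticalMethod
RoxygenNote: 7.3.3
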
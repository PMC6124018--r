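Package: hybridseer
Title: Hybrid Genome Diagnostics from K-mer Spectra, Gene Phasing, Variome
    Distances and S-Locus Haplotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Diagnostics for inter-specific plant hybrids from short-read
    resequencing data: canonical k-mer spectrum construction with
    heterozygous/homozygous peak fitting and genome-size estimation,
    parent-of-origin phasing of genes from parental read support at
    diagnostic SNPs, multi-sample variome summaries (heterozygous and
    homozygous SNP counts, InDels, Ti/Tv) with allele-sharing distances,
    classical multidimensional scaling and neighbor-joining trees, and
    S-locus (S-RNase/SFB) haplotype classification with gametophytic
    self-incompatibility checks. Includes a synthetic diploid F1/backcross
    genome and read simulator with ground-truth tracking used to validate
    every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    ape,
    igraph,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
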
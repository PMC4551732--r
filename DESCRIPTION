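Package: lepcompgen
Title: Comparative Genomics of Highly Heterozygous Lepidoptera Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative analysis of highly heterozygous
    butterfly genomes: 17-mer frequency histograms and heterozygosity peak
    detection, coverage-based haplotig identification and merging into
    primary scaffolds, diploid-region SNP-rate profiling with windowed
    tracks and one- versus two-component Gaussian mixture fits,
    synonymous/non-synonymous classification, per-protein substitution
    enrichment with binomial tests and Benjamini-Hochberg FDR, GO-term
    enrichment and cross-species combination, a gene-order rearrangement
    phylogeny built from four-state relative-orientation characters with a
    BioNJ tree and majority-rule consensus machinery, and an ortholog
    family expansion test. A synthetic-data module generates diploid
    genomes, reads, split assemblies, evolved gene orders and substitution
    profiles with known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    BiocGenerics,
    dplyr,
    generics,
    ggplot2,
    igraph,
    IRanges,
    phangorn,
    Rcpp,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
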
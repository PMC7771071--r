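Package: gameteBinning
Title: Haplotype Phasing, Genetic Mapping and Long-Read Binning from
    Single-Cell Gamete Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Phases a heterozygous diploid genome into its two haplotypes
    using hundreds of sparsely sequenced haploid gamete genomes. Selects
    heterozygous SNP markers by allele-frequency and depth filters,
    classifies marker-free regions into haplotype-specific (deletion) and
    conserved regions, genotypes individual gametes, screens for doublet
    nuclei by genotype-transition rates, phases SNPs along contigs by
    bi-marker majority voting, builds a gamete-derived genetic map from
    two-point LOD linkage of imputed contig-end markers, detects meiotic
    crossovers by segmenting per-gamete haplotype calls, separates long
    reads into per-haplotype, per-linkage-group bins using phased alleles,
    and validates haplotyping precision with parent-specific k-mers. A
    synthetic-data module generates diploid genomes, recombinant gametes,
    sparse observations, doublets and haplotype-tagged long reads with full
    ground truth for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    igraph,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
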
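# gameteBinning

Haplotype phasing, genetic mapping, crossover detection and long-read
binning from high-throughput single-cell sequencing of haploid gametes.

## The problem

Standard assemblies of a heterozygous diploid collapse the two homologous
chromosomes into one artificial consensus. *Gamete binning* resolves both
haplotypes without parents or progeny: hundreds of gamete nuclei are
sequenced very sparsely (~0.3x each), and because every gamete is a
haploid recombinant of the two parental haplotypes, the co-segregation of
alleles across gametes phases all heterozygous markers genome-wide. The
phased markers then (i) order and orient assembly contigs into linkage
groups via a gamete-derived genetic map and (ii) split whole-genome long
reads into 2 × (number of chromosomes) haplotype-specific bins for
independent assembly.

The core statistics are classical haploid-population genetics. Two-point
linkage between marker genotype sequences over gametes uses the LOD score

    LOD = NR·log10(2(1−r)) + R·log10(2r),    r = R/(R+NR),

with linkage groups as connected components at LOD > 3, Haldane map
distances d = −50·ln(1−2r) cM, and per-contig phase values that flip a
contig's genotype sequence into the group-wide haplotype convention.
Crossovers are haplotype switches between supported marker blocks in a
single gamete, and the recombination landscape in a window of size *w* is
100·*C*/*n*/(*w*/10⁶) cM/Mb for *C* recombinant gametes among *n*.
Haplotyping precision is validated reference-free by intersecting
assembly-specific canonical k-mers with parent-specific k-mer sets.

A first-class synthetic-data module simulates the diploid genome,
recombinant gametes, sparse noisy observations, doublet nuclei and
haplotype-tagged long reads with full ground truth, so the whole pipeline
is testable as a parameter-recovery problem.

## Worked example

```r
library(gameteBinning)

cfg <- simulationConfig(seed = 7, nReads = 2000)  # 2 chromosomes x 1 Mb,
res <- runGameteBinning(cfg)                      # 200 gametes at 0.3x

res$map
#> GeneticMap: 2 linkage group(s), 28 markers, 14 contigs
#>   total length: 200.1 cM (LG1: 89.2, LG2: 110.9)

length(res$doublets)                     # nuclei flagged by the 5/100
#> [1] 9                                  # transition screen and excluded

res$evaluation$evidence                  # how each long read was binned
#> deletion   random snp_vote
#>       44      100     1856

100 * res$evaluation$snpVotePrecision    # SNP-informative reads assigned
#> [1] 100                                # to their true haplotype (%)

res$evaluation$lambdaHat                 # recovered crossovers per gamete
#> [1] 0.94                               # per chromosome (simulated: 1.0)

head(res$crossovers[, c("gamete", "group", "leftPos", "rightPos")], 3)
#>      gamete group leftPos rightPos
#> 1 gamete001   LG1  604549   631333
#> 2 gamete003   LG1   79466    93474
#> 3 gamete004   LG1   24586    27994
```

The map recovers one linkage group per simulated chromosome; the total
genetic length (~100 cM per chromosome) matches the simulated one
crossover per gamete per chromosome; the binned reads split into SNP-vote
evidence (phased alleles on the read), deletion evidence (presence of a
haplotype-specific region) and random assignment inside conserved
regions, with every SNP-informative read landing on its true haplotype.

Individual stages are exported — `selectSnpMarkers()`,
`buildGenotypeMatrix()`, `phaseAllContigs()`, `screenPloidy()`,
`imputeVirtualMarkers()`, `buildGeneticMap()`, `segmentAndCall()`,
`binReads()`, `countKmers()`/`haplotypingPrecision()` — and a thin CLI
over them lives in `inst/scripts/gamete-binning.R`
(`simulate`, `select-markers`, `phase`, `screen-ploidy`, `build-map`,
`detect-co`, `bin-reads`, `kmer-precision`).

See `vignettes/gamete-binning-methods.Rmd` for the model, parameter and
design documentation.

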
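---
title: "Phasing and binning with gamete genomes: methods and design notes"
author: "gameteBinning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasing and binning with gamete genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gameteBinning)
```

# The problem

A heterozygous diploid genome carries two haplotypes that ordinary
assemblies collapse into one artificial consensus. Gamete binning avoids
this by exploiting meiosis itself: each gamete (pollen nucleus, sperm
cell) carries one haploid recombinant of the two parental haplotypes.
Sequencing hundreds of gametes very sparsely is enough to (i) phase every
heterozygous marker into two genome-wide haplotypes, (ii) build a genetic
map that orders and orients assembly contigs into chromosome-scale
linkage groups, and (iii) separate whole-genome long reads into
2 x (number of chromosomes) haplotype-specific bins that can be assembled
independently.

This package implements the analytical core of that workflow along with a
synthetic-data generator that produces all inputs with known truth, so
every stage can be tested as a parameter-recovery problem.

# The pipeline, stage by stage

## Marker selection

Candidate heterozygous SNPs come from pooled gamete alignments (a VCF
with site depth and allele depth). A candidate is kept iff

* alternative allele frequency in [0.38, 0.62],
* alternative allele depth in [60, 140] reads,
* total depth in [120, 280]x,

all bounds inclusive. The two depth bands are meaningful relative to the
pooled mode depth they were derived from (208x); `rescaleDepthBounds()`
scales them proportionally to the mode depth of the data at hand, which
is what `runGameteBinning()` does for synthetic data. All band edges are
inclusive, matching the inclusive reading used for the deletion depth
ceiling below.

Regions longer than 2 kb without any SNP marker are either *conserved*
(identical between haplotypes) or *deletions* (present in one haplotype
only). The two cases separate cleanly on pooled depth: a deletion region
is covered by roughly half the reads. The classifier is a single
inclusive threshold (default 146x against a 208x mode — the valley
between the half-coverage and full-coverage peaks of the depth
histogram); `depthValley()` recomputes that valley from data but is
advisory and never silently applied.

## Genotyping single gametes

At ~0.3x depth most markers in a gamete are covered by zero or one read.
`callSnpGenotype()` calls the single observed allele, `N` with no reads,
and resolves conflicting reads by majority only when
majority/minority >= 3 (the dominance ratio; conflicts below it give
`N`). The rule is this package's own choice — upstream callers leave the
handling of intra-gamete conflicts unspecified — and it is deliberately
conservative: at these depths a conflicted site is more likely barcode
noise than signal.

Deletion markers are genotyped by presence/absence of reads in the
region, with RPKM recorded (reads per kb per million mapped).

## Doublet screening

Two nuclei under one barcode look like a diploid mixture of two
recombinants. After phasing, a true haploid switches haplotype along a
chromosome only at genuine crossovers (a few per genome) plus isolated
genotyping errors, while a doublet switches wherever its two constituent
gametes differ. `screenPloidy()` counts inter-genotype transitions
between consecutive non-missing phased calls within each contig and
labels a gamete a doublet when transitions exceed 5 per 100 covered
markers (strict, per "more than"). We use this explicit ratio as a
deterministic rule rather than clustering transition counts against
covered markers, trading a data-adaptive boundary for reproducibility.
The rule presumes marker-dense data: with very few markers per
chromosome, legitimate crossovers alone can push a haploid over the
threshold, so the test genomes keep marker counts realistic. Gametes
with fewer than 30 covered markers are labeled haploid-with-warning
rather than trusted either way.

Because screening needs phased calls and phasing is more robust without
doublets, the pipeline phases twice: once with all gametes to screen,
then again excluding flagged doublets.

## Phasing along contigs

"Bi-marker majority voting" is implemented as adjacent-pair
co-segregation chaining: for each pair of adjacent markers, gametes with
both calls non-missing vote S (same raw symbol at both) against D
(different); the second marker keeps the first's orientation when S >= D
and flips otherwise. Chaining walks the contig once; the first marker is
+1 by convention, so the solution is defined up to a global flip — which
is all meiosis can ever tell us. Ties (S = D) carry the previous
orientation and are flagged. This greedy chain is guaranteed to attain
the global maximum of the pairwise-agreement objective (each adjacency is
optimised independently given the chain), and the test suite checks that
equivalence against exhaustive search over all orientation assignments on
small contigs.

## Virtual markers and the genetic map

Each contig contributes two *virtual markers* — the imputed gamete
genotypes at its head and tail, taken as the consensus symbol of the
first and last supported block of each gamete's haplotype string (the
same minimum-support segmentation as the crossover caller, so an
isolated error at a contig end does not leak into the map). An `aa`/`bb`
head–tail pair means no crossover on the contig for that gamete;
`ab`/`ba` means one inside.

Two-point linkage between genotype sequences is computed as in a haploid
mapping population: over gametes informative for both markers, R
recombinant vs NR non-recombinant, with the counts swapped (and the flip
recorded) when raw R > NR, r = R/(R+NR), and

LOD = NR log10(2(1-r)) + R log10(2r),  LOD = (R+NR) log10 2 when R = 0.

Linkage groups are connected components of the graph with edges at
LOD > 3 (strict). The two ends of a contig are forced into one group
(the one with the stronger edge) with a warning when they disagree.
Within a group, contig orientations (phase values 0/1) propagate along a
maximum-LOD spanning tree using the recorded flips; marker order comes
from greedy nearest-neighbour seriation seeded at the max-LOD pair,
refined by 2-opt on the sum of adjacent recombination fractions, and cM
positions accumulate Haldane distances d = -50 ln(1 - 2r), capped at
50 cM. Haldane rather than Kosambi because the simulator draws
crossovers without interference; the mapping function is exposed should
interference matter for real data. The proprietary regression-mapping
workflow this replaces (including its goodness-of-fit-jump removal and
two-round strategy) is out of scope; the seriation is guarded by
exhaustive-search oracles for groups of up to eight markers.

End markers with more than 10% missing gametes are dropped before
grouping (applying the filter before rather than after grouping is a
choice; the alternative is not better determined and the filter exists
to keep noisy ends from distorting the map).

Deletion markers integrate afterwards by minimum divergence: mismatches
over informative overlaps against every placed marker's oriented
sequence, minimised over both phases; placement requires divergence
<= 0.1 and >= 30 informative gametes. A gamete with zero reads in a
deletion region is recoded from `n` to `b` (the deleted haplotype) only
when its depth made >= 2 reads expected there — absence of evidence is
evidence of absence only when evidence was expected.

## Crossover calling

Per gamete and linkage group, the haplotype call string (missing calls
removed) is segmented into blocks of at least `minSupport = 5` markers;
one crossover is emitted between each pair of consecutive surviving
blocks, localised to the interval between the last marker of the left
block and the first of the right (interval length = resolution; the
midpoint is the point estimate). The segmentation is an exact dynamic
program: minimise relabeled markers subject to every block holding at
least `minSupport` markers, breaking ties by fewest blocks and then by
label. This makes the caller literally the optimum that the brute-force
oracle in the tests enumerates, and avoids the order-dependence of
absorbing short blocks greedily. Isolated flips — the signature of
genotyping error — are absorbed, never called as double crossovers. The
support threshold is configurable and reported in output headers; 5
markers balances error robustness against resolution at 0.3x coverage.

The recombination landscape counts, per sliding window (500 kb window,
50 kb step), the number C of distinct gametes with a crossover midpoint
inside, and reports 100 C / n / (w/10^6) cM/Mb, with SNP and gene
densities as counts per Mb over the same windows. Events from gametes at
or below 0.1x depth are excluded (strict) before landscape computation.

Non-allelic crossovers (between rearranged, non-homologous regions)
produce duplications visible as pseudo-heterozygosity plus elevated
coverage; `nonAllelicDiagnostics()` reports both per gamete but no
automated caller is attempted.

## Long-read binning

A read's best alignment carries substitutions relative to the assembly
(cs difference string). Three cases, in priority order:

1. **SNP votes**: at every phased marker the read covers, its base (the
   substitution base, or the reference base when no substitution is
   recorded) votes for the haplotype carrying that allele; majority
   wins; ties break at random (seeded). Bases matching neither allele
   abstain. An optional purity threshold can demote mixed-vote reads.
2. **Deletion**: no SNP votes but overlap with a placed deletion region
   assigns the read to the haplotype possessing the region (a read from
   the other haplotype could not align there — it lacks the sequence).
3. **Conserved**: overlap with only conserved regions assigns uniformly
   at random, keeping both bins complete for assembly.

Reads on unplaced contigs stay unassigned. Votes are unweighted (base
qualities are not modelled); each read is assigned once, from its best
alignment only.

## k-mer validation

Haplotyping precision is measured without truth alignments: canonical
k-mers (k = 21) specific to each haplotype assembly are intersected with
k-mers specific to each parent of the focal individual. Parent-specific
sets take k-mers in the parent's reads at 10–60x, absent from the other
parent (a single stray observation is tolerated as sequencing error —
"coverage over 1x" is read as count >= 2 disqualifies), and present in
the focal read set at 10–300x. Precision of a haplotype is the matched
parent's share of its parent-specific k-mers, the parent pairing chosen
to maximise the average. Counting is an in-memory canonical hash; no
external k-mer tool is required, and agreement with one is a test-level
concern, not a dependency.

# The synthetic-data generator

`simulationConfig()` defaults describe the desk-scale study conditions:
2 chromosomes x 1 Mb, one SNP per 500 bp of SNP territory, 10% of the
genome in deletion regions and 10% conserved (placed inside contigs, 10–
30 kb each), contigs of ~150 kb mean, 200 gametes at 0.3x (log-normal
depth factor, sd(log) = 0.5, emulating the heavy-tailed per-cell depth
of droplet libraries), 0.5% per-read genotyping error, 5% doublets
(pooled observations of two independent gametes), Poisson crossovers at
lambda = 1 per chromosome per gamete placed uniformly (no interference;
an optional minimum-distance knob exists but the method under test does
not depend on interference), and 10,000 long reads of ~15 kb. Deletion
false-positive reads arrive at Poisson(0.05) per region to exercise the
presence/absence genotyper.

What the generator deliberately does **not** emulate: indel and
structural sequencing errors in long reads (substitution flips at
markers only), chimeric reads, barcode collisions beyond simple gamete
pooling, reference bias, repeat-induced mismapping, and organellar
contamination. Passing the recovery tests therefore shows the
*algorithms* are correct under the stated noise model, not that the
pipeline is robust to every artefact of real libraries; the unassigned
fraction on real data (organelles, repeats) has no synthetic
counterpart.

# Numerical and degenerate-input choices

* Internal containers are `GRanges`/`IRanges`, hence 1-based closed
  coordinates throughout the package; PAF (0-based half-open) is
  converted at the reader/writer boundary only. One convention inside,
  conversions at the edge.
* LOD with no informative gametes is 0 and r undefined; uninformative
  pairs inside a group are joined at the 50-cM Haldane cap with a
  warning.
* Haldane distances cap at 50 cM for r >= 0.5 - 1e-6.
* Segmentation with fewer observed markers than the support threshold
  returns one majority block (no crossover can be supported).
* Single-marker contigs phase trivially (+1, no adjacencies); empty
  inputs yield empty, well-typed outputs everywhere.
* Zero-depth SNP candidates are rejected with an explicit reason; zero
  total mapped reads leave RPKM undefined but the presence call intact.
* Tie-breaks are deterministic wherever randomness is not meaningful
  (seriation: higher LOD then lexicographic id; segmentation: fewer
  blocks then label `a`); the two genuinely arbitrary choices — vote
  ties and conserved-region assignment — use the seeded RNG.

# Problem sizes in the tests

The test suite runs the full pipeline at the default conditions once
(shared fixture) and at reduced sizes for targeted properties: ideal-data
recovery on 2 x 300 kb with 80 gametes at 2x, the eight-chromosome
grouping property on 8 x 300 kb with 200 gametes, doublet screening on
3 x 200 kb at 0.5x, and read-noise robustness on 1 x 500 kb. These sizes
were chosen so each property is measured where its signal is clear —
e.g. enough contigs per group for a meaningful order correlation, enough
markers per chromosome that genuine crossovers stay far from the doublet
threshold.

# Known limitations

* Grouping quality degrades when chromosomes are so short (or lambda so
  high) that a single contig spans an appreciable genetic length; the
  contig-end coupling then relies on the forced-merge rule and its
  warning.
* The genetic map orders contig *ends*; markers of neighbouring ends at
  r ~ 0 may interleave, which is irrelevant for binning (contig-level
  phase and group are what matter) but means order indices are not a
  strict contig permutation.
* The deletion genotyper's `b`-inference depends on a depth estimate per
  gamete (from marker detection rates); at very low coverage the
  expected-read threshold of 2 leaves most absences uninformative, and
  deletion markers then place only by their `a` pattern.
* Precision evaluation matches haplotype labels per linkage group, as
  the labels are intrinsically arbitrary; a systematic within-group
  phase switch would surface as low precision, but a whole-group swap is
  undetectable and scientifically meaningless.
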
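## Shared fixtures. The default-conditions pipeline run is expensive, so it
## is computed once per test session and reused by the property tests.

.fixtureEnv <- new.env(parent = emptyenv())

defaultRun <- function() {
  if (is.null(.fixtureEnv$run)) {
    cfg <- simulationConfig(seed = 101, nReads = 2000)
    .fixtureEnv$run <- runGameteBinning(cfg)
  }
  .fixtureEnv$run
}

## a phased GenotypeMatrix on one contig built directly from symbols
phasedFixture <- function(callMatrix, contig = "ctg1") {
  gr <- GenomicRanges::GRanges(contig,
    IRanges::IRanges(seq_len(nrow(callMatrix)) * 100L, width = 1L))
  names(gr) <- sprintf("%s_m%d", contig, seq_len(nrow(callMatrix)))
  GenomicRanges::mcols(gr)$kind <- "snp"
  GenomicRanges::mcols(gr)$ref <- "A"
  GenomicRanges::mcols(gr)$alt <- "C"
  GenotypeMatrix(callMatrix, gr, phased = TRUE)
}

## random R/A/N matrix for phasing property tests
randomRawCalls <- function(nMarkers, nGametes, missing = 0.2) {
  m <- matrix(sample(c("R", "A"), nMarkers * nGametes, replace = TRUE),
              nMarkers, nGametes,
              dimnames = list(sprintf("m%d", seq_len(nMarkers)),
                              sprintf("g%d", seq_len(nGametes))))
  m[matrix(runif(length(m)) < missing, nrow(m))] <- "N"
  m
}

## midpoint of a called crossover expressed in chromosome coordinates,
## inverting the map-order pseudo-coordinate construction
.pseudoToChrom <- function(event, entries, truth) {
  eg <- entries[entries$linkage_group == event$group, ]
  eg <- eg[order(eg$order_index), ]
  ctgOrder <- unique(eg$contig)
  offset <- 0
  for (cn in ctgOrder) {
    info <- truth$contigs[truth$contigs$contig == cn, ]
    if (event$midpoint <= offset + info$length) {
      within <- event$midpoint - offset
      ends <- eg$end[eg$contig == cn]
      if (length(ends) && ends[1] == "tail")   # contig reversed in map
        within <- info$length - within + 1
      return(info$start + within - 1)
    }
    offset <- offset + info$length
  }
  NA_real_
}
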
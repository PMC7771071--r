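test_that("a fixed seed reproduces the simulation exactly", {
  cfg <- simulationConfig(seed = 42, nChromosomes = 1,
                          chromosomeLength = 2e5, nGametes = 30,
                          nReads = 100)
  run <- function() {
    t <- simulateGametes(simulateDiploid(cfg))
    list(obs = simulateObservations(t), reads = simulateLongReads(t),
         snps = t$snps, co = t$gametes$co)
  }
  a <- run(); b <- run()
  expect_identical(a$snps, b$snps)
  expect_identical(a$co, b$co)
  expect_identical(a$obs$snpObs, b$obs$snpObs)
  expect_identical(a$reads$alignments, b$reads$alignments)
})

test_that("SNP rate zero yields zero SNP markers with a warning", {
  cfg <- simulationConfig(seed = 1, nChromosomes = 1,
                          chromosomeLength = 1e5, snpRate = 0)
  expect_warning(truth <- simulateDiploid(cfg, makeSequences = FALSE),
                 "zero SNP")
  expect_equal(nrow(truth$snps), 0L)
})

test_that("SNP counts follow the configured rate (Poisson 3-sigma)", {
  cfg <- simulationConfig(seed = 11, nChromosomes = 1,
                          chromosomeLength = 1e6, snpRate = 1 / 500,
                          deletionFraction = 0, conservedFraction = 0)
  truth <- simulateDiploid(cfg, makeSequences = FALSE)
  expected <- 1e6 / 500
  expect_lt(abs(nrow(truth$snps) - expected), 3 * sqrt(expected))
})

test_that("deletion regions cover about the configured genome fraction", {
  cfg <- simulationConfig(seed = 5, nChromosomes = 2,
                          chromosomeLength = 1e6, deletionFraction = 0.1)
  truth <- simulateDiploid(cfg, makeSequences = FALSE)
  total <- sum(truth$deletions$end - truth$deletions$start + 1)
  frac <- total / sum(truth$chromLengths)
  expect_gt(frac, 0.08)
  expect_lt(frac, 0.13)
  ## deletion regions never overlap conserved regions on the same chrom
  for (ch in names(truth$chromLengths)) {
    d <- truth$deletions[truth$deletions$chrom == ch, ]
    cv <- truth$conserved[truth$conserved$chrom == ch, ]
    if (nrow(d) && nrow(cv))
      for (i in seq_len(nrow(d)))
        expect_false(any(d$start[i] <= cv$end & d$end[i] >= cv$start))
  }
})

test_that("lambda 0 gives intact parental haplotypes per chromosome", {
  cfg <- simulationConfig(seed = 2, nChromosomes = 2,
                          chromosomeLength = 2e5, nGametes = 40, coMean = 0)
  truth <- simulateGametes(simulateDiploid(cfg, makeSequences = FALSE))
  expect_equal(nrow(truth$gametes$co), 0L)
  for (ch in names(truth$chromLengths)) {
    h <- truth$gametes$snpHap[truth$snps$chrom == ch, , drop = FALSE]
    expect_true(all(apply(h, 2, function(x) length(unique(x)) == 1L)))
  }
})

test_that("crossover counts match the Poisson mean (3-sigma band)", {
  cfg <- simulationConfig(seed = 3, nChromosomes = 1,
                          chromosomeLength = 2e5, nGametes = 400,
                          coMean = 1.5, snpRate = 1 / 2000)
  truth <- simulateGametes(simulateDiploid(cfg, makeSequences = FALSE))
  meanCo <- nrow(truth$gametes$co) / 400
  expect_gt(meanCo, 1.35)
  expect_lt(meanCo, 1.65)
})

test_that("two crossovers produce a double recombinant mosaic", {
  ## mosaic construction is deterministic given breakpoints: check that
  ## haplotype flips at each recorded crossover
  cfg <- simulationConfig(seed = 9, nChromosomes = 1,
                          chromosomeLength = 2e5, nGametes = 50, coMean = 2)
  truth <- simulateGametes(simulateDiploid(cfg, makeSequences = FALSE))
  co <- truth$gametes$co
  snp <- truth$snps
  for (g in unique(co$gamete)[1:10]) {
    bp <- sort(co$pos[co$gamete == g])
    h <- truth$gametes$snpHap[, g]
    segs <- findInterval(snp$chromPos, bp)
    for (s in unique(segs)) {
      expect_equal(length(unique(h[segs == s])), 1L)
      if (s > 0 && any(segs == s - 1L))
        expect_false(h[segs == s][1] == h[segs == s - 1L][1])
    }
  }
})

test_that("with zero error observed alleles equal the gamete truth", {
  cfg <- simulationConfig(seed = 4, nChromosomes = 1,
                          chromosomeLength = 2e5, nGametes = 50,
                          errorRate = 0, doubletFraction = 0)
  truth <- simulateGametes(simulateDiploid(cfg, makeSequences = FALSE))
  obs <- simulateObservations(truth)
  si <- match(obs$snpObs$marker, truth$snps$id)
  gi <- match(obs$snpObs$gamete, truth$gametes$ids)
  hasAlt <- truth$gametes$snpHap[cbind(si, gi)] ==
    ifelse(truth$snps$altInA[si], "A", "B")
  expect_true(all(obs$snpObs$altCount[hasAlt] > 0))
  expect_true(all(obs$snpObs$refCount[hasAlt] == 0))
  expect_true(all(obs$snpObs$altCount[!hasAlt] == 0))
})

test_that("marker detection fraction matches 1 - exp(-coverage)", {
  cfg <- simulationConfig(seed = 6, nChromosomes = 1,
                          chromosomeLength = 5e5, nGametes = 100,
                          coverage = 0.1, depthSdLog = 0,
                          doubletFraction = 0)
  truth <- simulateGametes(simulateDiploid(cfg, makeSequences = FALSE))
  obs <- simulateObservations(truth)
  p <- 1 - exp(-0.1)
  cells <- nrow(truth$snps) * 100
  frac <- nrow(obs$snpObs) / cells
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / cells))
})

test_that("doublet count follows the configured fraction", {
  cfg <- simulationConfig(seed = 8, nChromosomes = 1,
                          chromosomeLength = 2e5, nGametes = 200,
                          doubletFraction = 0.1)
  truth <- simulateGametes(simulateDiploid(cfg, makeSequences = FALSE))
  obs <- simulateObservations(truth)
  n <- sum(obs$doublet)
  expect_lt(abs(n - 20), 3 * sqrt(200 * 0.1 * 0.9) + 1)
})

test_that("long reads carry their haplotype's alleles and avoid foreign deletions", {
  cfg <- simulationConfig(seed = 10, nChromosomes = 1,
                          chromosomeLength = 3e5, nReads = 300,
                          readLength = 15000)
  truth <- simulateGametes(simulateDiploid(cfg))
  reads <- simulateLongReads(truth)
  a <- reads$alignments
  s <- reads$substitutions
  ## substitutions are exactly the alt alleles of the read's haplotype
  si <- match(paste(a$contig[match(s$readId, a$readId)], s$tpos + 1L),
              paste(truth$snps$contig, truth$snps$pos))
  expect_false(anyNA(si))
  hap <- a$hapOrigin[match(s$readId, a$readId)]
  expect_true(all(truth$snps$altInA[si] == (hap == "A")))
  expect_true(all(toupper(s$readBase) == truth$snps$alt[si]))
  ## no read overlaps a deletion region its haplotype does not carry
  ctgStart <- setNames(truth$contigs$start, truth$contigs$contig)
  if (nrow(truth$deletions)) {
    d <- truth$deletions
    ds <- d$start - ctgStart[d$contig]        # 0-based contig coords
    de <- d$end - ctgStart[d$contig] + 1L
    for (i in seq_len(nrow(a))) {
      j <- which(d$contig == a$contig[i] & d$carrier != a$hapOrigin[i])
      if (length(j))
        expect_false(any(a$tstart[i] < de[j] & a$tend[i] > ds[j]))
    }
  }
  ## a read inside a conserved region has no substitutions and no markers
  if (nrow(truth$conserved)) {
    cv <- truth$conserved[1, ]
    cs0 <- cv$start - ctgStart[cv$contig]
    ce0 <- cv$end - ctgStart[cv$contig] + 1L
    inside <- a$tstart >= cs0 & a$tend <= ce0 & a$contig == cv$contig
    if (any(inside))
      expect_false(any(s$readId %in% a$readId[inside]))
  }
})

test_that("expected marker load per long read matches rate x length", {
  cfg <- simulationConfig(seed = 12, nChromosomes = 1,
                          chromosomeLength = 1e6, nReads = 400,
                          readLength = 15000, readLengthSd = 0,
                          deletionFraction = 0, conservedFraction = 0)
  truth <- simulateGametes(simulateDiploid(cfg))
  reads <- simulateLongReads(truth)
  ## each read covers ~30 SNPs; on average half show the alt allele
  subsPerRead <- nrow(reads$substitutions) / nrow(reads$alignments)
  expected <- 15000 * nrow(truth$snps) / 1e6 / 2
  expect_lt(abs(subsPerRead - expected), 0.2 * expected)
})
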
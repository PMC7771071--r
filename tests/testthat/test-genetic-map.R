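test_that("two-point LOD matches the haploid likelihood-ratio oracle", {
  ## R = 0 over 20 informative gametes: LOD = 20 log10 2
  g1 <- rep("a", 20); g2 <- rep("a", 20)
  l <- twoPointLod(g1, g2)
  expect_equal(l$lod, 20 * log10(2), tolerance = 1e-12)
  expect_equal(l$r, 0)
  ## R = NR: r = 0.5, LOD = 0
  l2 <- twoPointLod(c(rep("a", 10), rep("b", 10)), rep("a", 20))
  expect_equal(l2$r, 0.5)
  expect_equal(l2$lod, 0, tolerance = 1e-12)
  ## raw R = 18, NR = 2 flips to r = 0.1
  g3 <- c(rep("a", 18), rep("b", 2))
  g4 <- rep("b", 20)
  l3 <- twoPointLod(g3, g4)
  expect_true(l3$flip)
  expect_equal(l3$r, 0.1)
  expect_equal(l3$lod, 18 * log10(1.8) + 2 * log10(0.2), tolerance = 1e-12)
  expect_equal(l3$lod, 3.197, tolerance = 1e-3)
  ## missing symbols are uninformative
  l4 <- twoPointLod(c("a", "n"), c("n", "b"))
  expect_equal(l4$informative, 0L)
  expect_equal(l4$lod, 0)
  expect_error(twoPointLod("a", c("a", "b")), "length")
})

test_that("LOD is symmetric, flip-invariant and decreasing in r", {
  set.seed(31)
  g1 <- sample(c("a", "b", "n"), 50, replace = TRUE)
  g2 <- sample(c("a", "b", "n"), 50, replace = TRUE)
  expect_equal(twoPointLod(g1, g2)$lod, twoPointLod(g2, g1)$lod)
  expect_equal(twoPointLod(chartr("ab", "ba", g1), g2)$lod,
               twoPointLod(g1, g2)$lod)
  ## fixed informative count, increasing R: LOD strictly decreases
  lods <- vapply(0:9, function(R) {
    a <- rep("a", 20)
    b <- c(rep("b", R), rep("a", 20 - R))
    twoPointLod(a, b)$lod
  }, numeric(1))
  expect_true(all(diff(lods) < 0))
})

test_that("the pairwise linkage matrices agree with per-pair computation", {
  set.seed(32)
  seqs <- matrix(sample(c("a", "b", "n"), 8 * 30, replace = TRUE), 8, 30,
                 dimnames = list(paste0("m", 1:8), NULL))
  pl <- pairwiseLinkage(seqs)
  for (i in 1:8) for (j in 1:8) {
    l <- twoPointLod(seqs[i, ], seqs[j, ])
    expect_equal(pl$R[i, j], l$R)
    expect_equal(pl$NR[i, j], l$NR)
    expect_equal(pl$lod[i, j], l$lod, tolerance = 1e-12)
    if (i != j) expect_equal(pl$flip[i, j], l$flip)
  }
})

test_that("linkage grouping is connected components above the threshold", {
  lod <- matrix(0, 3, 3, dimnames = list(paste0("m", 1:3), paste0("m", 1:3)))
  lod[] <- 5; diag(lod) <- 0
  expect_equal(length(unique(groupMarkers(lod))), 1L)
  lod2 <- matrix(1, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(length(unique(groupMarkers(lod2))), 2L)
  ## chain: A-B and B-C linked, A-C not
  lod3 <- matrix(1, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  lod3["A", "B"] <- lod3["B", "A"] <- 5
  lod3["B", "C"] <- lod3["C", "B"] <- 5
  expect_equal(length(unique(groupMarkers(lod3))), 1L)
  ## the threshold is strict
  lod4 <- matrix(3, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(length(unique(groupMarkers(lod4))), 2L)
})

test_that("contig ends split across groups are pulled together with a warning", {
  ids <- c("c1:head", "c1:tail", "c2:head")
  lod <- matrix(0, 3, 3, dimnames = list(ids, ids))
  lod["c1:head", "c2:head"] <- lod["c2:head", "c1:head"] <- 8
  ## c1:tail is linked to nothing: it would form its own component
  ctg <- setNames(c("c1", "c1", "c2"), ids)
  expect_warning(comp <- groupMarkers(lod, markerContig = ctg),
                 "different linkage groups")
  expect_equal(comp[["c1:head"]], comp[["c1:tail"]])
})

test_that("marker ordering minimises adjacent recombination like exhaustive search", {
  mkMat <- function(ids, vals) {
    r <- matrix(0.5, length(ids), length(ids), dimnames = list(ids, ids))
    diag(r) <- 0
    for (v in vals) r[v[[1]], v[[2]]] <- r[v[[2]], v[[1]]] <- v[[3]]
    r
  }
  r <- mkMat(c("m1", "m2", "m3"),
             list(list("m1", "m2", 0.05), list("m2", "m3", 0.05),
                  list("m1", "m3", 0.10)))
  lod <- -10 * r + 6   # monotone proxy: closer pairs have higher LOD
  ord <- orderGroup(c("m1", "m2", "m3"), r, lod)
  expect_true(identical(ord$marker, c("m1", "m2", "m3")) ||
                identical(ord$marker, c("m3", "m2", "m1")))
  ## cM increments follow Haldane
  expect_equal(diff(ord$cM), rep(-50 * log(1 - 2 * 0.05), 2),
               tolerance = 1e-9)
  ## single member
  expect_equal(orderGroup("m1", r, lod)$cM, 0)
  ## randomized groups: greedy + 2-opt attains the exhaustive optimum
  set.seed(33)
  for (rep in 1:8) {
    k <- sample(4:7, 1)
    ids <- paste0("x", seq_len(k))
    pos <- sort(runif(k))
    rr <- outer(pos, pos, function(a, b)
      0.5 * (1 - exp(-2 * abs(a - b))))   # Haldane-consistent distances
    dimnames(rr) <- list(ids, ids)
    ll <- 6 - 10 * rr; diag(ll) <- 0
    ord <- orderGroup(ids, rr, ll)
    got <- sum(rr[cbind(ord$marker[-k], ord$marker[-1])])
    expect_equal(got, oracleOrderCost(ids, rr), tolerance = 1e-9)
  }
})

test_that("the Haldane map function caps at 50 cM", {
  expect_equal(haldane(0.1), -50 * log(0.8))
  expect_equal(haldane(0.1), 11.157, tolerance = 1e-3)
  expect_equal(haldane(0.5), 50)
  expect_equal(haldane(NA), 50)
})

test_that("deletion markers place by minimum divergence with phase", {
  set.seed(34)
  seqs <- matrix(sample(c("a", "b"), 4 * 60, replace = TRUE), 4, 60,
                 dimnames = list(c("c1:head", "c1:tail",
                                   "c2:head", "c2:tail"), NULL))
  e <- data.frame(linkage_group = "LG1", order_index = 1:4,
                  marker = rownames(seqs),
                  contig = c("c1", "c1", "c2", "c2"),
                  end = c("head", "tail", "head", "tail"),
                  cM = c(0, 5, 10, 15), phase = 0L)
  map <- GeneticMap(e)
  attr(map, "markerSeqs") <- seqs
  ## identical sequence: divergence 0, phase 0
  p1 <- integrateDeletionMarker(seqs["c2:head", ], map)
  expect_true(p1$placed)
  expect_equal(p1$nearestMarker, "c2:head")
  expect_equal(p1$phase, 0L)
  expect_equal(p1$divergence, 0)
  ## exact complement: divergence 0 after flip, phase 1
  p2 <- integrateDeletionMarker(chartr("ab", "ba", seqs["c1:tail", ]), map)
  expect_true(p2$placed)
  expect_equal(p2$nearestMarker, "c1:tail")
  expect_equal(p2$phase, 1L)
  ## far from everything: unplaced
  far <- seqs["c1:head", ]
  flipIdx <- seq(1, 60, by = 2)  # 50% divergence to its nearest neighbour
  far[flipIdx] <- chartr("ab", "ba", far[flipIdx])
  p3 <- integrateDeletionMarker(far, map, maxDivergence = 0.1)
  expect_false(p3$placed)
  ## too little overlap: unplaced regardless of divergence
  sparse <- seqs["c1:head", ]
  sparse[-(1:10)] <- "n"
  expect_false(integrateDeletionMarker(sparse, map,
                                       minOverlap = 30)$placed)
  expect_error(integrateDeletionMarker(sparse, GeneticMap(e[0, ])),
               "empty map")
})

test_that("absence calls are recoded only when reads were expected", {
  calls <- c("a", "n", "n", "n")
  expReads <- c(5, 5, 1.9, 0.1)
  expect_equal(inferDeletionAbsence(calls, expReads),
               c("a", "b", "n", "n"))
})

test_that("the genetic map recovers simulated linkage groups and order", {
  cfg <- simulationConfig(seed = 35, nChromosomes = 3,
                          chromosomeLength = 6e5, nGametes = 150,
                          coverage = 0.4, doubletFraction = 0)
  truth <- simulateGametes(simulateDiploid(cfg, makeSequences = FALSE))
  obs <- simulateObservations(truth)
  gr <- GenomicRanges::GRanges(truth$snps$contig,
    IRanges::IRanges(truth$snps$pos, width = 1),
    kind = "snp", ref = truth$snps$ref, alt = truth$snps$alt)
  names(gr) <- truth$snps$id
  gm <- buildGenotypeMatrix(obs$snpObs, gr, truth$gametes$ids)
  phased <- phaseAllContigs(gm)
  vm <- imputeVirtualMarkers(phased)
  map <- buildGeneticMap(vm)
  expect_equal(length(linkageGroups(map)), 3L)
  ## each group corresponds to one chromosome and orders its contigs well
  e <- mapEntries(map)
  for (g in linkageGroups(map)) {
    ctgs <- unique(e$contig[e$linkage_group == g])
    chroms <- truth$contigs$chrom[match(ctgs, truth$contigs$contig)]
    expect_equal(length(unique(chroms)), 1L)
    trueOrd <- truth$contigs$orderIndex[match(ctgs, truth$contigs$contig)]
    if (length(ctgs) >= 3) {
      tau <- stats::cor(seq_along(ctgs), trueOrd, method = "kendall")
      expect_gte(abs(tau), 0.9)
    }
  }
  ## both ends of every contig sit in the same group, close in order
  ## (markers of a neighbouring contig end may interleave at r ~ 0)
  for (ctg in unique(e$contig)) {
    rows <- e[e$contig == ctg, ]
    expect_equal(length(unique(rows$linkage_group)), 1L)
    expect_lte(abs(diff(rows$order_index)), 3L)
  }
})
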
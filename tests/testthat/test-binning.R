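## a tiny hand-built phased landscape: one contig in LG1, three markers,
## haplotype A carries the alt allele at every marker
mkAlleles <- function() {
  data.frame(marker = paste0("m", 1:3), contig = "c1",
             pos = c(1000L, 2000L, 3000L), group = "LG1",
             ref = c("A", "G", "T"), alt = c("C", "T", "G"),
             baseA = c("C", "T", "G"), baseB = c("A", "G", "T"))
}
mkAln <- function(readId = "r1", contig = "c1", tstart = 500L,
                  tend = 3500L) {
  data.frame(readId = readId, contig = contig, tstart = tstart,
             tend = tend)
}
cGroups <- c(c1 = "LG1", c2 = "LG1")

test_that("reads vote with their bases at phased markers", {
  ## substitutions at all three markers matching haplotype A
  subs <- data.frame(readId = "r1", tpos = c(999L, 1999L, 2999L),
                     readBase = c("c", "t", "g"))
  a <- assignRead(mkAln(), subs, mkAlleles(), contigGroups = cGroups)
  expect_equal(a$haplotype, "A")
  expect_equal(a$evidence, "snp_vote")
  expect_equal(a$votesA, 3L)
  expect_equal(a$votesB, 0L)
  ## no substitutions: the read carries the reference base everywhere,
  ## which is haplotype B here
  b <- assignRead(mkAln(), subs[0, ], mkAlleles(), contigGroups = cGroups)
  expect_equal(b$haplotype, "B")
  expect_equal(b$votesB, 3L)
  ## 2-1 majority
  subs21 <- data.frame(readId = "r1", tpos = c(999L, 1999L),
                       readBase = c("c", "t"))
  m <- assignRead(mkAln(), subs21, mkAlleles(), contigGroups = cGroups)
  expect_equal(m$haplotype, "A")
  expect_equal(c(m$votesA, m$votesB), c(2L, 1L))
  ## a base matching neither allele abstains
  subsBad <- data.frame(readId = "r1", tpos = 999L, readBase = "t")
  ab <- assignRead(mkAln(tstart = 500L, tend = 1500L), subsBad,
                   mkAlleles(), contigGroups = cGroups)
  expect_equal(ab$evidence, "none")
})

test_that("deletion overlap and conserved regions drive the fallback cases", {
  dels <- data.frame(contig = "c2", start = 1000L, end = 3000L,
                     group = "LG1", carrierHap = "B")
  cons <- data.frame(contig = "c2", start = 5000L, end = 9000L)
  d <- assignRead(mkAln(contig = "c2", tstart = 1500L, tend = 2500L),
                  data.frame(readId = character(0), tpos = integer(0),
                             readBase = character(0)),
                  mkAlleles(), deletions = dels, conserved = cons,
                  contigGroups = cGroups)
  expect_equal(d$haplotype, "B")
  expect_equal(d$evidence, "deletion")
  set.seed(1)
  cvd <- assignRead(mkAln(contig = "c2", tstart = 6000L, tend = 7000L),
                    data.frame(readId = character(0), tpos = integer(0),
                               readBase = character(0)),
                    mkAlleles(), deletions = dels, conserved = cons,
                    contigGroups = cGroups)
  expect_equal(cvd$evidence, "random")
  expect_true(cvd$haplotype %in% c("A", "B"))
  ## unplaced contig
  u <- assignRead(mkAln(contig = "c9"), data.frame(), mkAlleles(),
                  contigGroups = cGroups)
  expect_equal(u$haplotype, "unassigned")
  expect_equal(u$evidence, "none")
})

test_that("binReads conserves reads and matches the single-read contract", {
  aln <- rbind(mkAln("r1", tstart = 500L, tend = 3500L),
               mkAln("r2", tstart = 500L, tend = 3500L),
               mkAln("r3", contig = "c9"))
  subs <- data.frame(readId = c("r1", "r1", "r1"),
                     tpos = c(999L, 1999L, 2999L),
                     readBase = c("c", "t", "g"))
  res <- binReads(aln, subs, mkAlleles(), contigGroups = cGroups)
  expect_equal(nrow(res$assignments), 3L)
  expect_equal(res$assignments$haplotype[res$assignments$readId == "r1"],
               "A")
  expect_equal(res$assignments$haplotype[res$assignments$readId == "r2"],
               "B")
  expect_equal(res$assignments$haplotype[res$assignments$readId == "r3"],
               "unassigned")
  expect_equal(sum(res$assignments$haplotype != "unassigned") +
                 sum(res$assignments$haplotype == "unassigned"), 3L)
  expect_equal(res$summary$fractionAssigned, 2 / 3)
})

test_that("duplicate read ids keep the first alignment with a warning", {
  aln <- rbind(mkAln("r1"), mkAln("r1", contig = "c9"))
  expect_warning(res <- binReads(aln, data.frame(readId = character(0),
                                                 tpos = integer(0),
                                                 readBase = character(0)),
                                 mkAlleles(), contigGroups = cGroups),
                 "duplicate")
  expect_equal(nrow(res$assignments), 1L)
})

test_that("random-case assignment is deterministic under a fixed seed", {
  cons <- data.frame(contig = "c1", start = 5000L, end = 9000L)
  aln <- do.call(rbind, lapply(1:20, function(i)
    mkAln(sprintf("r%02d", i), tstart = 6000L, tend = 7000L)))
  empty <- data.frame(readId = character(0), tpos = integer(0),
                      readBase = character(0))
  r1 <- binReads(aln, empty, mkAlleles()[0, ], conserved = cons,
                 contigGroups = cGroups, seed = 99)
  r2 <- binReads(aln, empty, mkAlleles()[0, ], conserved = cons,
                 contigGroups = cGroups, seed = 99)
  expect_identical(r1$assignments, r2$assignments)
  expect_true(all(r1$assignments$evidence == "random"))
})

test_that("conserved-only reads split about evenly between haplotypes", {
  cons <- data.frame(contig = "c1", start = 5000L, end = 9000L)
  n <- 400
  aln <- do.call(rbind, lapply(seq_len(n), function(i)
    mkAln(sprintf("r%03d", i), tstart = 6000L, tend = 7000L)))
  empty <- data.frame(readId = character(0), tpos = integer(0),
                      readBase = character(0))
  res <- binReads(aln, empty, mkAlleles()[0, ], conserved = cons,
                  contigGroups = cGroups, seed = 5)
  nA <- sum(res$assignments$haplotype == "A")
  expect_lt(abs(nA - n / 2), 3 * sqrt(n * 0.25))
})

test_that("fully informative error-free reads all reach their true haplotype", {
  cfg <- simulationConfig(seed = 51, nChromosomes = 1,
                          chromosomeLength = 3e5, nGametes = 80,
                          nReads = 100, deletionFraction = 0,
                          conservedFraction = 0, doubletFraction = 0,
                          errorRate = 0, coverage = 1)
  res <- runGameteBinning(cfg)
  asg <- res$bins$assignments
  expect_true(all(asg$evidence == "snp_vote"))
  expect_equal(res$evaluation$snpVotePrecision, 1)
  expect_equal(res$evaluation$fractionAssigned, 1)
})
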
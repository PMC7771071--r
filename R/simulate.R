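#' Simulation configuration
#'
#' Parameters of the synthetic diploid / gamete / long-read generator. The
#' defaults describe a desk-scale heterozygous diploid: two 1-Mb
#' chromosomes, one SNP per 500 bp outside structural regions, 10% of the
#' genome haplotype-specific (deletion regions) and 10% conserved
#' (marker-free but shared), 200 gametes at 0.3x depth with a 0.5% per-base
#' genotyping error, a 5% doublet rate, and 10,000 long reads of ~15 kb.
#'
#' @param nChromosomes number of chromosomes.
#' @param chromosomeLength chromosome length in bp.
#' @param snpRate heterozygous SNP rate per bp of SNP territory.
#' @param deletionFraction fraction of each chromosome in haplotype-specific
#'   (deletion) regions.
#' @param conservedFraction fraction in conserved, marker-free regions.
#' @param regionLengthRange length range (bp) for deletion/conserved regions.
#' @param contigMeanLength mean length (bp) of assembly contigs the
#'   chromosomes are fragmented into.
#' @param nGametes number of gamete nuclei.
#' @param coMean mean crossover count per chromosome per gamete (Poisson
#'   lambda).
#' @param minCoDistance minimum distance (bp) between crossovers within a
#'   chromosome (0 disables; plain Poisson, no interference model).
#' @param obligateCo force at least one crossover per chromosome per gamete.
#' @param coverage mean per-gamete sequencing depth (x).
#' @param depthSdLog log-sd of the log-normal per-gamete depth factor.
#' @param errorRate per-base genotyping error rate in gamete observations.
#' @param doubletFraction fraction of gamete ids that pool two nuclei.
#' @param backgroundDeletionReads Poisson mean of false-positive reads in a
#'   deletion region for gametes not carrying it.
#' @param shortReadLength short-read length (bp) used to convert depth into
#'   expected read counts.
#' @param nReads number of simulated long reads.
#' @param readLength,readLengthSd mean and sd (bp) of long-read lengths.
#' @param readErrorRate probability that a long read shows the wrong allele
#'   at a covered SNP marker.
#' @param seed integer random seed; fixed seed gives identical output.
#'
#' @return A list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(nChromosomes = 2,
                             chromosomeLength = 1e6,
                             snpRate = 1 / 500,
                             deletionFraction = 0.10,
                             conservedFraction = 0.10,
                             regionLengthRange = c(10000, 30000),
                             contigMeanLength = 150000,
                             nGametes = 200,
                             coMean = 1.0,
                             minCoDistance = 0,
                             obligateCo = FALSE,
                             coverage = 0.3,
                             depthSdLog = 0.5,
                             errorRate = 0.005,
                             doubletFraction = 0.05,
                             backgroundDeletionReads = 0.05,
                             shortReadLength = 151,
                             nReads = 10000,
                             readLength = 15000,
                             readLengthSd = 1500,
                             readErrorRate = 0,
                             seed = NULL) {
  cfg <- as.list(environment())
  rates <- c(cfg$snpRate, cfg$deletionFraction, cfg$conservedFraction,
             cfg$errorRate, cfg$doubletFraction, cfg$readErrorRate)
  stopifnot(all(rates >= 0), all(rates <= 1),
            cfg$deletionFraction + cfg$conservedFraction < 1,
            cfg$coMean >= 0, cfg$chromosomeLength > 0,
            cfg$contigMeanLength > 0, cfg$nGametes >= 1,
            cfg$coverage >= 0)
  class(cfg) <- "SimulationConfig"
  cfg
}

## non-overlapping intervals totalling ~ frac * L, each fully inside one of
## the supplied host intervals; 1-based closed coordinates
.placeRegions <- function(hosts, targetTotal, lenRange, occupied = NULL) {
  out <- occupied
  total <- 0
  tries <- 0L
  while (total < targetTotal && tries < 10000L) {
    tries <- tries + 1L
    len <- round(stats::runif(1, lenRange[1], lenRange[2]))
    hi <- sample.int(nrow(hosts), 1L, prob = hosts$end - hosts$start + 1)
    if (hosts$end[hi] - hosts$start[hi] + 1 < len) next
    s <- floor(stats::runif(1, hosts$start[hi], hosts$end[hi] - len + 1))
    e <- s + len - 1
    if (!is.null(out) && nrow(out) &&
        any(s <= out$end & e >= out$start)) next
    out <- rbind(out, data.frame(start = s, end = e))
    total <- total + len
  }
  if (is.null(out)) out <- data.frame(start = integer(0), end = integer(0))
  out[order(out$start), , drop = FALSE]
}

.randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a heterozygous diploid genome and its marker truth
#'
#' Generates two haplotype sequences per chromosome that differ at SNP sites
#' at the configured rate, carry designated haplotype-specific (deletion)
#' regions in exactly one haplotype, and share conserved marker-free
#' regions. Chromosomes are fragmented into contigs (the curated-assembly
#' surrogate) with recorded true order; deletion and conserved regions are
#' placed fully inside contigs.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param makeSequences build actual DNA sequences (needed for long-read and
#'   k-mer work; skip for marker-level studies).
#'
#' @return A list of class \code{SyntheticTruth} with elements
#'   \code{config}, \code{chromLengths}, \code{contigs}, \code{snps},
#'   \code{deletions}, \code{conserved}, \code{markers} (a \code{GRanges}
#'   over contigs with a \code{kind} column), and, if requested,
#'   \code{sequences} (assembly contigs plus per-chromosome haplotype A/B
#'   sequences as \code{DNAStringSet}s).
#' @export
simulateDiploid <- function(config = simulationConfig(), makeSequences = TRUE) {
  if (!is.null(config$seed)) set.seed(config$seed)
  L <- config$chromosomeLength
  chroms <- paste0("chr", seq_len(config$nChromosomes))

  contigs <- snps <- dels <- cons <- NULL
  seqsAsm <- character(0)
  hapA <- hapB <- stats::setNames(character(length(chroms)), chroms)

  for (ci in seq_along(chroms)) {
    chrom <- chroms[ci]
    ## fragment chromosome into contigs
    lens <- integer(0)
    while (sum(lens) < L) {
      lens <- c(lens, max(30000L,
        round(stats::runif(1, 0.5, 1.5) * config$contigMeanLength)))
    }
    lens[length(lens)] <- L - sum(lens[-length(lens)])
    if (lens[length(lens)] < 30000L && length(lens) > 1L) {
      lens[length(lens) - 1L] <- lens[length(lens) - 1L] + lens[length(lens)]
      lens <- lens[-length(lens)]
    }
    cstart <- cumsum(c(1L, lens[-length(lens)]))
    ctg <- data.frame(contig = sprintf("%s_ctg%02d", chrom, seq_along(lens)),
                      chrom = chrom, start = cstart,
                      end = cstart + lens - 1L, length = lens,
                      orderIndex = seq_along(lens))
    contigs <- rbind(contigs, ctg)

    ## structural regions inside contigs
    hosts <- data.frame(start = ctg$start, end = ctg$end)
    dreg <- .placeRegions(hosts, config$deletionFraction * L,
                          config$regionLengthRange)
    creg <- .placeRegions(hosts, config$conservedFraction * L,
                          config$regionLengthRange, occupied = dreg)
    if (nrow(creg)) {
      inDel <- vapply(seq_len(nrow(creg)), function(i)
        any(creg$start[i] <= dreg$end & creg$end[i] >= dreg$start &
              nrow(dreg) > 0), logical(1))
      creg <- creg[!inDel, , drop = FALSE]
    }
    regionContig <- function(df) {
      if (!nrow(df)) return(character(0))
      ctg$contig[findInterval(df$start, ctg$start)]
    }
    if (nrow(dreg)) {
      dreg$chrom <- chrom
      dreg$contig <- regionContig(dreg)
      dreg$carrier <- sample(c("A", "B"), nrow(dreg), replace = TRUE)
    }
    if (nrow(creg)) {
      creg$chrom <- chrom
      creg$contig <- regionContig(creg)
    }
    dels <- rbind(dels, dreg)
    cons <- rbind(cons, creg)

    ## SNPs outside structural regions
    occ <- rbind(dreg[, c("start", "end")], creg[, c("start", "end")])
    freeMask <- rep(TRUE, L)
    if (nrow(occ)) for (i in seq_len(nrow(occ)))
      freeMask[occ$start[i]:occ$end[i]] <- FALSE
    freePos <- which(freeMask)
    nSnp <- stats::rpois(1, length(freePos) * config$snpRate)
    nSnp <- min(nSnp, length(freePos))
    if (nSnp > 0) {
      pos <- sort(sample(freePos, nSnp))
      sn <- data.frame(chrom = chrom, chromPos = pos)
      sn$contig <- ctg$contig[findInterval(pos, ctg$start)]
      sn$pos <- pos - ctg$start[match(sn$contig, ctg$contig)] + 1L
      sn$ref <- sample(c("A", "C", "G", "T"), nSnp, replace = TRUE)
      sn$alt <- vapply(sn$ref, function(r)
        sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
      sn$altInA <- sample(c(TRUE, FALSE), nSnp, replace = TRUE)
      snps <- rbind(snps, sn)
    }

    if (makeSequences) {
      base <- .randomDna(L)
      if (nSnp > 0) {
        bb <- strsplit(base, "")[[1]]
        bb[pos] <- sn$ref
        aa <- bb; aa[pos[sn$altInA]]  <- sn$alt[sn$altInA]
        b2 <- bb; b2[pos[!sn$altInA]] <- sn$alt[!sn$altInA]
        base <- paste(bb, collapse = "")
        strA <- paste(aa, collapse = "")
        strB <- paste(b2, collapse = "")
      } else strA <- strB <- base
      dropRegions <- function(s, keepCarrier) {
        if (!nrow(dreg)) return(s)
        drop <- dreg[dreg$carrier != keepCarrier, , drop = FALSE]
        if (!nrow(drop)) return(s)
        keepStart <- c(1L, drop$end + 1L)
        keepEnd <- c(drop$start - 1L, L)
        paste(substring(s, keepStart, keepEnd), collapse = "")
      }
      hapA[chrom] <- dropRegions(strA, "A")
      hapB[chrom] <- dropRegions(strB, "B")
      seqsAsm <- c(seqsAsm, stats::setNames(
        substring(base, ctg$start, ctg$end), ctg$contig))
    }
  }

  rownames(contigs) <- NULL
  if (is.null(snps))
    snps <- data.frame(chrom = character(0), chromPos = integer(0),
                       contig = character(0), pos = integer(0),
                       ref = character(0), alt = character(0),
                       altInA = logical(0))
  snps$id <- sprintf("%s_%d", snps$contig, snps$pos)
  if (is.null(dels))
    dels <- data.frame(start = integer(0), end = integer(0),
                       chrom = character(0), contig = character(0),
                       carrier = character(0))
  if (is.null(cons))
    cons <- data.frame(start = integer(0), end = integer(0),
                       chrom = character(0), contig = character(0))
  mkId <- function(df, tag) if (nrow(df))
    sprintf("%s_%s_%d", df$contig, tag,
            df$start - contigs$start[match(df$contig, contigs$contig)] + 1L)
    else character(0)
  dels$id <- mkId(dels, "del")
  cons$id <- mkId(cons, "cons")
  if (sum(contigs$length) > 0 && nrow(snps) == 0)
    warning("configured rates produced zero SNP markers")

  truth <- list(config = config,
                chromLengths = stats::setNames(
                  rep(L, length(chroms)), chroms),
                contigs = contigs, snps = snps, deletions = dels,
                conserved = cons)
  truth$markers <- .truthMarkerRanges(truth)
  if (makeSequences)
    truth$sequences <- list(
      assembly = Biostrings::DNAStringSet(seqsAsm),
      hapA = Biostrings::DNAStringSet(hapA),
      hapB = Biostrings::DNAStringSet(hapB))
  class(truth) <- "SyntheticTruth"
  truth
}

## marker GRanges in contig coordinates (1-based, as GRanges requires)
.truthMarkerRanges <- function(truth) {
  ctg <- truth$contigs
  ctgStart <- stats::setNames(ctg$start, ctg$contig)
  toCtg <- function(df) df$start - ctgStart[df$contig] + 1L
  gr <- c(
    GenomicRanges::GRanges(truth$snps$contig,
      IRanges::IRanges(truth$snps$pos, width = 1L),
      kind = rep("snp", nrow(truth$snps)),
      ref = truth$snps$ref, alt = truth$snps$alt),
    GenomicRanges::GRanges(truth$deletions$contig,
      IRanges::IRanges(as.integer(toCtg(truth$deletions)),
                       width = truth$deletions$end - truth$deletions$start + 1L),
      kind = rep("deletion", nrow(truth$deletions)),
      ref = rep(NA_character_, nrow(truth$deletions)),
      alt = rep(NA_character_, nrow(truth$deletions))),
    GenomicRanges::GRanges(truth$conserved$contig,
      IRanges::IRanges(as.integer(toCtg(truth$conserved)),
                       width = truth$conserved$end - truth$conserved$start + 1L),
      kind = rep("conserved", nrow(truth$conserved)),
      ref = rep(NA_character_, nrow(truth$conserved)),
      alt = rep(NA_character_, nrow(truth$conserved))))
  names(gr) <- c(truth$snps$id, truth$deletions$id, truth$conserved$id)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Simulate recombinant gametes
#'
#' Draws, per gamete and chromosome, a Poisson number of crossovers at
#' uniform positions and records the resulting parental-haplotype mosaic:
#' which haplotype each gamete carries at every SNP and deletion region, and
#' the exact breakpoints.
#'
#' @param truth a \code{SyntheticTruth} from \code{\link{simulateDiploid}}.
#' @param config the simulation configuration (defaults to the one inside
#'   \code{truth}).
#'
#' @return \code{truth} with an added \code{gametes} element: \code{ids},
#'   \code{co} (data.frame gamete/chrom/pos), \code{startHap},
#'   \code{snpHap} (SNPs x gametes matrix of \code{"A"}/\code{"B"}) and
#'   \code{delHap} (deletion regions x gametes carrier matrix).
#' @export
simulateGametes <- function(truth, config = truth$config) {
  n <- config$nGametes
  ids <- sprintf("gamete%03d", seq_len(n))
  chroms <- names(truth$chromLengths)
  co <- list(); startHap <- matrix("A", length(chroms), n,
                                   dimnames = list(chroms, ids))
  hapAt <- function(pos, breaks, start) {
    k <- findInterval(pos, breaks)
    ifelse((k %% 2L) == 0L, start, ifelse(start == "A", "B", "A"))
  }
  snpHap <- matrix(NA_character_, nrow(truth$snps), n,
                   dimnames = list(truth$snps$id, ids))
  delHap <- matrix(NA_character_, nrow(truth$deletions), n,
                   dimnames = list(truth$deletions$id, ids))
  delMid <- if (nrow(truth$deletions))
    (truth$deletions$start + truth$deletions$end) / 2 else numeric(0)
  for (g in seq_len(n)) {
    for (ch in chroms) {
      L <- truth$chromLengths[ch]
      k <- stats::rpois(1, config$coMean)
      if (config$obligateCo && k == 0L) k <- 1L
      tries <- 0L
      repeat {
        pos <- sort(ceiling(stats::runif(k) * L))
        tries <- tries + 1L
        if (k < 2L || config$minCoDistance <= 0 ||
            all(diff(pos) >= config$minCoDistance) || tries > 20L) break
      }
      sh <- sample(c("A", "B"), 1L)
      startHap[ch, g] <- sh
      if (k > 0L)
        co[[length(co) + 1L]] <- data.frame(
          gamete = ids[g], chrom = ch, pos = pos)
      smask <- truth$snps$chrom == ch
      if (any(smask))
        snpHap[smask, g] <- hapAt(truth$snps$chromPos[smask], pos, sh)
      dmask <- truth$deletions$chrom == ch
      if (any(dmask))
        delHap[dmask, g] <- hapAt(delMid[dmask], pos, sh)
    }
  }
  co <- if (length(co)) do.call(rbind, co) else
    data.frame(gamete = character(0), chrom = character(0), pos = integer(0))
  truth$gametes <- list(ids = ids, co = co, startHap = startHap,
                        snpHap = snpHap, delHap = delHap)
  truth
}

#' Simulate sparse per-gamete marker observations
#'
#' Each SNP marker in each gamete receives a Poisson number of reads at the
#' gamete's depth; each read reports the gamete's true allele except with
#' the configured error rate. Deletion-region read counts are Poisson at
#' the expected depth for carriers and at a small background mean for
#' non-carriers. Doublets pool the observations of two independent gametes
#' under one id.
#'
#' @param truth a \code{SyntheticTruth} with gametes simulated.
#' @param config simulation configuration.
#'
#' @return A list with \code{snpObs} (long data.frame: gamete, marker,
#'   refCount, altCount), \code{delObs} (gamete, marker, count,
#'   regionLength), \code{doublet} (named logical), \code{trueDepth} (named
#'   numeric, x), and \code{totalMapped} (named integer).
#' @export
simulateObservations <- function(truth, config = truth$config) {
  gm <- truth$gametes
  stopifnot(!is.null(gm))
  n <- length(gm$ids)
  depth <- config$coverage *
    stats::rlnorm(n, meanlog = -config$depthSdLog^2 / 2,
                  sdlog = config$depthSdLog)
  names(depth) <- gm$ids
  doublet <- stats::runif(n) < config$doubletFraction
  names(doublet) <- gm$ids
  partner <- rep(NA_integer_, n)
  if (any(doublet)) {
    partner[doublet] <- vapply(which(doublet), function(i)
      sample(setdiff(seq_len(n), i), 1L), integer(1))
  }

  nS <- nrow(truth$snps)
  drawSnp <- function(hapCol, depthVal) {
    r <- stats::rpois(nS, depthVal)
    altTrue <- hapCol == ifelse(truth$snps$altInA, "A", "B")
    altReads <- stats::rbinom(nS, r,
      ifelse(altTrue, 1 - config$errorRate, config$errorRate))
    cbind(ref = r - altReads, alt = altReads)
  }
  obsList <- vector("list", n)
  for (g in seq_len(n)) {
    cnt <- drawSnp(gm$snpHap[, g], depth[g])
    if (doublet[g]) cnt <- cnt + drawSnp(gm$snpHap[, partner[g]], depth[g])
    keep <- which(rowSums(cnt) > 0L)
    if (length(keep))
      obsList[[g]] <- data.frame(gamete = gm$ids[g],
                                 marker = truth$snps$id[keep],
                                 refCount = cnt[keep, "ref"],
                                 altCount = cnt[keep, "alt"])
  }
  snpObs <- do.call(rbind, obsList)
  if (is.null(snpObs))
    snpObs <- data.frame(gamete = character(0), marker = character(0),
                         refCount = integer(0), altCount = integer(0))

  nD <- nrow(truth$deletions)
  delObs <- NULL
  if (nD > 0) {
    regionLen <- truth$deletions$end - truth$deletions$start + 1L
    drawDel <- function(hapCol, depthVal) {
      lam <- ifelse(hapCol == truth$deletions$carrier,
                    depthVal * regionLen / config$shortReadLength,
                    config$backgroundDeletionReads)
      stats::rpois(nD, lam)
    }
    dl <- vector("list", n)
    for (g in seq_len(n)) {
      cnt <- drawDel(gm$delHap[, g], depth[g])
      if (doublet[g]) cnt <- cnt + drawDel(gm$delHap[, partner[g]], depth[g])
      dl[[g]] <- data.frame(gamete = gm$ids[g],
                            marker = truth$deletions$id,
                            count = cnt, regionLength = regionLen)
    }
    delObs <- do.call(rbind, dl)
  } else {
    delObs <- data.frame(gamete = character(0), marker = character(0),
                         count = integer(0), regionLength = integer(0))
  }

  effDepth <- depth * ifelse(doublet, 2, 1)
  totalMapped <- as.integer(round(
    effDepth * sum(truth$chromLengths) / config$shortReadLength))
  names(totalMapped) <- gm$ids
  list(snpObs = snpObs, delObs = delObs, doublet = doublet,
       trueDepth = depth, totalMapped = totalMapped)
}

#' Simulate haplotype-tagged long reads as PAF-like alignment records
#'
#' Each read is drawn from one haplotype, placed uniformly on the contig
#' assembly, and carries cs-style substitution records at SNPs where its
#' haplotype holds the alternative allele. Reads never overlap a deletion
#' region their haplotype does not carry (that haplotype lacks the
#' sequence, so no alignment could arise there).
#'
#' @param truth a \code{SyntheticTruth}.
#' @param config simulation configuration.
#'
#' @return A list with \code{alignments} (readId, qlen, contig, tstart,
#'   tend as 0-based half-open, strand, cs, hapOrigin) and
#'   \code{substitutions} (readId, tpos 0-based, refBase, readBase).
#' @export
simulateLongReads <- function(truth, config = truth$config) {
  ctg <- truth$contigs
  nR <- config$nReads
  rl <- pmax(1000L, round(stats::rnorm(nR, config$readLength,
                                       config$readLengthSd)))
  hap <- sample(c("A", "B"), nR, replace = TRUE)
  ci <- sample.int(nrow(ctg), nR, replace = TRUE, prob = ctg$length)

  snpsByCtg <- split(truth$snps, truth$snps$contig)
  delsByCtg <- split(truth$deletions, truth$deletions$contig)

  aln <- data.frame(readId = sprintf("read%05d", seq_len(nR)),
                    qlen = rl, contig = ctg$contig[ci],
                    tstart = 0L, tend = 0L, strand = "+",
                    cs = "", hapOrigin = hap,
                    stringsAsFactors = FALSE)
  subsList <- vector("list", nR)
  for (i in seq_len(nR)) {
    clen <- ctg$length[ci[i]]
    len <- min(rl[i], clen)
    dl <- delsByCtg[[ctg$contig[ci[i]]]]
    for (try in 1:50) {
      s0 <- floor(stats::runif(1, 0, clen - len + 1))  # 0-based start
      if (is.null(dl) || !nrow(dl)) break
      ds <- dl$start - ctg$start[ci[i]]                # 0-based in contig
      de <- dl$end - ctg$start[ci[i]] + 1L
      bad <- dl$carrier != hap[i] & s0 < de & (s0 + len) > ds
      if (!any(bad)) break
    }
    aln$tstart[i] <- s0
    aln$tend[i] <- s0 + len
    aln$qlen[i] <- len
    sn <- snpsByCtg[[ctg$contig[ci[i]]]]
    if (!is.null(sn) && nrow(sn)) {
      p0 <- sn$pos - 1L                                # 0-based marker pos
      inRead <- p0 >= s0 & p0 < s0 + len
      if (any(inRead)) {
        sn <- sn[inRead, , drop = FALSE]
        showsAlt <- sn$altInA == (hap[i] == "A")
        if (config$readErrorRate > 0) {
          flip <- stats::runif(nrow(sn)) < config$readErrorRate
          showsAlt <- xor(showsAlt, flip)
        }
        if (any(showsAlt)) {
          sub <- sn[showsAlt, , drop = FALSE]
          subsList[[i]] <- data.frame(readId = aln$readId[i],
                                      tpos = sub$pos - 1L,
                                      refBase = sub$ref,
                                      readBase = sub$alt)
        }
      }
    }
  }
  subs <- do.call(rbind, subsList)
  if (is.null(subs))
    subs <- data.frame(readId = character(0), tpos = integer(0),
                       refBase = character(0), readBase = character(0))
  aln$cs <- .buildCsTags(aln, subs)
  list(alignments = aln, substitutions = subs)
}

## cs difference strings (":n*ra:m" grammar, substitutions only)
.buildCsTags <- function(aln, subs) {
  cs <- character(nrow(aln))
  subsByRead <- split(subs, factor(subs$readId, levels = aln$readId))
  for (i in seq_len(nrow(aln))) {
    sb <- subsByRead[[i]]
    len <- aln$tend[i] - aln$tstart[i]
    if (is.null(sb) || !nrow(sb)) { cs[i] <- paste0(":", len); next }
    sb <- sb[order(sb$tpos), , drop = FALSE]
    rel <- sb$tpos - aln$tstart[i]
    parts <- character(0)
    prev <- 0L
    for (j in seq_len(nrow(sb))) {
      if (rel[j] > prev) parts <- c(parts, paste0(":", rel[j] - prev))
      parts <- c(parts, paste0("*", tolower(sb$refBase[j]),
                               tolower(sb$readBase[j])))
      prev <- rel[j] + 1L
    }
    if (len > prev) parts <- c(parts, paste0(":", len - prev))
    cs[i] <- paste(parts, collapse = "")
  }
  cs
}
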
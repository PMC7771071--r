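#' Segment a gamete's haplotype call string into supported blocks
#'
#' Missing (\code{n}) calls are ignored. The observed \code{a}/\code{b}
#' symbols are relabeled by an exact dynamic program that minimises the
#' number of relabeled symbols subject to every maximal run of identical
#' labels containing at least \code{minSupport} markers (ties broken by
#' fewest blocks, then label \code{a}). Runs of the optimal labeling are
#' the supported blocks; isolated flips shorter than the support threshold
#' are thereby absorbed as genotyping error rather than crossovers. If
#' fewer than \code{minSupport} markers are observed the whole string forms
#' one majority block.
#'
#' @param symbols character vector over \code{a/b/n} in map order.
#' @param minSupport minimum markers per block (default 5).
#' @return data.frame of blocks with columns \code{symbol}, \code{startIdx},
#'   \code{endIdx} (indices into the observed, non-\code{n} subsequence),
#'   \code{origStartIdx}, \code{origEndIdx} (indices into \code{symbols}),
#'   and \code{support} (markers in block). Zero rows when nothing observed.
#' @export
segmentCalls <- function(symbols, minSupport = 5) {
  obsIdx <- which(symbols %in% c("a", "b"))
  m <- length(obsIdx)
  empty <- data.frame(symbol = character(0), startIdx = integer(0),
                      endIdx = integer(0), origStartIdx = integer(0),
                      origEndIdx = integer(0), support = integer(0))
  if (m == 0L) return(empty)
  y <- symbols[obsIdx]
  s <- min(minSupport, m)
  if (m < minSupport || s <= 1L) {
    maj <- if (sum(y == "a") >= sum(y == "b")) "a" else "b"
    if (s <= 1L && m >= minSupport) {
      ## support 1: every run stands on its own
      r <- rle(y)
      endI <- cumsum(r$lengths)
      startI <- c(1L, utils::head(endI, -1L) + 1L)
      return(data.frame(symbol = r$values, startIdx = startI, endIdx = endI,
                        origStartIdx = obsIdx[startI],
                        origEndIdx = obsIdx[endI],
                        support = r$lengths))
    }
    return(data.frame(symbol = maj, startIdx = 1L, endIdx = m,
                      origStartIdx = obsIdx[1L], origEndIdx = obsIdx[m],
                      support = m))
  }

  ## DP over (position, label, min(run length, s)); cost = (mismatches,
  ## blocks) lexicographic, encoded as mismatches * BIG + blocks
  BIG <- 2L * m + 2L
  INF <- .Machine$integer.max %/% 2L
  labs <- c("a", "b")
  cost <- array(INF, dim = c(2L, s))      # current position
  from <- array(NA_integer_, dim = c(m, 2L, s))  # backpointer: lab*100+run
  for (l in 1:2)
    cost[l, 1L] <- (y[1L] != labs[l]) * BIG + 1L
  for (i in 2:m) {
    newCost <- array(INF, dim = c(2L, s))
    for (l in 1:2) {
      mis <- (y[i] != labs[l]) * BIG
      ## extend same label
      for (r in 1:s) {
        r2 <- min(r + 1L, s)
        v <- cost[l, r]
        if (v < INF && v + mis < newCost[l, r2]) {
          newCost[l, r2] <- v + mis
          from[i, l, r2] <- l * 100L + r
        }
      }
      ## switch from other label (its run must be complete)
      o <- 3L - l
      v <- cost[o, s]
      if (v < INF && v + mis + 1L < newCost[l, 1L]) {
        newCost[l, 1L] <- v + mis + 1L
        from[i, l, 1L] <- o * 100L + s
      }
    }
    cost <- newCost
  }
  ## final run must be complete
  best <- which.min(c(cost[1L, s], cost[2L, s]))
  lab <- integer(m)
  l <- best; r <- s
  for (i in m:1) {
    lab[i] <- l
    if (i > 1L) {
      bp <- from[i, l, r]
      l <- bp %/% 100L
      r <- bp %% 100L
    }
  }
  rl <- rle(labs[lab])
  endI <- cumsum(rl$lengths)
  startI <- c(1L, utils::head(endI, -1L) + 1L)
  data.frame(symbol = rl$values, startIdx = startI, endIdx = endI,
             origStartIdx = obsIdx[startI], origEndIdx = obsIdx[endI],
             support = rl$lengths)
}

#' Segment a call string and emit crossover events
#'
#' Runs \code{\link{segmentCalls}} and reports one crossover between every
#' pair of consecutive surviving blocks (which necessarily carry opposite
#' symbols). The crossover interval spans from the last marker of the left
#' block to the first marker of the right block; its length is the event's
#' resolution.
#'
#' @param symbols character vector over \code{a/b/n} in map order.
#' @param positions marker positions (bp, 1-based) parallel to
#'   \code{symbols}.
#' @param minSupport minimum markers per block (default 5).
#' @param gamete,group ids copied into the output.
#' @return list with \code{blocks} (see \code{\link{segmentCalls}}) and
#'   \code{events}: data.frame gamete, group, leftMarkerIdx,
#'   rightMarkerIdx, leftPos, rightPos, start/end (0-based half-open
#'   interval between the flanking markers), midpoint, resolution,
#'   leftSupport, rightSupport.
#' @export
segmentAndCall <- function(symbols, positions, minSupport = 5,
                           gamete = NA_character_, group = NA_character_) {
  stopifnot(length(symbols) == length(positions))
  blocks <- segmentCalls(symbols, minSupport)
  emptyEv <- data.frame(gamete = character(0), group = character(0),
                        leftMarkerIdx = integer(0),
                        rightMarkerIdx = integer(0),
                        leftPos = numeric(0), rightPos = numeric(0),
                        start = numeric(0), end = numeric(0),
                        midpoint = numeric(0), resolution = numeric(0),
                        leftSupport = integer(0), rightSupport = integer(0))
  if (nrow(blocks) < 2L) return(list(blocks = blocks, events = emptyEv))
  li <- blocks$origEndIdx[-nrow(blocks)]
  ri <- blocks$origStartIdx[-1L]
  lp <- positions[li]
  rp <- positions[ri]
  ev <- data.frame(gamete = gamete, group = group,
                   leftMarkerIdx = li, rightMarkerIdx = ri,
                   leftPos = lp, rightPos = rp,
                   start = lp, end = rp,   # 0-based half-open (lp, rp]
                   midpoint = (lp + rp) / 2,
                   resolution = rp - lp,
                   leftSupport = blocks$support[-nrow(blocks)],
                   rightSupport = blocks$support[-1L])
  list(blocks = blocks, events = ev)
}

#' Drop crossover events from under-sequenced gametes
#'
#' @param events crossover event data.frame (column \code{gamete}).
#' @param depths named numeric vector of per-gamete depth (x).
#' @param minDepth events are kept only for gametes with depth strictly
#'   above this (default 0.1x).
#' @return the filtered events.
#' @export
filterEventsByCoverage <- function(events, depths, minDepth = 0.1) {
  if (!nrow(events)) return(events)
  keep <- depths[events$gamete] > minDepth
  events[!is.na(keep) & keep, , drop = FALSE]
}

#' Recombination landscape in sliding windows
#'
#' For each window, C is the number of distinct gametes with a crossover
#' midpoint inside the window and the recombination frequency (cM/Mb) is
#' 100 * C / n / (w / 1e6). SNP and gene densities are feature counts per
#' Mb over the same windows.
#'
#' @param events crossover events (columns \code{gamete}, \code{chrom},
#'   \code{midpoint}).
#' @param n total number of gametes considered.
#' @param chromLengths named vector of chromosome (or linkage group
#'   scaffold) lengths.
#' @param windowSize window size in bp (default 500000).
#' @param step step in bp (default 50000).
#' @param snpPositions optional list (by chrom) of SNP positions.
#' @param geneIntervals optional data.frame chrom/start/end of genes
#'   (counted by midpoint).
#' @return data.frame with chrom, start (1-based), end, C, n, cMperMb,
#'   snpPerMb, genePerMb.
#' @export
recombinationLandscape <- function(events, n, chromLengths,
                                   windowSize = 5e5, step = 5e4,
                                   snpPositions = NULL,
                                   geneIntervals = NULL) {
  if (n == 0) stop("n must be positive")
  wMb <- windowSize / 1e6
  out <- list()
  for (ch in names(chromLengths)) {
    L <- chromLengths[[ch]]
    starts <- seq(1, max(1, L - windowSize + 1), by = step)
    ends <- pmin(starts + windowSize - 1, L)
    ev <- events[!is.na(events$chrom) & events$chrom == ch, , drop = FALSE]
    C <- integer(length(starts))
    if (nrow(ev)) {
      for (i in seq_along(starts)) {
        inWin <- ev$midpoint >= starts[i] & ev$midpoint <= ends[i]
        C[i] <- length(unique(ev$gamete[inWin]))
      }
    }
    snpD <- rep(NA_real_, length(starts))
    if (!is.null(snpPositions) && !is.null(snpPositions[[ch]])) {
      sp <- snpPositions[[ch]]
      snpD <- vapply(seq_along(starts), function(i)
        sum(sp >= starts[i] & sp <= ends[i]) / wMb, numeric(1))
    }
    geneD <- rep(NA_real_, length(starts))
    if (!is.null(geneIntervals)) {
      gi <- geneIntervals[geneIntervals$chrom == ch, , drop = FALSE]
      mid <- (gi$start + gi$end) / 2
      geneD <- vapply(seq_along(starts), function(i)
        sum(mid >= starts[i] & mid <= ends[i]) / wMb, numeric(1))
    }
    out[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                            C = C, n = n,
                            cMperMb = 100 * C / n / wMb,
                            snpPerMb = snpD, genePerMb = geneD)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-gamete diagnostic for non-allelic crossover signatures
#'
#' Reports, per gamete, the fraction of covered SNP markers at which both
#' alleles were observed (pseudo-heterozygosity) and the mean read count
#' per covered marker relative to the population median (a depth-ratio
#' proxy). Elevated values of both are the hallmark of a duplication
#' created by a non-allelic crossover; this is a report, not a caller.
#'
#' @param observations long observation data.frame (gamete, marker,
#'   refCount, altCount).
#' @return data.frame gamete, covered, pseudoHetFraction, depthRatio.
#' @export
nonAllelicDiagnostics <- function(observations) {
  sp <- split(observations, observations$gamete)
  res <- do.call(rbind, lapply(names(sp), function(g) {
    o <- sp[[g]]
    covered <- nrow(o)
    both <- sum(o$refCount > 0 & o$altCount > 0)
    data.frame(gamete = g, covered = covered,
               pseudoHetFraction = if (covered) both / covered else NA_real_,
               meanReads = if (covered)
                 mean(o$refCount + o$altCount) else NA_real_)
  }))
  res$depthRatio <- res$meanReads / stats::median(res$meanReads)
  res$meanReads <- NULL
  res
}
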
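#' Two-point linkage between two genotype sequences
#'
#' Over gametes where both sequences are non-missing, R counts recombinant
#' (differing) and NR non-recombinant (matching) gametes. Raw R > NR means
#' the two markers were phased in opposite orientations, so the counts are
#' swapped and the flip recorded. The recombination fraction is
#' r = R / (R + NR) and the haploid two-point LOD is
#' NR * log10(2 (1 - r)) + R * log10(2 r), with LOD = (R + NR) * log10(2)
#' when R = 0. With no informative gametes r is undefined and LOD is 0.
#'
#' @param g1,g2 genotype sequences over \code{a/b/n}, equal length.
#' @return list with \code{R}, \code{NR}, \code{r}, \code{lod},
#'   \code{flip}, \code{informative}.
#' @export
twoPointLod <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("genotype sequences differ in length")
  inf <- g1 != "n" & g2 != "n"
  n <- sum(inf)
  if (n == 0L)
    return(list(R = 0L, NR = 0L, r = NA_real_, lod = 0, flip = FALSE,
                informative = 0L))
  R <- sum(g1[inf] != g2[inf])
  NR <- n - R
  flip <- R > NR
  if (flip) { tmp <- R; R <- NR; NR <- tmp }
  r <- R / n
  lod <- if (R == 0L) n * log10(2) else
    NR * log10(2 * (1 - r)) + R * log10(2 * r)
  list(R = as.integer(R), NR = as.integer(NR), r = r, lod = lod,
       flip = flip, informative = as.integer(n))
}

#' All pairwise two-point linkages of a marker set
#'
#' Vectorised computation of the R/NR/r/LOD/flip matrices for every pair of
#' rows of a genotype-sequence matrix.
#'
#' @param seqs character matrix over \code{a/b/n}, markers x gametes.
#' @return list of matrices \code{R}, \code{NR}, \code{r}, \code{lod},
#'   \code{flip} (logical), \code{informative}, each markers x markers.
#' @export
pairwiseLinkage <- function(seqs) {
  A <- (seqs == "a") * 1
  B <- (seqs == "b") * 1
  I <- A + B
  M <- A %*% t(A) + B %*% t(B)      # matching informative pairs
  N <- I %*% t(I)                    # informative pairs
  R <- N - M
  flip <- R > M
  Rc <- pmin(R, M)
  NRc <- pmax(R, M)
  r <- ifelse(N > 0, Rc / N, NA_real_)
  lod <- matrix(0, nrow(seqs), nrow(seqs),
                dimnames = list(rownames(seqs), rownames(seqs)))
  pos <- N > 0 & Rc > 0
  lod[pos] <- NRc[pos] * log10(2 * (1 - r[pos])) +
    Rc[pos] * log10(2 * r[pos])
  zero <- N > 0 & Rc == 0
  lod[zero] <- N[zero] * log10(2)
  dimnames(R) <- dimnames(NRc) <- dimnames(r) <- dimnames(flip) <-
    dimnames(N) <- dimnames(lod)
  list(R = Rc, NR = NRc, r = r, lod = lod, flip = flip, informative = N)
}

#' Group markers into linkage groups
#'
#' Connected components of the graph whose edges join marker pairs with
#' LOD strictly above the threshold. When the two end markers of a contig
#' fall into different components, the whole contig is pulled into the
#' component holding its stronger edge and a warning is issued.
#'
#' @param lod markers x markers LOD matrix (named).
#' @param threshold LOD threshold (default 3, strict).
#' @param markerContig optional named vector mapping marker id to contig
#'   id, used to keep contig ends together.
#' @return named integer vector of group memberships (1, 2, ...).
#' @export
groupMarkers <- function(lod, threshold = 3, markerContig = NULL) {
  ids <- rownames(lod)
  adj <- lod > threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  names(comp) <- ids
  if (!is.null(markerContig)) {
    for (ctg in unique(markerContig)) {
      mk <- names(markerContig)[markerContig == ctg]
      mk <- intersect(mk, ids)
      if (length(mk) < 2L) next
      if (length(unique(comp[mk])) > 1L) {
        ## keep the contig in the component of its strongest external edge
        best <- vapply(mk, function(m) {
          o <- setdiff(ids, mk)
          if (!length(o)) return(-Inf)
          max(lod[m, o])
        }, numeric(1))
        target <- comp[mk[which.max(best)]]
        warning(sprintf(
          "contig %s: end markers fell into different linkage groups; forced into group %d",
          ctg, target))
        comp[mk] <- target
      }
    }
  }
  ## renumber by decreasing size for stable output
  sizes <- sort(table(comp), decreasing = TRUE)
  stats::setNames(match(comp, names(sizes)), ids)
}

#' Haldane map distance for a recombination fraction
#'
#' d = -50 * ln(1 - 2 r) cM, capped at 50 cM as r approaches 0.5 (the
#' no-interference mapping function).
#'
#' @param r recombination fraction(s) in [0, 0.5].
#' @param eps cap margin (default 1e-6).
#' @return distance(s) in cM.
#' @export
haldane <- function(r, eps = 1e-6) {
  ifelse(is.na(r) | r >= 0.5 - eps, 50, -50 * log(1 - 2 * r))
}

#' Order the markers of one linkage group and assign cM positions
#'
#' Greedy nearest-neighbour seriation — seeded at the pair with maximal
#' LOD, repeatedly appending the unplaced marker with smallest r to either
#' end (ties broken by higher LOD, then lexicographic id) — followed by
#' 2-opt refinement minimising the sum of adjacent recombination
#' fractions. Centimorgan positions accumulate Haldane distances between
#' adjacent markers. Pairs with no informative gametes are joined at the
#' 50-cM cap with a warning.
#'
#' @param ids marker ids in the group.
#' @param r,lod pairwise matrices (from \code{\link{pairwiseLinkage}}).
#' @return data.frame with \code{marker}, \code{order_index}, \code{cM}.
#' @export
orderGroup <- function(ids, r, lod) {
  k <- length(ids)
  if (k == 1L)
    return(data.frame(marker = ids, order_index = 1L, cM = 0))
  rr <- r[ids, ids, drop = FALSE]
  rr[is.na(rr)] <- 0.5      # uninformative pairs look unlinked
  ll <- lod[ids, ids, drop = FALSE]
  if (any(is.na(r[ids, ids])))
    warning("uninformative marker pair(s) in group; joined at cap distance")
  if (k == 2L) {
    path <- ids
  } else {
    ## seed with the max-LOD pair
    d <- ll; diag(d) <- -Inf
    seed <- which(d == max(d), arr.ind = TRUE)[1L, ]
    path <- ids[seed]
    left <- setdiff(ids, path)
    while (length(left)) {
      cand <- rbind(rr[path[1L], left], rr[path[length(path)], left])
      best <- which(cand == min(cand), arr.ind = TRUE)
      if (nrow(best) > 1L) {
        lods <- ll[cbind(c(path[1L], path[length(path)])[best[, 1L]],
                         left[best[, 2L]])]
        best <- best[order(-lods, left[best[, 2L]]), , drop = FALSE]
      }
      pick <- left[best[1L, 2L]]
      if (best[1L, 1L] == 1L) path <- c(pick, path) else
        path <- c(path, pick)
      left <- setdiff(left, pick)
    }
    path <- .twoOpt(path, rr)
  }
  ## canonical direction: lexicographically smaller first id
  if (path[length(path)] < path[1L]) path <- rev(path)
  adj <- rr[cbind(path[-k], path[-1L])]
  cm <- c(0, cumsum(haldane(adj)))
  data.frame(marker = path, order_index = seq_len(k), cM = cm)
}

.pathCost <- function(path, rr) sum(rr[cbind(path[-length(path)],
                                             path[-1L])])

.twoOpt <- function(path, rr) {
  k <- length(path)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in 1:(k - 1L)) {
      for (j in (i + 1L):k) {
        cand <- path
        cand[i:j] <- rev(cand[i:j])
        if (.pathCost(cand, rr) < .pathCost(path, rr) - 1e-12) {
          path <- cand
          improved <- TRUE
        }
      }
    }
  }
  path
}

#' Build a genetic map from contig-end virtual markers
#'
#' Filters end markers by missing-data fraction, computes all pairwise
#' linkages, groups them (LOD threshold), orients every contig relative to
#' its group by propagating two-point flip flags along a maximum-LOD
#' spanning tree, orders each group by seriation and assigns cM positions.
#'
#' @param virtual list with \code{head} and \code{tail} matrices from
#'   \code{\link{imputeVirtualMarkers}} (contigs x gametes).
#' @param lodThreshold grouping threshold (default 3, strict).
#' @param maxMissing end markers with a larger missing-gamete fraction are
#'   dropped before grouping (default 0.10).
#' @param exclude gamete ids (e.g. doublets) dropped before everything.
#' @return A \linkS4class{GeneticMap}; its \code{metadata}-like attribute
#'   \code{attr(, "markerSeqs")} holds the oriented genotype sequences of
#'   the placed markers (rows) for downstream deletion-marker integration.
#' @export
buildGeneticMap <- function(virtual, lodThreshold = 3, maxMissing = 0.10,
                            exclude = character(0)) {
  keepG <- !(colnames(virtual$head) %in% exclude)
  hm <- virtual$head[, keepG, drop = FALSE]
  tm <- virtual$tail[, keepG, drop = FALSE]
  contigs <- rownames(hm)
  seqs <- rbind(hm, tm)
  rownames(seqs) <- c(paste0(contigs, ":head"), paste0(contigs, ":tail"))
  markerContig <- stats::setNames(rep(contigs, 2L), rownames(seqs))
  markerEnd <- stats::setNames(rep(c("head", "tail"), each = length(contigs)),
                               rownames(seqs))
  ## missing-fraction filter
  missFrac <- rowMeans(seqs == "n")
  seqs <- seqs[missFrac <= maxMissing, , drop = FALSE]
  if (nrow(seqs) == 0L)
    return(GeneticMap(data.frame(linkage_group = character(0),
                                 order_index = integer(0),
                                 marker = character(0),
                                 contig = character(0), end = character(0),
                                 cM = numeric(0), phase = integer(0))))
  pl <- pairwiseLinkage(seqs)
  comp <- groupMarkers(pl$lod, lodThreshold, markerContig[rownames(seqs)])

  entries <- list()
  for (grp in sort(unique(comp))) {
    ids <- names(comp)[comp == grp]
    ## orient contigs: BFS over max-LOD spanning tree of the flip graph
    phase <- .propagatePhase(ids, pl, markerContig)
    ord <- orderGroup(ids, pl$r, pl$lod)
    entries[[length(entries) + 1L]] <- data.frame(
      linkage_group = sprintf("LG%d", grp),
      order_index = ord$order_index,
      marker = ord$marker,
      contig = unname(markerContig[ord$marker]),
      end = unname(markerEnd[ord$marker]),
      cM = ord$cM,
      phase = unname(phase[markerContig[ord$marker]]))
  }
  e <- do.call(rbind, entries)
  map <- GeneticMap(e)
  oriented <- seqs
  flip <- stats::setNames(
    contigPhase(map)[markerContig[rownames(seqs)]] == 1L, rownames(seqs))
  flip[is.na(flip)] <- FALSE
  oriented[flip, ] <- chartr("ab", "ba", oriented[flip, , drop = FALSE])
  attr(map, "markerSeqs") <- oriented
  map
}

## contig-level phase values within one group: 0 keeps the contig's own
## phasing, 1 flips it. Anchored at the first contig; flips propagate along
## a maximum-LOD spanning tree of the end-marker linkage graph.
.propagatePhase <- function(ids, pl, markerContig) {
  ctgs <- unique(unname(markerContig[ids]))
  phase <- stats::setNames(rep(NA_integer_, length(ctgs)), ctgs)
  phase[ctgs[1L]] <- 0L
  lod <- pl$lod[ids, ids, drop = FALSE]
  flip <- pl$flip[ids, ids, drop = FALSE]
  repeat {
    todo <- ctgs[is.na(phase[ctgs])]
    if (!length(todo)) break
    doneM <- ids[!is.na(phase[markerContig[ids]])]
    todoM <- ids[is.na(phase[markerContig[ids]])]
    if (!length(doneM)) { phase[todo[1L]] <- 0L; next }
    sub <- lod[doneM, todoM, drop = FALSE]
    best <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
    from <- doneM[best[1L]]; to <- todoM[best[2L]]
    rel <- as.integer(flip[from, to])
    phase[markerContig[to]] <- (phase[markerContig[from]] + rel) %% 2L
  }
  phase
}

#' Recode deletion-marker absence calls using expected coverage
#'
#' A gamete with zero reads in a deletion region is only informative about
#' the deleted haplotype when reads were expected there: if the expected
#' read count under the gamete's depth is at least \code{minExpected}, the
#' \code{n} call is recoded to \code{b} (the haplotype lacking the
#' region); otherwise it stays \code{n}.
#'
#' @param callsVec character vector over \code{a/n} for one deletion
#'   marker across gametes.
#' @param expectedReads expected read count per gamete in the region
#'   (depth * regionLength / shortReadLength).
#' @param minExpected threshold (default 2).
#' @return character vector over \code{a/b/n}.
#' @export
inferDeletionAbsence <- function(callsVec, expectedReads, minExpected = 2) {
  out <- callsVec
  out[callsVec == "n" & expectedReads >= minExpected] <- "b"
  out
}

#' Place a deletion marker in a genetic map by minimum divergence
#'
#' Divergence of the deletion's genotype sequence to every placed marker's
#' oriented sequence is mismatches over informative overlaps, minimised
#' over both phase assignments. The deletion is placed at the position of
#' the arg-min marker with the minimising phase if the minimum divergence
#' and informative overlap pass the thresholds, else left unplaced.
#'
#' @param delSeq genotype sequence over \code{a/b/n} for the deletion
#'   marker (gametes in the same order as the map's marker sequences).
#' @param map a \linkS4class{GeneticMap} built by
#'   \code{\link{buildGeneticMap}} (carries oriented marker sequences).
#' @param markerSeqs optional matrix overriding
#'   \code{attr(map, "markerSeqs")}.
#' @param maxDivergence placement ceiling (default 0.1).
#' @param minOverlap minimum informative overlap in gametes (default 30).
#' @return list with \code{placed} (logical), and when placed:
#'   \code{group}, \code{nearestMarker}, \code{cM}, \code{phase} (0/1),
#'   \code{divergence}, \code{overlap}.
#' @export
integrateDeletionMarker <- function(delSeq, map, markerSeqs = NULL,
                                    maxDivergence = 0.1, minOverlap = 30) {
  if (is.null(markerSeqs)) markerSeqs <- attr(map, "markerSeqs")
  e <- mapEntries(map)
  if (is.null(markerSeqs) || nrow(e) == 0L) stop("empty map")
  placedIds <- intersect(e$marker, rownames(markerSeqs))
  best <- list(div = Inf)
  for (id in placedIds) {
    ms <- markerSeqs[id, ]
    ov <- delSeq != "n" & ms != "n"
    n <- sum(ov)
    if (n < minOverlap) next
    mism <- sum(delSeq[ov] != ms[ov])
    d0 <- mism / n
    d1 <- (n - mism) / n
    d <- min(d0, d1)
    if (d < best$div) {
      row <- e[e$marker == id, ][1L, ]
      best <- list(div = d, phase = as.integer(d1 < d0), marker = id,
                   group = row$linkage_group, cM = row$cM, overlap = n)
    }
  }
  if (!is.finite(best$div) || best$div > maxDivergence)
    return(list(placed = FALSE,
                divergence = if (is.finite(best$div)) best$div else NA_real_))
  list(placed = TRUE, group = best$group, nearestMarker = best$marker,
       cM = best$cM, phase = best$phase, divergence = best$div,
       overlap = best$overlap)
}
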
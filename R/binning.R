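#' Per-marker haplotype-A alleles after map-level phasing
#'
#' Combines the within-contig marker orientations (from
#' \code{\link{phaseAllContigs}}) with the per-contig map phase values to
#' give, for every phased SNP marker, the base carried by haplotype A of
#' its linkage group.
#'
#' @param phased a phased \linkS4class{GenotypeMatrix} (metadata carries
#'   per-contig orientations).
#' @param map a \linkS4class{GeneticMap}.
#' @return data.frame with \code{marker}, \code{contig}, \code{pos}
#'   (1-based), \code{group}, \code{baseA}, \code{baseB}.
#' @export
phasedAlleleTable <- function(phased, map) {
  rr <- rowRanges(phased)
  ori <- metadata(phased)$orientation
  stopifnot(!is.null(ori))
  ctg <- as.character(seqnames(rr))
  grp <- contigGroup(map)
  ph <- contigPhase(map)
  oriVec <- integer(length(rr))
  for (cn in unique(ctg)) {
    rows <- which(ctg == cn)
    o <- ori[[cn]]
    oriVec[rows] <- if (is.null(o)) NA_integer_ else o
  }
  ref <- mcols(rr)$ref
  alt <- mcols(rr)$alt
  ## alt belongs to haplotype A iff orientation +1 and contig not flipped,
  ## or orientation -1 and contig flipped
  flip <- ph[ctg] == 1L
  altToA <- (oriVec == 1L) == !flip
  df <- data.frame(marker = names(rr), contig = ctg,
                   pos = GenomicRanges::start(rr),
                   group = unname(grp[ctg]),
                   ref = ref, alt = alt,
                   baseA = ifelse(altToA, alt, ref),
                   baseB = ifelse(altToA, ref, alt))
  df[!is.na(df$group), , drop = FALSE]
}

#' Assign one long read to a haplotype bin
#'
#' Case 1: the read covers at least one phased SNP marker — the read base
#' at each covered marker (substitution base, or the reference base when
#' no substitution is recorded) votes for the haplotype carrying that
#' allele; the majority wins and a tie is broken at random. Case 2: no SNP
#' vote but overlap with a placed deletion region — the read is assigned
#' to the haplotype possessing the region. Case 3: overlap only with
#' conserved regions — assigned uniformly at random. Otherwise, or when
#' the contig is not in the map, the read is unassigned. Bases matching
#' neither allele abstain.
#'
#' @param alignment one-row data.frame (contig, tstart, tend 0-based
#'   half-open).
#' @param substitutions data.frame (tpos 0-based, readBase) for this read.
#' @param alleles phased allele table from \code{\link{phasedAlleleTable}}.
#' @param deletions optional data.frame (contig, start, end 1-based,
#'   group, carrierHap in A/B) of placed deletion regions.
#' @param conserved optional data.frame (contig, start, end 1-based) of
#'   conserved regions.
#' @param contigGroups named vector contig -> linkage group.
#' @return one-row data.frame: readId-free assignment with \code{group},
#'   \code{haplotype} (A/B/unassigned), \code{evidence}
#'   (snp_vote/deletion/random/none), \code{votesA}, \code{votesB}.
#' @export
assignRead <- function(alignment, substitutions, alleles,
                       deletions = NULL, conserved = NULL,
                       contigGroups = NULL) {
  ctg <- alignment$contig
  grp <- if (!is.null(contigGroups)) unname(contigGroups[ctg]) else NA
  res <- data.frame(group = NA_character_, haplotype = "unassigned",
                    evidence = "none", votesA = 0L, votesB = 0L)
  if (is.na(grp)) return(res)
  mk <- alleles[alleles$contig == ctg &
                  alleles$pos - 1L >= alignment$tstart &
                  alleles$pos - 1L < alignment$tend, , drop = FALSE]
  if (nrow(mk)) {
    subBase <- substitutions$readBase[match(mk$pos - 1L,
                                            substitutions$tpos)]
    base <- ifelse(is.na(subBase), mk$ref, toupper(subBase))
    vA <- sum(base == mk$baseA)
    vB <- sum(base == mk$baseB)
    if (vA + vB > 0L) {
      hap <- if (vA > vB) "A" else if (vB > vA) "B" else
        sample(c("A", "B"), 1L)
      return(data.frame(group = grp, haplotype = hap,
                        evidence = "snp_vote", votesA = vA, votesB = vB))
    }
  }
  if (!is.null(deletions) && nrow(deletions)) {
    dd <- deletions[deletions$contig == ctg &
                      deletions$start - 1L < alignment$tend &
                      deletions$end > alignment$tstart, , drop = FALSE]
    if (nrow(dd))
      return(data.frame(group = grp, haplotype = dd$carrierHap[1L],
                        evidence = "deletion", votesA = 0L, votesB = 0L))
  }
  if (!is.null(conserved) && nrow(conserved)) {
    cc <- conserved[conserved$contig == ctg &
                      conserved$start - 1L < alignment$tend &
                      conserved$end > alignment$tstart, , drop = FALSE]
    if (nrow(cc))
      return(data.frame(group = grp, haplotype = sample(c("A", "B"), 1L),
                        evidence = "random", votesA = 0L, votesB = 0L))
  }
  res
}

#' Bin a stream of long reads into haplotype-specific clusters
#'
#' Vectorised equivalent of applying \code{\link{assignRead}} to every
#' read: SNP votes by overlap join of reads and phased markers, then
#' deletion overlap, then conserved-region random assignment, with
#' duplicate read ids collapsed to their first alignment. Every input read
#' appears exactly once across bins plus unassigned.
#'
#' @param alignments data.frame (readId, contig, tstart, tend 0-based
#'   half-open) — one best alignment per read.
#' @param substitutions data.frame (readId, tpos 0-based, readBase).
#' @param alleles phased allele table from \code{\link{phasedAlleleTable}}.
#' @param deletions,conserved,contigGroups see \code{\link{assignRead}}.
#' @param minPurity optional winner-votes/total threshold; mixed-vote reads
#'   below it fall through to the deletion/conserved/random cascade.
#' @param seed integer seed for the random assignments.
#' @return list with \code{assignments} (readId, group, haplotype,
#'   evidence, votesA, votesB) and \code{summary} (fraction assigned and
#'   per-evidence counts).
#' @export
binReads <- function(alignments, substitutions, alleles,
                     deletions = NULL, conserved = NULL,
                     contigGroups = NULL, minPurity = 0, seed = 1L) {
  set.seed(seed)
  if (anyDuplicated(alignments$readId)) {
    warning("duplicate read ids; keeping first alignment of each")
    alignments <- alignments[!duplicated(alignments$readId), , drop = FALSE]
  }
  n <- nrow(alignments)
  out <- data.frame(readId = alignments$readId,
                    group = NA_character_, haplotype = "unassigned",
                    evidence = "none", votesA = 0L, votesB = 0L,
                    stringsAsFactors = FALSE)
  if (n == 0L)
    return(list(assignments = out,
                summary = list(fractionAssigned = NA_real_,
                               evidence = table(character(0)))))
  grp <- if (!is.null(contigGroups))
    unname(contigGroups[alignments$contig]) else rep(NA, n)
  placed <- !is.na(grp)
  out$group[placed] <- grp[placed]

  ## --- case 1: SNP votes via overlap join -------------------------------
  alnGr <- GenomicRanges::GRanges(alignments$contig,
    IRanges::IRanges(alignments$tstart + 1L, alignments$tend))
  mkGr <- GenomicRanges::GRanges(alleles$contig,
    IRanges::IRanges(alleles$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(alnGr, mkGr)
  if (length(hits)) {
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    readId <- alignments$readId[qi]
    mk <- alleles[si, , drop = FALSE]
    key <- paste(readId, mk$contig, mk$pos - 1L)
    skey <- paste(substitutions$readId, alignments$contig[
      match(substitutions$readId, alignments$readId)], substitutions$tpos)
    subBase <- toupper(substitutions$readBase[match(key, skey)])
    base <- ifelse(is.na(subBase), mk$ref, subBase)
    vA <- as.integer(base == mk$baseA)
    vB <- as.integer(base == mk$baseB)
    keep <- placed[qi]
    agg <- rowsum(cbind(vA, vB)[keep, , drop = FALSE],
                  group = readId[keep])
    ids <- rownames(agg)
    tot <- agg[, 1L] + agg[, 2L]
    winner <- pmax(agg[, 1L], agg[, 2L])
    voted <- tot > 0L
    pure <- voted & (winner / pmax(tot, 1L) >= minPurity)
    hap <- ifelse(agg[, 1L] > agg[, 2L], "A",
                  ifelse(agg[, 2L] > agg[, 1L], "B", NA))
    tieIdx <- which(pure & is.na(hap))
    if (length(tieIdx))
      hap[tieIdx] <- sample(c("A", "B"), length(tieIdx), replace = TRUE)
    ri <- match(ids[pure], out$readId)
    out$haplotype[ri] <- hap[pure]
    out$evidence[ri] <- "snp_vote"
    riAll <- match(ids, out$readId)
    out$votesA[riAll] <- agg[, 1L]
    out$votesB[riAll] <- agg[, 2L]
  }

  ## --- case 2: deletion overlap ----------------------------------------
  pending <- placed & out$evidence == "none"
  if (!is.null(deletions) && nrow(deletions) && any(pending)) {
    delGr <- GenomicRanges::GRanges(deletions$contig,
      IRanges::IRanges(deletions$start, deletions$end))
    hits <- GenomicRanges::findOverlaps(alnGr[pending], delGr)
    if (length(hits)) {
      first <- !duplicated(S4Vectors::queryHits(hits))
      qi <- which(pending)[S4Vectors::queryHits(hits)[first]]
      out$haplotype[qi] <-
        deletions$carrierHap[S4Vectors::subjectHits(hits)[first]]
      out$evidence[qi] <- "deletion"
    }
  }

  ## --- case 3: conserved-region random assignment ----------------------
  pending <- placed & out$evidence == "none"
  if (!is.null(conserved) && nrow(conserved) && any(pending)) {
    conGr <- GenomicRanges::GRanges(conserved$contig,
      IRanges::IRanges(conserved$start, conserved$end))
    hits <- GenomicRanges::findOverlaps(alnGr[pending], conGr)
    if (length(hits)) {
      qi <- which(pending)[unique(S4Vectors::queryHits(hits))]
      out$haplotype[qi] <- sample(c("A", "B"), length(qi), replace = TRUE)
      out$evidence[qi] <- "random"
    }
  }
  out$group[out$haplotype == "unassigned"] <- NA_character_

  assigned <- out$haplotype != "unassigned"
  list(assignments = out,
       summary = list(fractionAssigned = mean(assigned),
                      evidence = table(out$evidence)))
}
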
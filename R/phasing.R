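#' Phase the SNPs of one contig by bi-marker majority voting
#'
#' For each pair of adjacent markers, gametes with both calls non-missing
#' vote: S counts gametes with the same raw symbol at both markers (RR or
#' AA), D counts gametes with different symbols. The second marker keeps
#' the orientation of the first when S >= D and flips otherwise; chaining
#' this along the contig orients every marker. Orientation +1 means the
#' alternative allele belongs to haplotype A; the first marker is +1 by
#' convention, so the solution is reported up to a global flip. Ties
#' (S == D) carry the previous orientation forward and are flagged.
#'
#' @param rawCalls character matrix over \code{R/A/N}, markers (rows,
#'   ordered by position) by gametes (columns).
#' @param exclude gamete ids (column names) excluded from the S/D votes,
#'   e.g. doublets flagged by \code{\link{screenPloidy}}; their calls are
#'   still phased in the output.
#'
#' @return list with \code{orientation} (+1/-1 per marker), \code{tie}
#'   (logical per adjacency, length nrow-1), and \code{phasedCalls}
#'   (matrix over \code{a/b/n}, all gametes).
#' @export
phaseContig <- function(rawCalls, exclude = character(0)) {
  stopifnot(is.matrix(rawCalls), nrow(rawCalls) >= 1L)
  m <- nrow(rawCalls)
  vote <- rawCalls[, !(colnames(rawCalls) %in% exclude), drop = FALSE]
  orientation <- rep(1L, m)
  tie <- logical(max(0L, m - 1L))
  if (m > 1L) {
    for (i in 2:m) {
      x <- vote[i - 1L, ]
      z <- vote[i, ]
      both <- x != "N" & z != "N"
      S <- sum(x[both] == z[both])
      D <- sum(both) - S
      orientation[i] <- if (S >= D) orientation[i - 1L] else
        -orientation[i - 1L]
      tie[i - 1L] <- (S == D)
    }
  }
  phased <- matrix("n", m, ncol(rawCalls),
                   dimnames = dimnames(rawCalls))
  plus <- orientation == 1L
  phased[plus, ][rawCalls[plus, , drop = FALSE] == "A"] <- "a"
  phased[plus, ][rawCalls[plus, , drop = FALSE] == "R"] <- "b"
  phased[!plus, ][rawCalls[!plus, , drop = FALSE] == "A"] <- "b"
  phased[!plus, ][rawCalls[!plus, , drop = FALSE] == "R"] <- "a"
  list(orientation = orientation, tie = tie, phasedCalls = phased)
}

#' Phase every contig of a genotype matrix
#'
#' Splits the unphased matrix by contig (rows ordered by position within
#' contig), applies \code{\link{phaseContig}} to each, and returns a phased
#' \linkS4class{GenotypeMatrix} with per-contig orientations stored in its
#' metadata.
#'
#' @param gm an unphased \linkS4class{GenotypeMatrix}.
#' @param exclude gamete ids excluded from the phasing votes.
#' @return A phased \linkS4class{GenotypeMatrix};
#'   \code{metadata()$orientation} holds a named list of per-contig
#'   orientation vectors, \code{metadata()$tie} the tie flags.
#' @export
phaseAllContigs <- function(gm, exclude = character(0)) {
  stopifnot(is(gm, "GenotypeMatrix"), !isPhased(gm))
  rr <- rowRanges(gm)
  ord <- order(as.character(seqnames(rr)), GenomicRanges::start(rr))
  gm <- gm[ord, ]
  rr <- rowRanges(gm)
  raw <- calls(gm)
  ctg <- as.character(seqnames(rr))
  phased <- raw
  orientations <- list()
  ties <- list()
  for (rows in split(seq_len(nrow(raw)), factor(ctg, unique(ctg)))) {
    ph <- phaseContig(raw[rows, , drop = FALSE], exclude)
    phased[rows, ] <- ph$phasedCalls
    cname <- ctg[rows[1L]]
    orientations[[cname]] <- ph$orientation
    ties[[cname]] <- ph$tie
  }
  out <- GenotypeMatrix(phased, rr, colData = colData(gm), phased = TRUE)
  metadata(out)$orientation <- orientations
  metadata(out)$tie <- ties
  out
}

#' A gamete's haplotype call string along one contig
#'
#' @param phased a phased \linkS4class{GenotypeMatrix}.
#' @param gamete a gamete id.
#' @param contig optional contig id to restrict to.
#' @return character vector over \code{a/b/n}, one symbol per marker.
#' @export
gameteHaplotypeString <- function(phased, gamete, contig = NULL) {
  stopifnot(isPhased(phased))
  if (!gamete %in% gameteIds(phased)) stop("unknown gamete id: ", gamete)
  m <- calls(phased)[, gamete]
  if (!is.null(contig))
    m <- m[as.character(seqnames(rowRanges(phased))) == contig]
  m
}

#' Find recombinant gametes between two markers
#'
#' Given the genotype sequences of two markers over the same gametes,
#' returns the 1-based indices of gametes whose calls are both non-missing
#' and differ — the gametes with a crossover between the two markers.
#'
#' @param calls1,calls2 genotype sequences over \code{a/b/n}: character
#'   vectors of single symbols, or single strings that are split.
#' @return sorted integer vector of recombinant gamete indices.
#' @export
findRecombinants <- function(calls1, calls2) {
  if (length(calls1) == 1L && nchar(calls1) > 1L)
    calls1 <- strsplit(calls1, "")[[1]]
  if (length(calls2) == 1L && nchar(calls2) > 1L)
    calls2 <- strsplit(calls2, "")[[1]]
  if (length(calls1) != length(calls2))
    stop("genotype sequences differ in length")
  which(calls1 != "n" & calls2 != "n" & calls1 != calls2)
}

#' Impute virtual markers at the two ends of each contig
#'
#' For each gamete and contig, the head (tail) virtual-marker symbol is the
#' symbol of the first (last) supported block of the gamete's haplotype
#' call string, using the same minimum-support segmentation as the
#' crossover caller so that isolated genotyping errors at contig ends do
#' not leak into the map. Gametes with no calls on the contig get
#' \code{n}. An \code{aa}/\code{bb} head-tail pair means no crossover on
#' the contig for that gamete; \code{ab}/\code{ba} means a crossover
#' inside.
#'
#' @param phased a phased \linkS4class{GenotypeMatrix}.
#' @param minSupport segmentation support threshold (default 5).
#' @return list of two character matrices, \code{head} and \code{tail}
#'   (contigs x gametes, symbols over \code{a/b/n}).
#' @export
imputeVirtualMarkers <- function(phased, minSupport = 5) {
  stopifnot(isPhased(phased))
  m <- calls(phased)
  ctg <- as.character(seqnames(rowRanges(phased)))
  contigs <- unique(ctg)
  headM <- matrix("n", length(contigs), ncol(m),
                  dimnames = list(contigs, colnames(m)))
  tailM <- headM
  for (cn in contigs) {
    sub <- m[ctg == cn, , drop = FALSE]
    for (j in seq_len(ncol(sub))) {
      if (!any(sub[, j] != "n")) next
      b <- segmentCalls(sub[, j], minSupport)
      headM[cn, j] <- b$symbol[1L]
      tailM[cn, j] <- b$symbol[nrow(b)]
    }
  }
  list(head = headM, tail = tailM)
}
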
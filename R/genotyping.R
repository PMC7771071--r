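#' Call a gamete's genotype at a SNP marker
#'
#' Haploid base calling from ref/alt supporting read counts. \code{N} if no
#' reads; the single observed allele if only one is seen; with conflicting
#' reads, the majority allele is called when majority/minority is at least
#' the dominance ratio, else \code{N}.
#'
#' @param refCount,altCount non-negative read counts (vectorised).
#' @param dominanceRatio majority/minority ratio required to resolve a
#'   conflict (default 3).
#' @return character vector over \code{R/A/N}.
#' @export
callSnpGenotype <- function(refCount, altCount, dominanceRatio = 3) {
  stopifnot(all(refCount >= 0), all(altCount >= 0))
  hi <- pmax(refCount, altCount)
  lo <- pmin(refCount, altCount)
  out <- rep("N", length(refCount))
  out[refCount > 0 & altCount == 0] <- "R"
  out[altCount > 0 & refCount == 0] <- "A"
  conflict <- refCount > 0 & altCount > 0
  resolved <- conflict & (hi / lo >= dominanceRatio) & (refCount != altCount)
  out[resolved & refCount > altCount] <- "R"
  out[resolved & altCount > refCount] <- "A"
  out
}

#' Call a gamete's genotype at a deletion marker
#'
#' Presence/absence genotyping by read count in the region: \code{a} means
#' reads are present (the gamete carries the haplotype that has the
#' region), \code{n} means absence of evidence. Also returns the RPKM
#' (reads per kb of region per million mapped reads).
#'
#' @param count aligned read count in the region (vectorised).
#' @param regionLength region length in bp.
#' @param totalMapped total mapped reads of the gamete.
#' @param minReads minimum reads for a presence call (default 1).
#' @return data.frame with columns \code{call} (\code{a}/\code{n}) and
#'   \code{rpkm} (NA when \code{totalMapped} is 0).
#' @export
callDeletionGenotype <- function(count, regionLength, totalMapped,
                                 minReads = 1) {
  stopifnot(all(regionLength > 0), all(count >= 0))
  rpkm <- ifelse(totalMapped > 0,
                 count / ((regionLength / 1e3) * (totalMapped / 1e6)),
                 NA_real_)
  data.frame(call = ifelse(count >= minReads, "a", "n"), rpkm = rpkm)
}

#' Build the gametes-by-markers genotype matrix
#'
#' Applies \code{\link{callSnpGenotype}} to a long observation table and
#' assembles the calls into a \linkS4class{GenotypeMatrix} over the given
#' SNP markers.
#'
#' @param observations data.frame with columns \code{gamete},
#'   \code{marker}, \code{refCount}, \code{altCount} (at most one row per
#'   gamete/marker pair).
#' @param markers \code{GRanges} of SNP markers; names are marker ids.
#' @param gametes character vector of gamete ids (defaults to those seen).
#' @param dominanceRatio see \code{\link{callSnpGenotype}}.
#' @return An unphased \linkS4class{GenotypeMatrix}.
#' @export
buildGenotypeMatrix <- function(observations, markers, gametes = NULL,
                                dominanceRatio = 3) {
  if (anyDuplicated(observations[c("gamete", "marker")]))
    stop("more than one observation row per (gamete, marker)")
  if (is.null(gametes)) gametes <- sort(unique(observations$gamete))
  ids <- names(markers)
  m <- matrix("N", length(ids), length(gametes),
              dimnames = list(ids, gametes))
  obs <- observations[observations$marker %in% ids &
                        observations$gamete %in% gametes, , drop = FALSE]
  if (nrow(obs)) {
    g <- callSnpGenotype(obs$refCount, obs$altCount, dominanceRatio)
    m[cbind(match(obs$marker, ids), match(obs$gamete, gametes))] <- g
  }
  GenotypeMatrix(m, markers, phased = FALSE)
}

#' Screen gametes for doublets by genotype-transition rate
#'
#' For each gamete, counts inter-genotype transitions (a to b or b to a)
#' between consecutive non-missing phased calls within each contig, summed
#' over contigs, and compares the transition ratio to a per-100-marker
#' threshold. A haploid nucleus shows few transitions (genotyping error and
#' genuine crossovers only), while pooled nuclei from two gametes switch
#' constantly. Invariant under a global a/b relabeling.
#'
#' @param phased a phased \linkS4class{GenotypeMatrix} (calls in
#'   \code{a/b/n}).
#' @param threshold transitions per 100 covered markers above which
#'   (strictly) a gamete is labeled a doublet (default 5).
#' @param minCovered below this many covered markers the gamete is labeled
#'   haploid with a warning flag (too little information).
#'
#' @return A \code{DataFrame} with per-gamete \code{covered},
#'   \code{transitions}, \code{ratio}, \code{label}
#'   (\code{haploid}/\code{doublet}) and \code{lowInformation}.
#' @export
screenPloidy <- function(phased, threshold = 5, minCovered = 30) {
  stopifnot(isPhased(phased))
  m <- calls(phased)
  if (ncol(m) == 0L)
    return(S4Vectors::DataFrame(covered = integer(0),
                                transitions = integer(0), ratio = numeric(0),
                                label = character(0),
                                lowInformation = logical(0)))
  ctg <- as.character(seqnames(rowRanges(phased)))
  covered <- colSums(m != "n")
  transitions <- integer(ncol(m))
  for (rows in split(seq_len(nrow(m)), ctg)) {
    sub <- m[rows, , drop = FALSE]
    for (j in seq_len(ncol(sub))) {
      x <- sub[, j]
      x <- x[x != "n"]
      if (length(x) > 1L)
        transitions[j] <- transitions[j] + sum(x[-1] != x[-length(x)])
    }
  }
  ratio <- ifelse(covered > 0, transitions / covered, 0)
  lowInfo <- covered < minCovered
  label <- ifelse(!lowInfo & ratio > threshold / 100, "doublet", "haploid")
  S4Vectors::DataFrame(covered = as.integer(covered),
                       transitions = transitions, ratio = ratio,
                       label = label, lowInformation = lowInfo,
                       row.names = colnames(m))
}
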
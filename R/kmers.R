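#' Count canonical k-mers with a coverage band filter
#'
#' Canonical form is the lexicographic minimum of a k-mer and its reverse
#' complement. Windows containing non-ACGT symbols are skipped. The
#' returned multiset is filtered to counts within [minCount, maxCount]
#' inclusive.
#'
#' @param sequences \code{DNAStringSet} or character vector of sequences
#'   (e.g. from \code{Biostrings::readDNAStringSet}).
#' @param k odd k-mer size, at least 11 for genome-scale specificity
#'   (default 21); smaller odd values are allowed for testing.
#' @param minCount,maxCount inclusive count band.
#' @return named integer vector: canonical k-mer -> count.
#' @export
countKmers <- function(sequences, k = 21, minCount = 1, maxCount = Inf) {
  stopifnot(k %% 2 == 1)
  seqs <- as.character(sequences)
  kmers <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(toupper(s), 1:(n - k + 1), k:n)
  }), use.names = FALSE)
  if (!length(kmers)) return(stats::setNames(integer(0), character(0)))
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  if (!length(kmers)) return(stats::setNames(integer(0), character(0)))
  kmers <- canonicalKmers(kmers)
  tab <- table(kmers)
  cnt <- as.integer(tab)
  names(cnt) <- names(tab)
  cnt[cnt >= minCount & cnt <= maxCount]
}

#' Canonicalise k-mers
#'
#' @param kmers character vector of ACGT k-mers.
#' @return the lexicographic minimum of each k-mer and its reverse
#'   complement (idempotent).
#' @export
canonicalKmers <- function(kmers) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(kmers)))
  pmin(kmers, rc)
}

#' Build a specific k-mer set from three count sources
#'
#' Keeps k-mers whose count in the target source lies within the target
#' band, that are absent from the exclusion source (count strictly below
#' its floor; a single stray observation is tolerated as sequencing
#' error), and that are present in the requirement source within its
#' band. Pure set algebra; order-independent.
#'
#' @param target,exclude,require named count vectors (as from
#'   \code{\link{countKmers}} without band filtering).
#' @param targetBand inclusive count band in the target (default c(10, 60)).
#' @param excludeFloor counts at or above this in \code{exclude} disqualify
#'   a k-mer (default 2, i.e. "coverage over 1x" means seen at least twice).
#' @param requireBand inclusive count band in \code{require}
#'   (default c(10, 300)).
#' @return character vector of canonical k-mers.
#' @export
buildSpecificSet <- function(target, exclude, require,
                             targetBand = c(10, 60), excludeFloor = 2,
                             requireBand = c(10, 300)) {
  keep <- names(target)[target >= targetBand[1] & target <= targetBand[2]]
  exc <- names(exclude)[exclude >= excludeFloor]
  keep <- setdiff(keep, exc)
  req <- names(require)[require >= requireBand[1] &
                          require <= requireBand[2]]
  intersect(keep, req)
}

#' Summarise assembly- and parent-specific k-mer sets
#'
#' Intersects the two haplotype-assembly-specific sets with the two
#' parent-specific sets, giving the four counts on which haplotyping
#' precision rests.
#'
#' @param rC,rO haplotype-assembly-specific k-mer sets (character).
#' @param pC,pO parent-specific k-mer sets.
#' @param k k-mer size (annotation only).
#' @return list of class \code{KmerSetSummary}: set sizes and the four
#'   intersection counts \code{rC_pC}, \code{rC_pO}, \code{rO_pC},
#'   \code{rO_pO}.
#' @export
kmerSetSummary <- function(rC, rO, pC, pO, k = 21) {
  s <- list(k = k,
            nrC = length(rC), nrO = length(rO),
            npC = length(pC), npO = length(pO),
            rC_pC = length(intersect(rC, pC)),
            rC_pO = length(intersect(rC, pO)),
            rO_pC = length(intersect(rO, pC)),
            rO_pO = length(intersect(rO, pO)))
  class(s) <- "KmerSetSummary"
  s
}

#' Build a KmerSetSummary directly from intersection counts
#'
#' @param rC_pC,rC_pO,rO_pC,rO_pO the four intersection counts.
#' @param k k-mer size (annotation only).
#' @return a \code{KmerSetSummary}.
#' @export
kmerSummaryFromCounts <- function(rC_pC, rC_pO, rO_pC, rO_pO, k = 21) {
  s <- list(k = k, nrC = NA_integer_, nrO = NA_integer_,
            npC = NA_integer_, npO = NA_integer_,
            rC_pC = rC_pC, rC_pO = rC_pO, rO_pC = rO_pC, rO_pO = rO_pO)
  class(s) <- "KmerSetSummary"
  s
}

#' Haplotyping precision from k-mer set intersections
#'
#' Pairs each haplotype assembly with a parent (the pairing maximising the
#' average is chosen and reported) and computes, per haplotype, 100 times
#' the matched-parent intersection over the total parent-specific k-mers
#' found in that assembly; the average weights each haplotype by its
#' denominator. A zero denominator leaves that haplotype's precision
#' undefined and excluded from the average with a warning.
#'
#' @param summary a \code{KmerSetSummary}.
#' @return list with \code{pairing} (named character), \code{precision}
#'   (named numeric per haplotype, percent) and \code{average} (percent).
#' @export
haplotypingPrecision <- function(summary) {
  stopifnot(inherits(summary, "KmerSetSummary"))
  prec <- function(match, mismatch) {
    den <- match + mismatch
    if (den == 0) NA_real_ else 100 * match / den
  }
  ## pairing 1: rC-pC / rO-pO; pairing 2: rC-pO / rO-pC
  avg <- function(m1, x1, m2, x2) {
    den <- (m1 + x1) + (m2 + x2)
    if (den == 0) return(NA_real_)
    100 * (m1 + m2) / den
  }
  a1 <- avg(summary$rC_pC, summary$rC_pO, summary$rO_pO, summary$rO_pC)
  a2 <- avg(summary$rC_pO, summary$rC_pC, summary$rO_pC, summary$rO_pO)
  if (!is.na(a1) && (is.na(a2) || a1 >= a2)) {
    pairing <- c(rC = "pC", rO = "pO")
    p <- c(rC = prec(summary$rC_pC, summary$rC_pO),
           rO = prec(summary$rO_pO, summary$rO_pC))
    average <- a1
  } else {
    pairing <- c(rC = "pO", rO = "pC")
    p <- c(rC = prec(summary$rC_pO, summary$rC_pC),
           rO = prec(summary$rO_pC, summary$rO_pO))
    average <- a2
  }
  if (any(is.na(p)))
    warning("zero denominator: precision undefined for ",
            paste(names(p)[is.na(p)], collapse = ","),
            "; excluded from average")
  list(pairing = pairing, precision = p, average = average)
}
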
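#' SNP marker filter configuration
#'
#' Bounds for selecting allelic heterozygous SNPs from pooled-gamete
#' candidate calls. All bounds are inclusive. The defaults correspond to a
#' pooled depth whose genome-wide mode is 208x; use
#' \code{\link{rescaleDepthBounds}} to adapt the depth bounds to data
#' sequenced at a different pooled depth.
#'
#' @param freqLow,freqHigh alternative allele frequency bounds.
#' @param altLow,altHigh alternative allele read-count bounds.
#' @param totalLow,totalHigh total depth bounds.
#' @param referenceModeDepth the pooled mode depth the depth bounds refer to.
#' @return A list of class \code{SnpFilterConfig}.
#' @export
snpFilterConfig <- function(freqLow = 0.38, freqHigh = 0.62,
                            altLow = 60, altHigh = 140,
                            totalLow = 120, totalHigh = 280,
                            referenceModeDepth = 208) {
  stopifnot(freqLow >= 0, freqLow < freqHigh, freqHigh <= 1,
            altLow >= 0, altLow <= altHigh,
            totalLow > 0, totalLow <= totalHigh)
  structure(as.list(environment()), class = "SnpFilterConfig")
}

#' Rescale SNP-filter depth bounds to an observed pooled mode depth
#'
#' The absolute depth bounds in \code{\link{snpFilterConfig}} are relative
#' to the pooled mode depth of the dataset they were derived from. This
#' helper scales the alt-depth and total-depth bounds proportionally to the
#' mode depth observed in the data at hand; the frequency bounds are
#' depth-free and unchanged.
#'
#' @param config a \code{SnpFilterConfig}.
#' @param modeDepth observed genome-wide pooled mode depth (x).
#' @return A rescaled \code{SnpFilterConfig}.
#' @export
rescaleDepthBounds <- function(config, modeDepth) {
  stopifnot(modeDepth > 0)
  f <- modeDepth / config$referenceModeDepth
  snpFilterConfig(config$freqLow, config$freqHigh,
                  config$altLow * f, config$altHigh * f,
                  config$totalLow * f, config$totalHigh * f,
                  referenceModeDepth = modeDepth)
}

#' Region classifier configuration
#'
#' @param minLength minimum length (bp) for a marker-free region to be
#'   classified; shorter gaps stay ordinary SNP territory.
#' @param depthCeiling pooled mean depth (x) at or below which a
#'   marker-free region is called a deletion (present in one haplotype
#'   only); above it the region is conserved. The default valley of 146x
#'   sits between the half-coverage and full-coverage peaks of a 208x
#'   pooled depth histogram.
#' @return A list of class \code{RegionClassifierConfig}.
#' @export
regionClassifierConfig <- function(minLength = 2000, depthCeiling = 146) {
  stopifnot(minLength > 0, depthCeiling > 0)
  structure(list(minLength = minLength, depthCeiling = depthCeiling),
            class = "RegionClassifierConfig")
}

#' Select allelic SNP markers from candidate calls
#'
#' A candidate is retained iff its alternative allele frequency, alternative
#' allele depth and total depth all lie within the configured inclusive
#' bounds. Candidates with zero total depth are rejected with reason
#' \code{"zero depth"}.
#'
#' @param candidates data.frame with columns \code{contig}, \code{pos}
#'   (1-based), \code{ref}, \code{alt}, \code{altDepth}, \code{totalDepth}
#'   (e.g. from \code{\link{readVcfCandidates}}).
#' @param config a \code{\link{snpFilterConfig}}.
#' @param keepReasons attach a \code{rejectionReason} attribute tabulating
#'   why candidates were dropped.
#'
#' @return A \code{GRanges} of retained SNP markers sorted by (contig,
#'   position) with mcols \code{kind = "snp"}, \code{ref}, \code{alt},
#'   \code{altDepth}, \code{totalDepth}.
#' @export
selectSnpMarkers <- function(candidates, config = snpFilterConfig(),
                             keepReasons = FALSE) {
  if (nrow(candidates) == 0L) {
    gr <- GenomicRanges::GRanges()
    return(gr)
  }
  tot <- candidates$totalDepth
  alt <- candidates$altDepth
  reason <- rep(NA_character_, nrow(candidates))
  zero <- tot == 0
  reason[zero] <- "zero depth"
  freq <- ifelse(zero, NA_real_, alt / tot)
  badFreq <- !zero & (freq < config$freqLow | freq > config$freqHigh)
  badAlt <- !zero & (alt < config$altLow | alt > config$altHigh)
  badTot <- !zero & (tot < config$totalLow | tot > config$totalHigh)
  reason[is.na(reason) & badFreq] <- "frequency"
  reason[is.na(reason) & badAlt] <- "alt depth"
  reason[is.na(reason) & badTot] <- "total depth"
  keep <- is.na(reason)
  kept <- candidates[keep, , drop = FALSE]
  gr <- GenomicRanges::GRanges(kept$contig,
    IRanges::IRanges(kept$pos, width = 1L),
    kind = rep("snp", nrow(kept)), ref = kept$ref, alt = kept$alt,
    altDepth = kept$altDepth, totalDepth = kept$totalDepth)
  names(gr) <- sprintf("%s_%d", kept$contig, kept$pos)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  if (keepReasons)
    attr(gr, "rejectionReason") <- table(reason[!keep])
  gr
}

#' Find maximal marker-free intervals on each contig
#'
#' Returns maximal intervals (including contig ends) that contain no SNP
#' marker and are strictly longer than the configured minimum. Contigs with
#' no SNP at all yield one full-length interval.
#'
#' @param markers \code{GRanges} of SNP markers (1-based single-base).
#' @param contigLengths named integer vector of contig lengths.
#' @param config a \code{\link{regionClassifierConfig}}.
#'
#' @return A \code{GRanges} of marker-free intervals (1-based closed).
#' @export
findMarkerlessRegions <- function(markers, contigLengths,
                                  config = regionClassifierConfig()) {
  out <- list()
  snp <- markers[mcols(markers)$kind == "snp"]
  bad <- GenomicRanges::start(snp) >
    contigLengths[as.character(seqnames(snp))]
  if (any(bad, na.rm = TRUE))
    stop("SNP marker position beyond contig length: ",
         paste(names(snp)[which(bad)], collapse = ","))
  for (ctg in names(contigLengths)) {
    L <- contigLengths[[ctg]]
    pos <- sort(GenomicRanges::start(snp[seqnames(snp) == ctg]))
    starts <- c(1L, pos + 1L)
    ends <- c(pos - 1L, L)
    w <- ends - starts + 1L
    keep <- w > config$minLength
    if (any(keep))
      out[[ctg]] <- GenomicRanges::GRanges(ctg,
        IRanges::IRanges(starts[keep], ends[keep]))
  }
  if (!length(out)) return(GenomicRanges::GRanges())
  gr <- do.call(c, unname(out))
  mcols(gr)$kind <- NA_character_
  gr
}

#' Classify a marker-free region as deletion or conserved
#'
#' A region whose mean pooled-gamete depth is at or below the ceiling is a
#' deletion (present in only one haplotype, hence covered by roughly half
#' the reads); above the ceiling it is conserved (shared by both
#' haplotypes).
#'
#' @param meanDepth mean pooled depth over the interval (vectorised).
#' @param config a \code{\link{regionClassifierConfig}}.
#' @return character vector, \code{"deletion"} or \code{"conserved"}.
#' @export
classifyRegion <- function(meanDepth, config = regionClassifierConfig()) {
  if (any(meanDepth < 0)) stop("negative depth")
  ifelse(meanDepth <= config$depthCeiling, "deletion", "conserved")
}

#' Advisory valley detection in a pooled depth histogram
#'
#' Smooths the depth histogram and reports the minimum between its two
#' highest peaks — the natural ceiling separating half-coverage
#' (haplotype-specific) from full-coverage (shared) regions. The value is
#' advisory: pass it to \code{\link{regionClassifierConfig}} explicitly if
#' you want to use it.
#'
#' @param depths numeric vector of per-window or per-region pooled depths.
#' @param bw density bandwidth (default \code{"nrd0"}).
#' @return list with \code{valley}, \code{peaks} (the two peak depths).
#' @export
depthValley <- function(depths, bw = "nrd0") {
  d <- stats::density(depths, bw = bw)
  isMax <- which(diff(sign(diff(d$y))) == -2) + 1L
  if (length(isMax) < 2L)
    return(list(valley = NA_real_, peaks = d$x[isMax]))
  top2 <- isMax[order(d$y[isMax], decreasing = TRUE)[1:2]]
  lo <- min(top2); hi <- max(top2)
  vi <- lo + which.min(d$y[lo:hi]) - 1L
  list(valley = d$x[vi], peaks = sort(d$x[top2]))
}

#' Build a full marker table from SNPs and classified regions
#'
#' Combines selected SNP markers with marker-free regions classified into
#' deletion and conserved kinds into one sorted \code{GRanges}.
#'
#' @param snpMarkers \code{GRanges} from \code{\link{selectSnpMarkers}}.
#' @param regions \code{GRanges} from \code{\link{findMarkerlessRegions}}.
#' @param regionDepth mean pooled depth per region (same order).
#' @param config a \code{\link{regionClassifierConfig}}.
#' @return A sorted \code{GRanges} with \code{kind} in
#'   \code{snp/deletion/conserved}.
#' @export
buildMarkerTable <- function(snpMarkers, regions, regionDepth,
                             config = regionClassifierConfig()) {
  if (length(regions)) {
    mcols(regions)$kind <- classifyRegion(regionDepth, config)
    mcols(regions)$ref <- NA_character_
    mcols(regions)$alt <- NA_character_
    mcols(regions)$altDepth <- NA_integer_
    mcols(regions)$totalDepth <- NA_integer_
    names(regions) <- sprintf("%s_%s_%d",
      as.character(seqnames(regions)),
      ifelse(mcols(regions)$kind == "deletion", "del", "cons"),
      GenomicRanges::start(regions))
  }
  GenomicRanges::sort(c(snpMarkers, regions), ignore.strand = TRUE)
}
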
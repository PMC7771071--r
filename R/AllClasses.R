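#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges colData
NULL

.CALL_ALPHABET_RAW    <- c("R", "A", "N")
.CALL_ALPHABET_PHASED <- c("a", "b", "n")

#' Gametes-by-markers genotype call container
#'
#' A \linkS4class{RangedSummarizedExperiment} holding one character assay,
#' \code{"calls"}, with markers as rows (a \code{GRanges} over assembly
#' contigs) and gametes as columns. Before phasing, calls are in
#' \code{{R, A, N}} (reference allele, alternative allele, missing); after
#' phasing they are in \code{{a, b, n}} (the two parental haplotypes plus
#' missing). Phasing state and the per-contig marker orientations that
#' produced a phased matrix are kept in \code{metadata()}.
#'
#' @slot .Data see \code{SummarizedExperiment}; use \code{\link{calls}},
#'   \code{\link{isPhased}}, \code{\link{markerIds}} and
#'   \code{\link{gameteIds}} rather than slots.
#' @export
setClass("GenotypeMatrix", contains = "RangedSummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  if (!"calls" %in% SummarizedExperiment::assayNames(object))
    return("assay 'calls' is required")
  m <- SummarizedExperiment::assay(object, "calls")
  if (!is.character(m))
    return("'calls' must be a character matrix")
  alphabet <- if (isTRUE(metadata(object)$phased))
    .CALL_ALPHABET_PHASED else .CALL_ALPHABET_RAW
  bad <- !(m %in% alphabet)
  if (any(bad))
    return(sprintf("invalid call symbol(s): %s (expected one of %s)",
                   paste(unique(m[bad]), collapse = ","),
                   paste(alphabet, collapse = ",")))
  TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param calls character matrix of genotype calls, markers in rows and
#'   gametes in columns. Symbols must be \code{R/A/N} (unphased) or
#'   \code{a/b/n} (phased).
#' @param markers \code{GRanges} of the row markers (same order as rows);
#'   names are used as marker ids.
#' @param colData optional \code{DataFrame} of per-gamete annotation.
#' @param phased logical; whether \code{calls} are phased.
#'
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
GenotypeMatrix <- function(calls, markers, colData = NULL, phased = FALSE) {
  stopifnot(is.matrix(calls), length(markers) == nrow(calls))
  if (is.null(rownames(calls)) && !is.null(names(markers)))
    rownames(calls) <- names(markers)
  if (is.null(colData))
    colData <- S4Vectors::DataFrame(row.names = colnames(calls))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(calls = calls), rowRanges = markers, colData = colData)
  metadata(se)$phased <- isTRUE(phased)
  obj <- new("GenotypeMatrix", se)
  validObject(obj)
  obj
}

#' @describeIn GenotypeMatrix extract the call matrix.
#' @param x a \code{GenotypeMatrix}.
#' @export
calls <- function(x) SummarizedExperiment::assay(x, "calls")

#' @describeIn GenotypeMatrix whether calls are phased (\code{a/b/n}).
#' @export
isPhased <- function(x) isTRUE(metadata(x)$phased)

#' @describeIn GenotypeMatrix marker (row) ids.
#' @export
markerIds <- function(x) rownames(x)

#' @describeIn GenotypeMatrix gamete (column) ids.
#' @export
gameteIds <- function(x) colnames(x)

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d markers x %d gametes (%s)\n",
              nrow(object), ncol(object),
              if (isPhased(object)) "phased, a/b/n" else "unphased, R/A/N"))
  m <- calls(object)
  cov <- mean(m != if (isPhased(object)) "n" else "N")
  cat(sprintf("  marker coverage: %.1f%% of cells called\n", 100 * cov))
  cat(sprintf("  contigs: %d\n",
              length(unique(as.character(seqnames(rowRanges(object)))))))
  invisible(NULL)
})

#' Gamete-derived genetic map
#'
#' Ordered linkage groups of contig-end (virtual) and deletion markers with
#' cumulative centimorgan positions and per-contig phase values. Phase 1
#' means the contig's genotype sequence was flipped to align with the
#' group-wide haplotype convention.
#'
#' @slot entries data.frame with columns \code{linkage_group},
#'   \code{order_index}, \code{marker}, \code{contig}, \code{end}
#'   (\code{head}/\code{tail}/\code{deletion}), \code{cM}, \code{phase}.
#' @export
setClass("GeneticMap", representation(entries = "data.frame"))

setValidity("GeneticMap", function(object) {
  e <- object@entries
  need <- c("linkage_group", "order_index", "marker", "contig", "end",
            "cM", "phase")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  if (nrow(e) == 0L) return(TRUE)
  if (!all(e$end %in% c("head", "tail", "deletion")))
    return("end must be head, tail or deletion")
  if (!all(e$phase %in% c(0L, 1L)))
    return("phase must be 0 or 1")
  for (g in unique(e$linkage_group)) {
    cm <- e$cM[e$linkage_group == g][order(e$order_index[e$linkage_group == g])]
    if (is.unsorted(cm)) return(sprintf("cM not non-decreasing in group %s", g))
  }
  ph <- tapply(e$phase[e$end != "deletion"], e$contig[e$end != "deletion"],
               function(p) length(unique(p)))
  if (any(ph > 1L))
    return("a contig's two end markers carry different phase values")
  TRUE
})

#' Construct a GeneticMap
#'
#' @param entries data.frame of map entries (see \linkS4class{GeneticMap}).
#' @return A \linkS4class{GeneticMap}.
#' @export
GeneticMap <- function(entries) {
  entries$phase <- as.integer(entries$phase)
  entries$order_index <- as.integer(entries$order_index)
  obj <- new("GeneticMap", entries = entries)
  validObject(obj)
  obj
}

#' @describeIn GeneticMap the entries data.frame.
#' @param x a \code{GeneticMap}.
#' @export
mapEntries <- function(x) x@entries

#' @describeIn GeneticMap linkage group ids.
#' @export
linkageGroups <- function(x) unique(x@entries$linkage_group)

#' @describeIn GeneticMap named vector of per-contig phase values (0/1).
#' @export
contigPhase <- function(x) {
  e <- x@entries[x@entries$end != "deletion", , drop = FALSE]
  ph <- tapply(e$phase, e$contig, `[`, 1L)
  stats::setNames(as.integer(ph), names(ph))
}

#' @describeIn GeneticMap named vector of per-contig linkage group.
#' @export
contigGroup <- function(x) {
  e <- x@entries[x@entries$end != "deletion", , drop = FALSE]
  g <- tapply(e$linkage_group, e$contig, `[`, 1L)
  stats::setNames(as.vector(g), names(g))
}

#' @describeIn GeneticMap total genetic length (cM) per linkage group.
#' @export
mapLength <- function(x) {
  e <- x@entries
  if (nrow(e) == 0L) return(numeric(0))
  vapply(split(e$cM, e$linkage_group), max, numeric(1))
}

setMethod("show", "GeneticMap", function(object) {
  e <- object@entries
  cat(sprintf("GeneticMap: %d linkage group(s), %d markers, %d contigs\n",
              length(linkageGroups(object)), nrow(e),
              length(unique(e$contig[e$end != "deletion"]))))
  if (nrow(e) > 0L) {
    len <- mapLength(object)
    cat(sprintf("  total length: %.1f cM (%s)\n", sum(len),
                paste(sprintf("%s: %.1f", names(len), len), collapse = ", ")))
  }
  invisible(NULL)
})
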
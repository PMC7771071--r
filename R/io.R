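#' Read candidate heterozygous SNPs from a VCF
#'
#' Ingests biallelic SNP lines from a VCF 4.x with per-site depth
#' information (INFO fields \code{DP} and \code{AD} as written by common
#' callers and by \code{\link{writeVcfCandidates}}). Multiallelic and
#' indel lines are skipped and counted, as are lines without usable depth
#' fields.
#'
#' @param path VCF file (plain text or gzipped).
#' @return data.frame with \code{contig}, \code{pos} (1-based),
#'   \code{ref}, \code{alt}, \code{altDepth}, \code{totalDepth}; the
#'   numbers of skipped multiallelic/indel and depth-less records are
#'   attached as attribute \code{skipped}.
#' @export
readVcfCandidates <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix)))   # single-record files come back as a bare vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(structure(data.frame(contig = character(0), pos = integer(0),
                                ref = character(0), alt = character(0),
                                altDepth = integer(0),
                                totalDepth = integer(0)),
                     skipped = c(nonSnp = 0L, noDepth = 0L)))
  pos <- suppressWarnings(as.integer(fix$POS))
  bad <- is.na(pos) | pos < 1L
  if (any(bad))
    stop("malformed VCF record (position must be a positive integer) at data line ",
         which(bad)[1L])
  isSnp <- !is.na(fix$ALT) & !grepl(",", fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  dp <- suppressWarnings(as.integer(
    vcfR::extract.info(vcf, "DP")))
  ad <- vcfR::extract.info(vcf, "AD")
  altDepth <- suppressWarnings(as.integer(vapply(strsplit(ad, ","),
    function(x) if (length(x) >= 2L) x[2L] else NA_character_,
    character(1))))
  hasDepth <- !is.na(dp) & !is.na(altDepth)
  keep <- isSnp & hasDepth
  out <- data.frame(contig = fix$CHROM[keep], pos = pos[keep],
                    ref = fix$REF[keep], alt = fix$ALT[keep],
                    altDepth = altDepth[keep], totalDepth = dp[keep],
                    stringsAsFactors = FALSE)
  attr(out, "skipped") <- c(nonSnp = sum(!isSnp),
                            noDepth = sum(isSnp & !hasDepth))
  out
}

#' Write candidate SNPs as a minimal VCF
#'
#' @param candidates data.frame as returned by
#'   \code{\link{readVcfCandidates}}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeVcfCandidates <- function(candidates, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##INFO=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(candidates))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AD=%d,%d",
                       candidates$contig, candidates$pos, candidates$ref,
                       candidates$alt, candidates$totalDepth,
                       candidates$totalDepth - candidates$altDepth,
                       candidates$altDepth), con)
  invisible(path)
}

#' Read long-read alignments with cs difference strings from a PAF file
#'
#' Parses the 12 mandatory PAF columns plus the \code{cs:Z:} tag and
#' reconstructs the substitution sites (target position, read base) from
#' the cs grammar. Substitution positions are reported in target
#' coordinates (0-based) for both strands. Alignments without a cs tag are
#' flagged as usable only for overlap tests.
#'
#' @param path PAF file.
#' @return list with \code{alignments} (readId, qlen, contig, tlen,
#'   tstart, tend 0-based half-open, strand, hasCs) and
#'   \code{substitutions} (readId, tpos 0-based, refBase, readBase).
#' @export
readPafAlignments <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(list(alignments = data.frame(readId = character(0),
                  qlen = integer(0), contig = character(0),
                  tlen = integer(0), tstart = integer(0),
                  tend = integer(0), strand = character(0),
                  hasCs = logical(0)),
                substitutions = data.frame(readId = character(0),
                  tpos = integer(0), refBase = character(0),
                  readBase = character(0))))
  fields <- strsplit(lines, "\t")
  short <- vapply(fields, length, integer(1)) < 12L
  if (any(short))
    stop("truncated PAF line ", which(short)[1L])
  getcol <- function(i) vapply(fields, `[[`, character(1), i)
  aln <- data.frame(readId = getcol(1L),
                    qlen = as.integer(getcol(2L)),
                    contig = getcol(6L),
                    tlen = as.integer(getcol(7L)),
                    tstart = as.integer(getcol(8L)),
                    tend = as.integer(getcol(9L)),
                    strand = getcol(5L),
                    stringsAsFactors = FALSE)
  cs <- vapply(fields, function(f) {
    tag <- grep("^cs:Z:", f[-(1:12)], value = TRUE)
    if (length(tag)) sub("^cs:Z:", "", tag[1L]) else NA_character_
  }, character(1))
  aln$hasCs <- !is.na(cs)
  subs <- lapply(which(aln$hasCs), function(i)
    decodeCsSubstitutions(cs[i], aln$tstart[i], aln$readId[i]))
  subs <- do.call(rbind, subs)
  if (is.null(subs))
    subs <- data.frame(readId = character(0), tpos = integer(0),
                       refBase = character(0), readBase = character(0))
  list(alignments = aln, substitutions = subs)
}

#' Decode substitution sites from a cs difference string
#'
#' Walks the cs grammar (\code{:n} match, \code{=SEQ} match, \code{*xy}
#' substitution, \code{+seq} insertion, \code{-seq} deletion) and returns
#' the substitutions in target coordinates.
#'
#' @param cs the cs string (without the \code{cs:Z:} prefix).
#' @param tstart 0-based target start of the alignment.
#' @param readId id copied into the output.
#' @return data.frame readId, tpos (0-based target position), refBase,
#'   readBase.
#' @export
decodeCsSubstitutions <- function(cs, tstart = 0L, readId = NA_character_) {
  toks <- regmatches(cs, gregexpr(
    ":[0-9]+|\\*[a-zA-Z]{2}|\\+[a-zA-Z]+|-[a-zA-Z]+|=[A-Za-z]+", cs))[[1]]
  if (sum(nchar(toks)) != nchar(cs))
    stop("unparseable cs string: ", cs)
  pos <- as.integer(tstart)
  out <- list()
  for (t in toks) {
    op <- substr(t, 1L, 1L)
    if (op == ":") {
      pos <- pos + as.integer(substr(t, 2L, nchar(t)))
    } else if (op == "=") {
      pos <- pos + nchar(t) - 1L
    } else if (op == "*") {
      out[[length(out) + 1L]] <- data.frame(readId = readId, tpos = pos,
        refBase = toupper(substr(t, 2L, 2L)),
        readBase = toupper(substr(t, 3L, 3L)))
      pos <- pos + 1L
    } else if (op == "-") {
      pos <- pos + nchar(t) - 1L
    } ## '+' insertion consumes no target bases
  }
  if (!length(out))
    return(data.frame(readId = character(0), tpos = integer(0),
                      refBase = character(0), readBase = character(0)))
  do.call(rbind, out)
}

#' Write alignment records as PAF with cs tags
#'
#' @param reads list with \code{alignments} and \code{substitutions} as
#'   produced by \code{\link{simulateLongReads}}.
#' @param path output file.
#' @param contigLengths named vector of target contig lengths.
#' @return invisibly, the path.
#' @export
writePaf <- function(reads, path, contigLengths) {
  a <- reads$alignments
  cs <- if (!is.null(a$cs)) a$cs else .buildCsTags(a, reads$substitutions)
  alen <- a$tend - a$tstart
  lines <- sprintf("%s\t%d\t0\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t60\tcs:Z:%s",
                   a$readId, a$qlen, a$qlen, a$strand, a$contig,
                   as.integer(contigLengths[a$contig]),
                   a$tstart, a$tend, alen, alen, cs)
  writeLines(lines, path)
  invisible(path)
}

#' Write a genetic map as TSV
#'
#' Columns: linkage_group, order_index, marker, contig, end, cM, phase.
#' \code{\link{readGeneticMap}} inverts the file exactly.
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeGeneticMap <- function(map, path) {
  e <- mapEntries(map)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("linkage_group", "order_index", "marker", "contig",
                     "end", "cM", "phase"), collapse = "\t"), con)
  if (nrow(e))
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t%s\t%d",
                       e$linkage_group, e$order_index, e$marker, e$contig,
                       e$end, sprintf("%.17g", e$cM), e$phase), con)
  invisible(path)
}

#' Read a genetic map written by \code{\link{writeGeneticMap}}
#'
#' @param path TSV file.
#' @return a \linkS4class{GeneticMap}.
#' @export
readGeneticMap <- function(path) {
  e <- utils::read.delim(path, colClasses = c(
    linkage_group = "character", order_index = "integer",
    marker = "character", contig = "character", end = "character",
    cM = "numeric", phase = "integer"))
  GeneticMap(e)
}

#' Write a per-gamete observation table as TSV
#'
#' @param observations data.frame (gamete, marker, refCount, altCount).
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeObservations <- function(observations, path) {
  utils::write.table(observations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a per-gamete observation table
#'
#' @param path TSV file from \code{\link{writeObservations}}.
#' @return data.frame (gamete, marker, refCount, altCount).
#' @export
readObservations <- function(path) {
  utils::read.delim(path, colClasses = c(
    gamete = "character", marker = "character",
    refCount = "integer", altCount = "integer"))
}
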
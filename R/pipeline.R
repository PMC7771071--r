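#' Run the full gamete-binning pipeline on a synthetic dataset
#'
#' Simulates a heterozygous diploid, recombinant gametes, sparse gamete
#' observations and haplotype-tagged long reads, then runs the whole
#' method: pooled-candidate SNP selection (depth bounds rescaled to the
#' pooled mode depth), per-gamete genotyping, a first phasing pass,
#' doublet screening, re-phasing on haploid gametes only, virtual-marker
#' imputation, genetic-map construction, deletion-marker integration,
#' crossover calling along each linkage group and long-read binning.
#' Evaluation against the simulator's truth (haplotype labels matched per
#' linkage group, since the global a/b labeling of each group is
#' arbitrary) is returned alongside all intermediate objects.
#'
#' @param config a \code{\link{simulationConfig}}; its \code{seed} drives
#'   every random draw.
#' @param minSupport crossover/virtual-marker segmentation support.
#' @param lodThreshold linkage-group LOD threshold.
#' @param binSeed seed for the random assignments during binning.
#' @param verbose print stage progress.
#'
#' @return list with the truth, observations, marker table, genotype
#'   matrices, ploidy screen, genetic map, crossover events, read
#'   assignments and an \code{evaluation} list (SNP-informative binning
#'   precision, fraction assigned, linkage-group count, doublet screen
#'   confusion, detected crossovers per gamete).
#' @export
runGameteBinning <- function(config = simulationConfig(),
                             minSupport = 5, lodThreshold = 3,
                             binSeed = 1L, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  say("simulating diploid truth")
  truth <- simulateDiploid(config)
  truth <- simulateGametes(truth)
  obs <- simulateObservations(truth)
  reads <- simulateLongReads(truth)

  ## --- marker selection from pooled candidate counts --------------------
  say("selecting SNP markers")
  pooledRef <- rowsum(obs$snpObs$refCount, obs$snpObs$marker)
  pooledAlt <- rowsum(obs$snpObs$altCount, obs$snpObs$marker)
  ids <- rownames(pooledRef)
  si <- match(ids, truth$snps$id)
  candidates <- data.frame(contig = truth$snps$contig[si],
                           pos = truth$snps$pos[si],
                           ref = truth$snps$ref[si],
                           alt = truth$snps$alt[si],
                           altDepth = pooledAlt[, 1L],
                           totalDepth = pooledRef[, 1L] + pooledAlt[, 1L])
  modeDepth <- stats::median(candidates$totalDepth)
  cfgSnp <- rescaleDepthBounds(snpFilterConfig(), modeDepth)
  markers <- selectSnpMarkers(candidates, cfgSnp)

  ## --- genotyping and two-pass phasing with doublet screening -----------
  say(sprintf("genotyping %d gametes at %d markers",
              length(truth$gametes$ids), length(markers)))
  gm <- buildGenotypeMatrix(obs$snpObs, markers, truth$gametes$ids)
  phased1 <- phaseAllContigs(gm)
  screen <- screenPloidy(phased1)
  doublets <- rownames(screen)[screen$label == "doublet"]
  say(sprintf("flagged %d doublet(s)", length(doublets)))
  phased <- phaseAllContigs(gm, exclude = doublets)

  ## --- genetic map from virtual end markers -----------------------------
  say("building genetic map")
  virtual <- imputeVirtualMarkers(phased, minSupport)
  map <- buildGeneticMap(virtual, lodThreshold, exclude = doublets)

  ## --- deletion markers: genotype, infer absence, place -----------------
  delPlacements <- NULL
  if (nrow(obs$delObs)) {
    keepG <- setdiff(truth$gametes$ids, doublets)
    dg <- obs$delObs[obs$delObs$gamete %in% keepG, , drop = FALSE]
    depthHat <- .estimateDepths(gm)[keepG]
    dcall <- callDeletionGenotype(dg$count, dg$regionLength,
                                  obs$totalMapped[dg$gamete])
    dg$call <- dcall$call
    expReads <- depthHat[dg$gamete] * dg$regionLength /
      config$shortReadLength
    dg$call <- inferDeletionAbsence(dg$call, expReads)
    seqOrder <- colnames(attr(map, "markerSeqs"))
    delPlacements <- do.call(rbind, lapply(split(dg, dg$marker),
      function(d) {
        s <- stats::setNames(d$call, d$gamete)[seqOrder]
        s[is.na(s)] <- "n"
        pl <- integrateDeletionMarker(s, map)
        data.frame(marker = d$marker[1L], placed = pl$placed,
                   group = if (pl$placed) pl$group else NA_character_,
                   cM = if (pl$placed) pl$cM else NA_real_,
                   phase = if (pl$placed) pl$phase else NA_integer_,
                   divergence = pl$divergence)
      }))
  }

  ## --- crossover calling along each linkage group -----------------------
  say("calling crossovers")
  co <- .callPipelineCrossovers(phased, map, truth, minSupport,
                                exclude = doublets)

  ## --- long-read binning ------------------------------------------------
  say("binning long reads")
  alleles <- phasedAlleleTable(phased, map)
  grp <- contigGroup(map)
  delTable <- .placedDeletionTable(delPlacements, truth, map)
  consTable <- .conservedTable(truth)
  bins <- binReads(reads$alignments, reads$substitutions, alleles,
                   deletions = delTable, conserved = consTable,
                   contigGroups = grp, seed = binSeed)

  ## --- evaluation against truth ----------------------------------------
  evaluation <- .evaluateRun(truth, obs, screen, map, co, bins, reads)
  list(truth = truth, observations = obs, markers = markers,
       genotypes = gm, phased = phased, screen = screen,
       doublets = doublets, virtual = virtual, map = map,
       deletionPlacements = delPlacements, crossovers = co,
       alleles = alleles, bins = bins, evaluation = evaluation)
}

## crude per-gamete depth from the fraction of markers observed:
## P(covered) = 1 - exp(-depth)
.estimateDepths <- function(gm) {
  frac <- colMeans(calls(gm) != "N")
  -log(pmax(1e-6, 1 - pmin(frac, 0.999)))
}

## per-gamete, per-linkage-group crossover calling in map order
.callPipelineCrossovers <- function(phased, map, truth, minSupport,
                                    exclude = character(0)) {
  e <- mapEntries(map)
  e <- e[e$end != "deletion", , drop = FALSE]
  m <- calls(phased)
  rr <- rowRanges(phased)
  ctg <- as.character(seqnames(rr))
  ph <- contigPhase(map)
  ctgInfo <- truth$contigs
  gametes <- setdiff(colnames(m), exclude)
  events <- list()
  for (g in unique(e$linkage_group)) {
    eg <- e[e$linkage_group == g, , drop = FALSE]
    eg <- eg[order(eg$order_index), , drop = FALSE]
    ## contig order and orientation along the group
    ctgOrder <- unique(eg$contig)
    rowsList <- list()
    posList <- list()
    offset <- 0
    for (cn in ctgOrder) {
      rows <- which(ctg == cn)
      if (!length(rows)) next
      ends <- eg$end[eg$contig == cn]
      reversed <- length(ends) >= 1L && ends[1L] == "tail"
      if (reversed) rows <- rev(rows)
      p <- GenomicRanges::start(rr)[rows]
      if (reversed) {
        clen <- ctgInfo$length[match(cn, ctgInfo$contig)]
        p <- clen - p + 1L
      }
      rowsList[[cn]] <- rows
      posList[[cn]] <- p + offset
      offset <- offset +
        ctgInfo$length[match(cn, ctgInfo$contig)]
    }
    rows <- unlist(rowsList, use.names = FALSE)
    pos <- unlist(posList, use.names = FALSE)
    if (!length(rows)) next
    flipRow <- ph[ctg[rows]] == 1L
    sub <- m[rows, gametes, drop = FALSE]
    if (any(flipRow))
      sub[flipRow, ] <- chartr("ab", "ba", sub[flipRow, , drop = FALSE])
    for (gam in gametes) {
      sc <- segmentAndCall(sub[, gam], pos, minSupport,
                           gamete = gam, group = g)
      if (nrow(sc$events)) events[[length(events) + 1L]] <- sc$events
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(gamete = character(0), group = character(0),
               leftMarkerIdx = integer(0), rightMarkerIdx = integer(0),
               leftPos = numeric(0), rightPos = numeric(0),
               start = numeric(0), end = numeric(0),
               midpoint = numeric(0), resolution = numeric(0),
               leftSupport = integer(0), rightSupport = integer(0))
  rownames(ev) <- NULL
  ev
}

.placedDeletionTable <- function(delPlacements, truth, map) {
  if (is.null(delPlacements) || !any(delPlacements$placed)) return(NULL)
  pl <- delPlacements[delPlacements$placed, , drop = FALSE]
  d <- truth$deletions[match(pl$marker, truth$deletions$id), , drop = FALSE]
  ctgStart <- truth$contigs$start[match(d$contig, truth$contigs$contig)]
  data.frame(contig = d$contig,
             start = d$start - ctgStart + 1L,
             end = d$end - ctgStart + 1L,
             group = pl$group,
             ## phase 0: reads-present gametes are haplotype A carriers
             carrierHap = ifelse(pl$phase == 0L, "A", "B"))
}

.conservedTable <- function(truth) {
  if (!nrow(truth$conserved)) return(NULL)
  ctgStart <- truth$contigs$start[match(truth$conserved$contig,
                                        truth$contigs$contig)]
  data.frame(contig = truth$conserved$contig,
             start = truth$conserved$start - ctgStart + 1L,
             end = truth$conserved$end - ctgStart + 1L)
}

## truth-based evaluation; haplotype labels are matched per linkage group
.evaluateRun <- function(truth, obs, screen, map, co, bins, reads) {
  asg <- bins$assignments
  origin <- reads$alignments$hapOrigin[match(asg$readId,
                                             reads$alignments$readId)]
  snpMask <- asg$evidence == "snp_vote"
  prec <- NA_real_
  if (any(snpMask)) {
    agree <- asg$haplotype[snpMask] == origin[snpMask]
    byGroup <- split(agree, asg$group[snpMask])
    nAgree <- sum(vapply(byGroup, function(x) max(sum(x), sum(!x)),
                         numeric(1)))
    prec <- nAgree / sum(snpMask)
  }
  trueDoublet <- obs$doublet[rownames(screen)]
  conf <- table(called = screen$label,
                truth = ifelse(trueDoublet, "doublet", "haploid"))
  nHaploid <- sum(!obs$doublet)
  lambdaHat <- if (nrow(co)) {
    keep <- !(co$gamete %in% names(obs$doublet)[obs$doublet])
    sum(keep) / nHaploid / truth$config$nChromosomes
  } else 0
  list(snpVotePrecision = prec,
       fractionAssigned = bins$summary$fractionAssigned,
       evidence = bins$summary$evidence,
       nLinkageGroups = length(linkageGroups(map)),
       doubletConfusion = conf,
       lambdaHat = lambdaHat)
}
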
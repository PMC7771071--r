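## Independent brute-force oracles used to check the package's algorithms
## on small inputs. These deliberately share no code with the implementation.

## maximal runs of non-SNP bases on a contig of length L (1-based closed)
oracleMarkerlessRegions <- function(snpPos, L, minLen = 2000) {
  isSnp <- rep(FALSE, L)
  isSnp[snpPos] <- TRUE
  r <- rle(!isSnp)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths > minLen
  data.frame(start = starts[keep], end = ends[keep])
}

## best achievable bi-marker agreement: exhaustive over all orientation
## assignments; objective sums, per adjacency, the gametes agreeing with
## the relative orientation
oraclePhaseObjective <- function(raw) {
  m <- nrow(raw)
  adjCounts <- lapply(seq_len(m - 1L), function(i) {
    x <- raw[i, ]; z <- raw[i + 1L, ]
    both <- x != "N" & z != "N"
    S <- sum(x[both] == z[both])
    c(S = S, D = sum(both) - S)
  })
  best <- -Inf
  for (bits in 0:(2^m - 1)) {
    o <- ifelse(bitwAnd(bits, 2^(seq_len(m) - 1L)) > 0, 1L, -1L)
    obj <- sum(vapply(seq_len(m - 1L), function(i) {
      sc <- adjCounts[[i]]
      if (o[i] == o[i + 1L]) sc["S"] else sc["D"]
    }, numeric(1)))
    best <- max(best, obj)
  }
  best
}

## objective value achieved by a given orientation vector
phaseObjectiveOf <- function(raw, o) {
  m <- nrow(raw)
  sum(vapply(seq_len(m - 1L), function(i) {
    x <- raw[i, ]; z <- raw[i + 1L, ]
    both <- x != "N" & z != "N"
    S <- sum(x[both] == z[both])
    D <- sum(both) - S
    if (o[i] == o[i + 1L]) S else D
  }, numeric(1)))
}

## exhaustive segmentation: all 2^m labelings whose maximal runs each hold
## at least minSupport markers; cost = (mismatches, blocks) lexicographic.
## Returns c(mismatches, blocks) of the optimum, or the majority single
## block when fewer than minSupport markers are observed.
oracleSegmentCost <- function(symbols, minSupport) {
  y <- symbols[symbols %in% c("a", "b")]
  m <- length(y)
  if (m == 0L) return(c(NA_integer_, 0L))
  if (m < minSupport)
    return(c(min(sum(y == "a"), sum(y == "b")), 1L))
  best <- c(Inf, Inf)
  for (bits in 0:(2^m - 1)) {
    lab <- ifelse(bitwAnd(bits, 2^(seq_len(m) - 1L)) > 0, "a", "b")
    r <- rle(lab)
    if (any(r$lengths < minSupport)) next
    cost <- c(sum(lab != y), length(r$lengths))
    if (cost[1] < best[1] || (cost[1] == best[1] && cost[2] < best[2]))
      best <- cost
  }
  best
}

## all permutations (n small)
allPerms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in allPerms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], p)
  out
}

## minimum sum of adjacent recombination fractions over all marker orders
oracleOrderCost <- function(ids, rr) {
  best <- Inf
  for (p in allPerms(ids)) {
    cost <- sum(rr[cbind(p[-length(p)], p[-1L])])
    best <- min(best, cost)
  }
  best
}

## direct recomputation of the landscape formula for one chromosome
oracleLandscape <- function(events, n, L, w, step) {
  starts <- seq(1, max(1, L - w + 1), by = step)
  vapply(starts, function(s) {
    inWin <- events$midpoint >= s & events$midpoint <= s + w - 1
    100 * length(unique(events$gamete[inWin])) / n / (w / 1e6)
  }, numeric(1))
}

## hand enumeration of canonical k-mers via Biostrings (independent of
## countKmers' substring walk)
oracleCanonicalSet <- function(seq, k) {
  n <- nchar(seq)
  km <- vapply(1:(n - k + 1), function(i) substr(seq, i, i + k - 1),
               character(1))
  rc <- vapply(km, function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x))), character(1))
  sort(unique(pmin(km, rc)))
}
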
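## Subcommunity-recovery loss: how far a union of candidate clusters is
## from a true subcommunity. One point for each member missed, one for
## each extra member, one for each cluster beyond the first in the union.

#' Subcommunity recovery loss
#'
#' @param trueSet integer vector, the true subcommunity.
#' @param clusters list of integer vectors whose union approximates it
#'   (an empty list scores `length(trueSet)`).
#' @return integer loss.
#' @export
#' @examples
#' subcommunityLoss(1:10, list(1:5, 6:10))  # 1 (one extra cluster)
subcommunityLoss <- function(trueSet, clusters) {
  trueSet <- unique(as.integer(trueSet))
  u <- unique(unlist(clusters))
  length(setdiff(trueSet, u)) + length(setdiff(u, trueSet)) +
    max(0L, length(clusters) - 1L)
}

## multi-word bitmask helpers over a fixed universe (31 bits per word)
.toMask <- function(set, universe, nw) {
  pos <- match(set, universe)
  m <- integer(nw)
  w <- (pos - 1L) %/% 31L + 1L
  bit <- (pos - 1L) %% 31L
  for (i in seq_along(pos)) m[w[i]] <- bitwOr(m[w[i]], bitwShiftL(1L, bit[i]))
  m
}
## bitw* ops drop dims; this applies one columnwise against a length-nw
## vector (recycled down each column) and restores the matrix shape
.bitCols <- function(op, M, v) matrix(op(as.vector(M), v), nrow = nrow(M))
.popcountCols <- function(M) {
  ## M: words x N integer matrix; column-wise popcount
  cnt <- integer(ncol(M))
  for (b in 0:30) {
    bit <- bitwShiftL(1L, b)
    cnt <- cnt + colSums(.bitCols(bitwAnd, M, bit) != 0L)
  }
  cnt
}

#' Minimum recovery loss over unions of candidate clusters
#'
#' Searches for the subset of `candidates` whose union minimizes
#' [subcommunityLoss()] against `trueSet`. With at most 20 candidates the
#' minimization is exhaustive over all subsets; larger families use a
#' beam search of width 100 (with a warning).
#'
#' @param trueSet true subcommunity (integer vector).
#' @param candidates list of integer vectors (e.g. thresholded NMF types
#'   or co-occurrence components).
#' @param beamWidth beam width for large families.
#' @return list with `loss` and `union` (the chosen subset of candidates,
#'   as a list).
#' @export
optimalLoss <- function(trueSet, candidates, beamWidth = 100L) {
  trueSet <- unique(as.integer(trueSet))
  candidates <- lapply(candidates, function(s) unique(as.integer(s)))
  nf <- length(candidates)
  if (nf == 0) return(list(loss = length(trueSet), union = list()))
  universe <- sort(unique(c(trueSet, unlist(candidates))))

  if (nf <= 20 && length(universe) <= 62) {
    nw <- (length(universe) - 1L) %/% 31L + 1L
    masks <- vapply(candidates, .toMask, integer(nw),
                    universe = universe, nw = nw)
    masks <- matrix(masks, nrow = nw)
    trueM <- .toMask(trueSet, universe, nw)
    full <- .toMask(universe, universe, nw)
    notTrue <- bitwAnd(bitwXor(trueM, full), full)
    ## subset unions by doubling: column s of U is the union of the
    ## candidates whose bits are set in s-1
    U <- matrix(0L, nw, 1L)
    cnt <- 0L
    for (i in seq_len(nf)) {
      U <- cbind(U, .bitCols(bitwOr, U, masks[, i]))
      cnt <- c(cnt, cnt + 1L)
    }
    extra <- .popcountCols(.bitCols(bitwAnd, U, notTrue))
    notU <- .bitCols(bitwAnd, .bitCols(bitwXor, U, full), full)
    miss <- .popcountCols(.bitCols(bitwAnd, notU, trueM))
    loss <- extra + miss + pmax(cnt - 1L, 0L)
    best <- which.min(loss)
    chosen <- which(bitwAnd(best - 1L, bitwShiftL(1L, 0:(nf - 1L))) != 0L)
    return(list(loss = as.integer(loss[best]),
                union = candidates[chosen]))
  }

  if (nf > 20)
    warning("more than 20 candidate clusters: beam search (width ",
            beamWidth, "), minimum not guaranteed")
  u <- length(universe)
  maskMat <- vapply(candidates, function(s) universe %in% s, logical(u))
  trueLog <- universe %in% trueSet
  lossOf <- function(unionLog, k)
    sum(unionLog & !trueLog) + sum(trueLog & !unionLog) + max(0L, k - 1L)
  states <- list(list(sel = integer(0), un = rep(FALSE, u)))
  bestLoss <- length(trueSet)
  bestSel <- integer(0)
  for (layer in seq_len(nf)) {
    cand <- list()
    losses <- numeric(0)
    keys <- character(0)
    for (st in states) {
      newUn <- maskMat | st$un
      ex <- colSums(newUn & !trueLog)
      mi <- colSums(trueLog & !newUn)
      ls <- ex + mi + (layer - 1L)
      for (cidx in order(ls)[seq_len(min(beamWidth, nf))]) {
        if (cidx %in% st$sel) next
        key <- paste(sort(c(st$sel, cidx)), collapse = ",")
        if (key %in% keys) next
        keys <- c(keys, key)
        cand <- c(cand, list(list(sel = c(st$sel, cidx),
                                  un = newUn[, cidx])))
        losses <- c(losses, ls[cidx])
      }
    }
    if (!length(cand)) break
    keep <- order(losses)[seq_len(min(beamWidth, length(losses)))]
    states <- cand[keep]
    layerBest <- min(losses)
    if (layerBest < bestLoss) {
      bestLoss <- layerBest
      bestSel <- states[[which.min(losses[keep])]]$sel
    } else if (layerBest > bestLoss) break  # adding only costs from here
  }
  list(loss = as.integer(bestLoss), union = candidates[bestSel])
}

#' Candidate clusters from an NMF type by threshold sweep
#'
#' For each type column, every distinct positive abundance value defines
#' a candidate cluster: the features with abundance at or above that
#' threshold. The family over all types feeds [optimalLoss()].
#'
#' @param types type matrix (or [PoissonNMF-class] fit).
#' @param maxPerType cap on thresholds per type (largest supports are
#'   kept; the sweep is nested so nearby thresholds are redundant).
#' @return list of integer vectors (feature indices).
#' @export
nmfClusterFamily <- function(types, maxPerType = 30L) {
  if (is(types, "PoissonNMF")) types <- typeMatrix(types)
  fam <- list()
  for (a in seq_len(ncol(types))) {
    v <- types[, a]
    thr <- sort(unique(v[v > 0]), decreasing = TRUE)
    if (length(thr) > maxPerType)
      thr <- thr[round(seq(1, length(thr), length.out = maxPerType))]
    for (t in thr) fam <- c(fam, list(which(v >= t)))
  }
  unique(lapply(fam, as.integer))
}
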
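## Permutation-based co-occurrence network baseline: for every feature
## pair, the observed correlation is compared against a null built by
## permuting the abundances of one member, and the empirical p-values are
## Benjamini-Hochberg corrected across all pairs.

#' Co-occurrence network by permutation test
#'
#' Computes pairwise correlations between features, builds a permutation
#' null per pair by shuffling the sample order of the higher-indexed
#' member, converts to two-sided empirical p-values
#' \eqn{(\#\{|null| \ge |obs|\} + 1)/(nPerm + 1)}, and applies
#' Benjamini-Hochberg correction across all pairs. Pairs involving a
#' constant feature are skipped with p = 1.
#'
#' @param X count matrix (features x samples, n >= 3).
#' @param nPerm number of permutations (default 1000).
#' @param method correlation flavor: `"spearman"` (default) or
#'   `"pearson"`.
#' @param seed integer seed.
#' @return data.frame with columns `from`, `to`, `cor`, `p`, `padj`, one
#'   row per unordered feature pair, plus attribute `"nFeatures"`.
#' @export
cooccurrenceNetwork <- function(X, nPerm = 1000L,
                                method = c("spearman", "pearson"),
                                seed = 1L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  p <- nrow(X); n <- ncol(X)
  if (n < 3) stop("need at least 3 samples")
  old <- .saveRNG(); on.exit(.restoreRNG(old))
  set.seed(as.integer(seed))

  V <- if (method == "spearman") t(apply(X, 1, rank)) else X
  sds <- apply(V, 1, sd)
  constant <- sds == 0
  Z <- matrix(0, p, n)
  okRows <- which(!constant)
  Z[okRows, ] <- t(scale(t(V[okRows, , drop = FALSE])))  # unit variance
  obs <- tcrossprod(Z) / (n - 1)

  pair <- t(combn(p, 2))
  pv <- rep(1, nrow(pair))
  ## one permutation set per higher-indexed member h; null correlations
  ## for all partners g < h computed in one matrix product
  for (h in 2:p) {
    if (constant[h]) next
    gs <- pair[pair[, 2] == h, 1]
    gs <- gs[!constant[gs]]
    if (!length(gs)) next
    P <- vapply(seq_len(nPerm), function(i) Z[h, sample(n)],
                numeric(n))
    nullCor <- (Z[gs, , drop = FALSE] %*% P) / (n - 1)
    obsRow <- abs(obs[gs, h])
    exceed <- rowSums(abs(nullCor) >= obsRow)
    pv[match(paste(gs, h), paste(pair[, 1], pair[, 2]))] <-
      (exceed + 1) / (nPerm + 1)
  }
  res <- data.frame(from = pair[, 1], to = pair[, 2],
                    cor = obs[pair], p = pv,
                    padj = p.adjust(pv, method = "BH"))
  attr(res, "nFeatures") <- p
  res
}

#' Connected components of a co-occurrence network
#'
#' Thresholds the corrected p-values and returns the connected components
#' of the resulting graph (singletons omitted).
#'
#' @param network result of [cooccurrenceNetwork()].
#' @param fdrLevel keep edges with `padj <= fdrLevel`.
#' @return list of integer vectors.
#' @export
cooccurrenceComponents <- function(network, fdrLevel = 0.05) {
  keep <- network$padj <= fdrLevel
  if (!any(keep)) return(list())
  g <- igraph::graph_from_edgelist(
    as.matrix(network[keep, c("from", "to")]), directed = FALSE)
  comp <- igraph::components(g)
  out <- split(seq_len(igraph::vcount(g)), comp$membership)
  out <- out[vapply(out, length, integer(1)) > 1]
  unname(lapply(out, as.integer))
}

#' Candidate clusters from a co-occurrence network across all levels
#'
#' Collects the connected components obtained at every distinct corrected
#' p-value threshold. Because components at different significance levels
#' may serve different subcommunities, the whole family is offered to
#' [optimalLoss()], which effectively picks a separate level per
#' component.
#'
#' @param network result of [cooccurrenceNetwork()].
#' @param maxLevels cap on the number of distinct thresholds scanned.
#' @return list of integer vectors.
#' @export
cooccurrenceClusterFamily <- function(network, maxLevels = 30L) {
  levels <- sort(unique(network$padj))
  levels <- levels[levels < 1]
  if (length(levels) > maxLevels)
    levels <- levels[round(seq(1, length(levels), length.out = maxLevels))]
  fam <- list()
  for (lv in levels)
    fam <- c(fam, cooccurrenceComponents(network, lv))
  unique(fam)
}
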
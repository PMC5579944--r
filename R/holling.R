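## Holling type II community-dynamics simulation: a fixed interaction
## network whose parameters are drawn once per system, integrated to a
## (near-)steady state separately for each sample with sample-specific
## growth parameters. The ground-truth subcommunities are the overlapping
## clusters the network is built from.

#' Default edge plan for a Holling network
#'
#' Builds the undirected edge plan used by [buildHollingNetwork()]: every
#' within-cluster pair is a black (facilitating) link, plus a configurable
#' number of blue (mixed-sign, weak) and red (inhibitory) links between
#' randomly chosen cross-cluster pairs. A pair lying in two overlapping
#' clusters appears once.
#'
#' @param clusterBlocks list of integer vectors (default three overlapping
#'   blocks 1-10, 9-18, 17-26).
#' @param nBlue,nRed number of blue / red cross-cluster links.
#' @param nOtus total nodes (nodes beyond the clusters are isolated).
#' @param seed integer seed for choosing the colored cross pairs.
#' @return data.frame with columns `from`, `to`, `color`.
#' @export
defaultHollingPlan <- function(clusterBlocks = list(1:10, 9:18, 17:26),
                               nBlue = 10L, nRed = 60L, nOtus = 30L,
                               seed = 1L) {
  pairs <- unique(do.call(rbind, lapply(clusterBlocks, function(cl) {
    cmb <- t(combn(sort(cl), 2))
    data.frame(from = cmb[, 1], to = cmb[, 2])
  })))
  pairs$color <- "black"
  old <- .saveRNG(); on.exit(.restoreRNG(old))
  set.seed(as.integer(seed))
  inCluster <- paste(pairs$from, pairs$to)
  all2 <- t(combn(seq_len(nOtus), 2))
  cross <- all2[!(paste(all2[, 1], all2[, 2]) %in% inCluster), ,
                drop = FALSE]
  nCol <- min(nBlue + nRed, nrow(cross))
  pick <- cross[sample(nrow(cross), nCol), , drop = FALSE]
  colored <- data.frame(from = pick[, 1], to = pick[, 2],
                        color = rep(c("blue", "red"),
                                    c(min(nBlue, nCol),
                                      nCol - min(nBlue, nCol))))
  rbind(pairs, colored)
}

#' Build a Holling type II system with drawn parameters
#'
#' Each undirected link of the edge plan becomes two directed influences,
#' each with its own interaction coefficient drawn by link color --
#' black: U(0, 0.008); blue: U(-0.002, 0.008); red: U(-0.08, 0) -- and
#' its own handling time drawn as \eqn{1/T_H \sim 10^5 Beta(5, 1)}.
#' Attack rates default to 1 (only the products \eqn{a T_H M} and
#' \eqn{b a M} enter the dynamics). Non-edges have zero interaction.
#'
#' @param clusterBlocks ground-truth subcommunities (may overlap).
#' @param nOtus total number of OTUs (extras are isolated).
#' @param edgePlan data.frame `from`, `to`, `color` of undirected links;
#'   default [defaultHollingPlan()]. Assigning two colors to one pair is
#'   an error.
#' @param attackRate attack rate for every edge.
#' @param seed integer seed.
#' @return a [HollingSystem-class] object.
#' @export
buildHollingNetwork <- function(clusterBlocks = list(1:10, 9:18, 17:26),
                                nOtus = 30L, edgePlan = NULL,
                                attackRate = 1, seed = 1L) {
  nOtus <- as.integer(nOtus)
  if (is.null(edgePlan))
    edgePlan <- defaultHollingPlan(clusterBlocks, nOtus = nOtus,
                                   seed = seed)
  key <- paste(pmin(edgePlan$from, edgePlan$to),
               pmax(edgePlan$from, edgePlan$to))
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    clash <- vapply(unique(dup), function(kk)
      length(unique(edgePlan$color[key == kk])) > 1, logical(1))
    if (any(clash))
      stop("conflicting colors for pair(s): ",
           paste(unique(dup)[clash], collapse = ", "))
    edgePlan <- edgePlan[!duplicated(key), ]
  }
  if (!all(edgePlan$color %in% c("black", "blue", "red")))
    stop("edge colors must be black, blue or red")

  old <- .saveRNG(); on.exit(.restoreRNG(old))
  set.seed(as.integer(seed))
  ## two directed edges per link, independent draws per direction
  edges <- data.frame(
    from = c(edgePlan$from, edgePlan$to),
    to = c(edgePlan$to, edgePlan$from),
    color = rep(edgePlan$color, 2))
  ne <- nrow(edges)
  edges$b <- rep(NA_real_, ne)
  for (colr in c("black", "blue", "red")) {
    idx <- which(edges$color == colr)
    rng <- switch(colr, black = c(0, 0.008), blue = c(-0.002, 0.008),
                  red = c(-0.08, 0))
    edges$b[idx] <- runif(length(idx), rng[1], rng[2])
  }
  edges$a <- rep(attackRate, ne)
  edges$th <- 1 / (1e5 * rbeta(ne, 5, 1))
  new("HollingSystem", nOtus = nOtus, edges = edges,
      clusters = lapply(clusterBlocks, as.integer),
      seed = as.integer(seed))
}

#' Simulate samples from a Holling type II system
#'
#' For each sample, intrinsic growth rates \eqn{r_i \sim U(0,1)} and
#' intraspecific coefficients with \eqn{1/c_i - 1 \sim 99 Beta(1,2)} are
#' drawn (carrying capacities between 1 and 100), initial abundances
#' \eqn{M_i(0) \sim U(0.1, 10)}, and the dynamics integrated by explicit
#' Euler. The final state, rounded to integer counts, is the sample.
#' Samples whose abundances diverge beyond `maxAbundance` are redrawn
#' (with a message) up to `maxRedraw` times.
#'
#' @param system a [HollingSystem-class].
#' @param nSamples number of samples.
#' @param seed integer seed.
#' @param dt Euler step size.
#' @param nSteps number of Euler steps.
#' @param m0Range range of the uniform initial abundances.
#' @param maxAbundance divergence threshold.
#' @param maxRedraw redraw attempts for diverged samples.
#' @return list with `counts` (rounded abundances, nOtus x nSamples),
#'   `abundances` (raw), `growthRates` and `intraCoefs` (both
#'   nOtus x nSamples).
#' @export
simulateHolling <- function(system, nSamples, seed = 1L, dt = 0.001,
                            nSteps = 1e6, m0Range = c(0.1, 10),
                            maxAbundance = 1e12, maxRedraw = 5L) {
  stopifnot(is(system, "HollingSystem"), dt > 0, nSteps >= 1)
  p <- system@nOtus
  e <- system@edges
  old <- .saveRNG(); on.exit(.restoreRNG(old))
  set.seed(as.integer(seed))

  drawPars <- function(n) {
    list(R = matrix(runif(p * n), p, n),
         C = matrix(1 / (1 + 99 * rbeta(p * n, 1, 2)), p, n),
         M0 = matrix(runif(p * n, m0Range[1], m0Range[2]), p, n))
  }
  pars <- drawPars(nSamples)
  out <- hollingEuler(pars$M0, pars$R, pars$C, as.integer(e$from),
                      as.integer(e$to), e$b, e$a, e$th, dt,
                      as.integer(nSteps), maxAbundance)
  M <- out$M; R <- pars$R; C <- pars$C
  bad <- which(out$diverged)
  attempt <- 0L
  while (length(bad) && attempt < maxRedraw) {
    attempt <- attempt + 1L
    message(length(bad), " diverged sample(s) redrawn (attempt ",
            attempt, ")")
    pars <- drawPars(length(bad))
    out <- hollingEuler(pars$M0, pars$R, pars$C, as.integer(e$from),
                        as.integer(e$to), e$b, e$a, e$th, dt,
                        as.integer(nSteps), maxAbundance)
    M[, bad] <- out$M; R[, bad] <- pars$R; C[, bad] <- pars$C
    bad <- bad[out$diverged]
  }
  if (length(bad))
    warning("samples still diverged after ", maxRedraw, " redraws")
  dimnames(M) <- list(paste0("M", seq_len(p)),
                      paste0("sample", seq_len(nSamples)))
  list(counts = round(M), abundances = M, growthRates = R, intraCoefs = C)
}

#' Integrate one sample with given growth parameters
#'
#' Deterministic explicit-Euler integration of a Holling system for a
#' single parameter set (no random draws), useful for checking fixed
#' points and equilibria.
#'
#' @param system a [HollingSystem-class].
#' @param growthRates length-p vector of r_i.
#' @param intraCoefs length-p vector of c_i.
#' @param m0 length-p initial abundances.
#' @param dt,nSteps Euler step size and count.
#' @return length-p final abundances.
#' @export
hollingTrajectory <- function(system, growthRates, intraCoefs, m0,
                              dt = 0.001, nSteps = 1e6) {
  p <- system@nOtus
  stopifnot(length(growthRates) == p, length(intraCoefs) == p,
            length(m0) == p)
  e <- system@edges
  out <- hollingEuler(matrix(m0, p, 1), matrix(growthRates, p, 1),
                      matrix(intraCoefs, p, 1), as.integer(e$from),
                      as.integer(e$to), e$b, e$a, e$th, dt,
                      as.integer(nSteps), 1e12)
  if (out$diverged[1]) warning("trajectory diverged")
  drop(out$M)
}
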
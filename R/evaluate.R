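## Evaluation utilities: weight-space distances, PAM mis-clustering, and
## the static convex projection of normalized weights onto user-supplied
## type positions.

#' Euclidean distances between samples in weight space
#'
#' @param W normalized weight matrix (k x n, unit column sums).
#' @return n x n symmetric distance matrix with zero diagonal.
#' @export
weightDistance <- function(W) {
  D <- as.matrix(stats::dist(t(W)))
  dimnames(D) <- list(colnames(W), colnames(W))
  D
}

#' PAM mis-clustering error against known labels
#'
#' Partitions the samples with Partitioning Around Medoids on the given
#' distance matrix and reports the misassignment fraction, minimized over
#' all cluster-to-class label assignments.
#'
#' @param D distance matrix (or `dist`).
#' @param trueLabels true class per sample.
#' @param kClusters number of clusters (default 2).
#' @return mis-clustering error in `[0, 1]`.
#' @export
pamMisclustering <- function(D, trueLabels, kClusters = 2L) {
  trueLabels <- as.factor(trueLabels)
  cl <- cluster::pam(stats::as.dist(as.matrix(D)), k = kClusters,
                     diss = TRUE, cluster.only = TRUE)
  n <- length(trueLabels)
  classes <- levels(trueLabels)
  if (kClusters == length(classes)) {
    if (kClusters > 8) stop("label assignment search supports k <= 8")
    best <- n
    for (pr in .permutations(seq_len(kClusters))) {
      mapped <- classes[pr[cl]]
      best <- min(best, sum(mapped != as.character(trueLabels)))
    }
  } else {
    ## more clusters than classes: each cluster takes its majority class
    best <- sum(vapply(split(as.character(trueLabels), cl), function(tl)
      length(tl) - max(table(tl)), numeric(1)))
  }
  best / n
}

.permutations <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(.permutations(v[-i]), function(rest) c(v[i], rest)))
  out
}

#' Project normalized weights onto type positions in the plane
#'
#' Every sample is drawn at the convex combination of the type positions
#' given by its normalized weights, so the layout of the samples is
#' entirely determined by where the types are placed. Default positions
#' are the vertices of a regular k-gon.
#'
#' @param W normalized weight matrix (k x n).
#' @param typePositions k x 2 matrix of type coordinates; default regular
#'   k-gon on the unit circle.
#' @return list with `typePositions` and `sampleCoords` (n x 2).
#' @export
projectLayout <- function(W, typePositions = NULL) {
  k <- nrow(W)
  if (is.null(typePositions)) {
    ang <- 2 * pi * (seq_len(k) - 1) / k
    typePositions <- cbind(x = cos(ang), y = sin(ang))
  }
  typePositions <- as.matrix(typePositions)
  if (nrow(typePositions) != k || ncol(typePositions) != 2)
    stop("typePositions must be k x 2")
  coords <- t(typePositions) %*% W
  rownames(typePositions) <- rownames(W)
  list(typePositions = typePositions,
       sampleCoords = cbind(x = coords[1, ], y = coords[2, ]))
}
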
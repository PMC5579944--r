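## Small fixtures built in code.

## two types with completely disjoint supports
disjointTypes <- function(p = 20, seed = 1) {
  set.seed(seed)
  half <- p %/% 2
  t1 <- c(runif(half), rep(0, p - half))
  t2 <- c(rep(0, half), runif(p - half))
  Tm <- cbind(t1 / sum(t1), t2 / sum(t2))
  rownames(Tm) <- paste0("f", seq_len(p))
  Tm
}

## counts from a single composition at a given depth
poissonFrom <- function(comp, depth, n, seed = 1) {
  set.seed(seed)
  X <- matrix(rpois(length(comp) * n, depth * comp), length(comp), n)
  rownames(X) <- names(comp) %||% paste0("f", seq_along(comp))
  colnames(X) <- paste0("s", seq_len(n))
  X
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## independent likelihood evaluation, written without reference to the
## package internals (oracle for log-likelihood checks)
naiveLoglik <- function(X, Tm, Wm) {
  M <- Tm %*% Wm
  total <- 0
  for (i in seq_len(nrow(X))) for (j in seq_len(ncol(X))) {
    if (X[i, j] > 0) {
      if (M[i, j] == 0) return(-Inf)
      total <- total + X[i, j] * log(M[i, j])
    }
    total <- total - M[i, j]
  }
  total
}
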
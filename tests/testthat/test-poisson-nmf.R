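test_that("poissonLogLik matches closed forms and handles zeros", {
  expect_equal(poissonLogLik(matrix(1), matrix(1), matrix(1)), -1)
  expect_equal(poissonLogLik(matrix(2), matrix(1), matrix(2)),
               2 * log(2) - 2)
  expect_equal(
    poissonLogLik(matrix(c(0, 3)), matrix(c(0.5, 0.5)), matrix(4)),
    0 - 2 + 3 * log(2) - 2)
  ## zero mean against zero count contributes 0; against positive -> -Inf
  expect_equal(poissonLogLik(matrix(c(0, 2)), matrix(c(0, 1)), matrix(3)),
               2 * log(3) - 3)
  expect_equal(poissonLogLik(matrix(c(1, 0)), matrix(c(0, 1)), matrix(3)),
               -Inf)
  expect_error(poissonLogLik(matrix(1:4, 2), matrix(1), matrix(1)),
               "dimension")
  expect_error(poissonLogLik(matrix(-1), matrix(1), matrix(1)),
               "negative")
})

test_that("poissonLogLik agrees with a naive double-loop evaluation", {
  set.seed(42)
  for (rep in 1:5) {
    X <- matrix(rpois(24, 4), 6, 4)
    Tm <- matrix(runif(12), 6, 2)
    Tm <- sweep(Tm, 2, colSums(Tm), "/")
    Wm <- matrix(runif(8, 0, 10), 2, 4)
    expect_equal(poissonLogLik(X, Tm, Wm), naiveLoglik(X, Tm, Wm))
  }
})

test_that("rank-one data are factorized exactly up to the unit-sum scale", {
  X <- outer(c(2, 6), c(3, 5))
  fit <- fitNMF(X, k = 1, seed = 3, tol = 1e-12)
  expect_equal(unname(typeMatrix(fit)[, 1]), c(0.25, 0.75),
               tolerance = 1e-6)
  expect_equal(unname(weightMatrix(fit)[1, ]), c(24, 40),
               tolerance = 1e-6)
  expect_equal(logLik(fit), poissonLogLik(X, typeMatrix(fit),
                                          weightMatrix(fit)),
               tolerance = 1e-8)
})

test_that("k = 1 fits match the closed form (row profile, column sums)", {
  set.seed(7)
  for (rep in 1:5) {
    X <- matrix(rpois(12, 8) + 1, 4, 3)
    fit <- fitNMF(X, 1, seed = rep, tol = 1e-12)
    expect_equal(unname(typeMatrix(fit)[, 1]),
                 rowSums(X) / sum(X), tolerance = 1e-6)
    expect_equal(unname(weightMatrix(fit)[1, ]), colSums(X),
                 tolerance = 1e-6)
  }
})

test_that("likelihood trace is monotone and column sums are conserved", {
  set.seed(11)
  for (rep in 1:4) {
    p <- sample(8:25, 1); n <- sample(5:15, 1); k <- sample(1:3, 1)
    X <- matrix(rpois(p * n, 6), p, n)
    X[, colSums(X) == 0] <- 1
    fit <- fitNMF(X, k, seed = 100 + rep)
    expect_true(all(diff(fit@loglikTrace) >= -1e-9))
    TW <- typeMatrix(fit) %*% weightMatrix(fit)
    expect_equal(colSums(TW), colSums(X), tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(colSums(weightMatrix(fit)), colSums(X),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("likelihood is invariant to rescaling absorbed by normalization", {
  set.seed(5)
  X <- matrix(rpois(40, 5), 8, 5)
  Tm <- matrix(runif(16), 8, 2); Tm <- sweep(Tm, 2, colSums(Tm), "/")
  Wm <- matrix(runif(10, 1, 5), 2, 5)
  c0 <- c(2.5, 0.4)
  Tm2 <- sweep(Tm, 2, 1 / c0, "*")   # unscale columns
  Wm2 <- Wm * c0
  cs <- colSums(Tm2)
  Tm2 <- sweep(Tm2, 2, cs, "/"); Wm2 <- Wm2 * cs  # renormalize back
  expect_equal(poissonLogLik(X, Tm, Wm), poissonLogLik(X, Tm2, Wm2))
})

test_that("larger k never fits worse on the same data", {
  Tm <- disjointTypes(20, seed = 2)
  sim <- simulateFromTypes(Tm, rep(500, 30), seed = 4)
  l1 <- fitNMF(sim$counts, 1, seed = 1)@loglik
  l2 <- max(vapply(1:5, function(s)
    fitNMF(sim$counts, 2, seed = s)@loglik, numeric(1)))
  expect_gte(l2, l1)
})

test_that("disjoint block supports are recovered up to permutation", {
  ## block-structured mean data make the k = 2 solution essentially
  ## unique; oracle = best of many restarts
  t1 <- c(0.5, 0.3, 0.2, 0, 0, 0)
  t2 <- c(0, 0, 0, 0.6, 0.3, 0.1)
  W0 <- rbind(c(100, 80, 0, 10, 50, 5), c(0, 20, 90, 70, 40, 60))
  X <- cbind(t1, t2) %*% W0
  fits <- lapply(1:50, function(s) fitNMF(X, 2, seed = s, tol = 1e-10))
  best <- fits[[which.max(vapply(fits, logLik, numeric(1)))]]
  Tf <- typeMatrix(best)
  d1 <- max(abs(Tf - cbind(t1, t2)))
  d2 <- max(abs(Tf - cbind(t2, t1)))
  expect_lt(min(d1, d2), 0.05)
})

## reproduce the sub-seed stream used by logLikCurve for the single-k call
.subSeedsOracle <- function(seed) {
  set.seed(seed)
  sample.int(2147483646L, 1)
}

test_that("log-likelihood curve saturates past the true rank", {
  set.seed(30)
  Tm <- disjointTypes(12, seed = 9)
  ## exact rank-2 mean data: no Poisson sampling, no rounding
  X <- Tm %*% matrix(runif(2 * 8, 50, 150), 2, 8)
  curve <- suppressWarnings(
    logLikCurve(X, 1:4, seed = 21, nStarts = 8, tol = 1e-10))
  expect_equal(names(curve), as.character(1:4))
  expect_true(all(diff(curve) >= -1e-6 * abs(curve[-1])))
  relGain <- diff(curve) / abs(curve[-length(curve)])
  expect_gt(relGain[1], 1e-3)          # big jump from 1 to 2
  expect_lt(max(abs(relGain[2:3])), 1e-6)  # flat beyond the true rank
  single <- logLikCurve(X, 1, seed = 33, nStarts = 1)
  expect_equal(unname(single), fitNMF(X, 1, seed = .subSeedsOracle(33))@loglik)
})

test_that("elbow heuristic finds the true number of separated types", {
  set.seed(17)
  Tm <- matrix(0, 30, 3)
  Tm[1:10, 1] <- runif(10); Tm[11:20, 2] <- runif(10)
  Tm[21:30, 3] <- runif(10)
  Tm <- sweep(Tm, 2, colSums(Tm), "/")
  sim <- simulateFromTypes(Tm, rep(2000, 40), seed = 8)
  curve <- logLikCurve(sim$counts, 1:6, seed = 19, nStarts = 5)
  expect_equal(elbowPoint(curve), 3L)
})

test_that("invalid inputs are rejected", {
  X <- matrix(rpois(20, 3), 5, 4); X[, colSums(X) == 0] <- 1
  expect_error(fitNMF(X, 0, seed = 1), "k must")
  expect_error(fitNMF(X, 5, seed = 1), "k must")
  expect_error(fitNMF(cbind(X, 0), 2, seed = 1), "all-zero")
})
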
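test_that("noise SD vectors follow the SNR definition", {
  Tm <- disjointTypes(10, seed = 1)
  expect_equal(noiseSd(Tm, Inf), rep(0, 10))
  expect_equal(noiseSd(Tm, 2), 2 * noiseSd(Tm, 4))
  expect_equal(noiseSd(Tm, 1), apply(Tm, 1, sd))
  expect_error(noiseSd(Tm, 3), "snr")
})

test_that("noiseless simulation converges to the mixture proportions", {
  Tm <- disjointTypes(12, seed = 2)
  sim <- simulateFromTypes(Tm, rep(1e6, 3), seed = 3)
  props <- sweep(sim$counts, 2, colSums(sim$counts), "/")
  expected <- sweep(Tm %*% sim$trueWeights, 2, 1e6, "/")
  expect_lt(max(abs(props - expected)), 0.01)
  expect_equal(dim(sim$counts), c(12L, 3L))
})

test_that("single-type draws are Poisson at the stated mean", {
  comp <- c(0.5, 0.3, 0.2)
  set.seed(10)
  pvals <- replicate(50, {
    sim <- simulateFromTypes(matrix(comp), 2000, seed = sample.int(1e6, 1))
    stats::chisq.test(sim$counts[, 1], p = comp)$p.value
  })
  expect_gt(mean(pvals > 0.01), 0.9)
})

test_that("tiny Dirichlet concentration produces near-degenerate weights", {
  set.seed(4)
  Tm <- matrix(1 / 10, 10, 6)
  sim <- simulateZeroInflated(Tm, rep(100, 400), alpha = 0.005, seed = 5)
  Wn <- sweep(sim$trueWeights, 2, colSums(sim$trueWeights), "/")
  fracTiny <- mean(colMeans(Wn < 1e-6))
  expect_gt(fracTiny, 0.5)
})

test_that("zero inflation increases count sparsity over uniform weights", {
  Tm <- disjointTypes(30, seed = 6)
  for (s in 1:3) {
    u <- simulateFromTypes(Tm, rep(200, 50), seed = 100 + s)
    z <- simulateZeroInflated(Tm, rep(200, 50), seed = 100 + s)
    expect_gt(mean(z$counts == 0), mean(u$counts == 0))
  }
})

test_that("mislabel flips exactly the requested fraction and is an involution", {
  lab <- factor(rep(c("x", "y"), each = 10))
  expect_equal(mislabel(lab, 0, seed = 1), lab)
  half <- mislabel(lab, 0.5, seed = 2)
  expect_equal(sum(half != lab), 10)
  expect_equal(mislabel(half, 0.5, seed = 2), lab)
  expect_error(mislabel(factor(c("a", "b", "c")), 0.1), "two-class")
  expect_error(mislabel(lab, 1), "fraction")
})

test_that("mixture classes follow the effect-size construction", {
  p1 <- c(0.7, 0.2, 0.1, 0); p2 <- c(0, 0.1, 0.2, 0.7)
  sim <- simulateMixtureClasses(p1, p2, effectSize = 1, depth = 10000,
                                nPerClass = 200, seed = 7)
  expect_true(all(colSums(sim$counts) == 10000))
  expect_equal(table(sim$labels), table(rep(c("A", "B"), each = 200)),
               ignore_attr = TRUE)
  ## s = 1: both classes share (p1+p2)/2
  pooledA <- rowSums(sim$counts[, sim$labels == "A"])
  pooledB <- rowSums(sim$counts[, sim$labels == "B"])
  expect_lt(max(abs(pooledA / sum(pooledA) - (p1 + p2) / 2)), 0.01)
  expect_lt(max(abs(pooledB / sum(pooledB) - (p1 + p2) / 2)), 0.01)
  ## large s: classes approach the opposite base vectors
  big <- simulateMixtureClasses(p1, p2, effectSize = 1e6, depth = 10000,
                                nPerClass = 50, seed = 8)
  pA <- rowSums(big$counts[, big$labels == "A"])
  expect_lt(max(abs(pA / sum(pA) - p2)), 0.01)
})

test_that("holling edge parameters respect their color ranges", {
  sys <- buildHollingNetwork(seed = 9)
  e <- sys@edges
  expect_true(all(e$b[e$color == "black"] >= 0 &
                  e$b[e$color == "black"] <= 0.008))
  expect_true(all(e$b[e$color == "blue"] >= -0.002 &
                  e$b[e$color == "blue"] <= 0.008))
  expect_true(all(e$b[e$color == "red"] >= -0.08 &
                  e$b[e$color == "red"] <= 0))
  expect_true(all(1 / e$th > 0 & 1 / e$th <= 1e5))
  ## pooled handling-time draws match the Beta(5,1) mean within 2%
  inv <- unlist(lapply(1:40, function(s)
    1 / buildHollingNetwork(seed = 1000 + s)@edges$th))
  expect_lt(abs(mean(inv) - 1e5 * 5 / 6) / (1e5 * 5 / 6), 0.02)
})

test_that("conflicting edge colors are rejected", {
  plan <- data.frame(from = c(1, 2), to = c(2, 1),
                     color = c("black", "red"))
  expect_error(buildHollingNetwork(clusterBlocks = list(1:2), nOtus = 3,
                                   edgePlan = plan, seed = 1),
               "conflicting colors")
})

test_that("isolated logistic dynamics reach the carrying capacity", {
  sys <- buildHollingNetwork(clusterBlocks = list(1:3), nOtus = 3,
                             edgePlan = data.frame(from = integer(0),
                                                   to = integer(0),
                                                   color = character(0)),
                             seed = 1)
  final <- hollingTrajectory(sys, growthRates = rep(1, 3),
                             intraCoefs = rep(0.01, 3),
                             m0 = c(5, 0, 150), nSteps = 5e4)
  expect_equal(final[1], 100, tolerance = 1e-3)
  expect_equal(final[2], 0)            # zero is absorbing
  expect_equal(final[3], 100, tolerance = 1e-3)
})

test_that("mutualists equilibrate above their isolated capacities", {
  plan <- data.frame(from = 1, to = 2, color = "black")
  sys <- buildHollingNetwork(clusterBlocks = list(1:2), nOtus = 2,
                             edgePlan = plan, seed = 3)
  r <- c(0.5, 0.5); cc <- c(0.02, 0.02)
  final <- hollingTrajectory(sys, r, cc, m0 = c(10, 10), nSteps = 2e5)
  expect_true(all(final > 1 / cc - 1e-6))
  ## oracle: solve the two fixed-point equations numerically
  e <- sys@edges
  rhs <- function(M) {
    inter <- numeric(2)
    for (k in seq_len(nrow(e)))
      inter[e$to[k]] <- inter[e$to[k]] +
        e$b[k] * e$a[k] * M[e$from[k]] / (1 + e$a[k] * e$th[k] * M[e$from[k]])
    r * (1 - cc * M) + inter
  }
  sol <- stats::optim(final, function(M) sum(rhs(M)^2),
                      method = "BFGS")$par
  expect_equal(final, sol, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("generators are reproducible under a fixed seed", {
  Tm <- disjointTypes(8, seed = 1)
  a <- simulateFromTypes(Tm, rep(100, 4), seed = 11)
  b <- simulateFromTypes(Tm, rep(100, 4), seed = 11)
  expect_identical(a, b)
  s1 <- buildHollingNetwork(seed = 12)
  s2 <- buildHollingNetwork(seed = 12)
  expect_identical(s1@edges, s2@edges)
})
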
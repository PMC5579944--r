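test_that("wilcoxonZ matches the exact permutation distribution", {
  ## oracle: enumerate every assignment of the pooled ranks to the two
  ## groups and standardize by the enumeration mean and SD
  enumZ <- function(own, oth) {
    pooled <- c(own, oth)
    r <- rank(pooled)
    m <- length(oth)
    sets <- combn(length(pooled), m)
    sums <- apply(sets, 2, function(idx) sum(r[idx]))
    obs <- sum(r[(length(own) + 1):length(pooled)])
    (obs - mean(sums)) / sqrt(mean(sums^2) - mean(sums)^2)
  }
  cases <- list(
    list(own = c(1, 2, 3), oth = c(4, 5, 6)),
    list(own = c(5, 1, 9, 2), oth = c(3, 7)),
    list(own = c(1, 2, 2, 3), oth = c(2, 4, 5)),     # ties
    list(own = c(10, 20), oth = c(5, 15, 25, 30, 2)))
  for (cs in cases)
    expect_equal(wilcoxonZ(cs$own, cs$oth), enumZ(cs$own, cs$oth),
                 tolerance = 1e-12)
  expect_equal(wilcoxonZ(c(1, 2, 3), c(4, 5, 6)), 4.5 / sqrt(5.25),
               tolerance = 1e-12)
})

test_that("wilcoxonZ is antisymmetric, shift-invariant, zero on ties", {
  expect_equal(wilcoxonZ(c(1, 2, 7), c(1, 2, 7)), 0)
  expect_equal(wilcoxonZ(c(2, 2, 2), c(2, 2)), 0)   # all tied
  a <- c(0.2, 1.5, 3.1, 0.9); b <- c(2.2, 0.4, 5)
  expect_equal(wilcoxonZ(a, b), -wilcoxonZ(b, a))
  expect_equal(wilcoxonZ(a + 100, b + 100), wilcoxonZ(a, b))
  expect_equal(wilcoxonZ(a, c(b, Inf)), wilcoxonZ(a, c(b, 1e9)))
})

test_that("an easy two-type class is selected at k = 2", {
  ## own class mixes 2 disjoint types; the other class's composition is a
  ## reshuffle inside the same support, so only k = 1 fails to achieve
  ## (near-)total deviance separation
  chosen <- integer(0)
  cvs <- numeric(0)
  for (s in 1:5) {
    set.seed(s)
    Tm <- matrix(0, 24, 3)
    Tm[1:8, 1] <- runif(8); Tm[9:16, 2] <- runif(8)
    Tm[1:16, 3] <- sample(c(Tm[1:8, 1], Tm[9:16, 2]))
    Tm <- sweep(Tm, 2, colSums(Tm), "/")
    own <- simulateFromTypes(Tm[, 1:2], rep(600, 40), seed = 10 + s)$counts
    oth <- simulateFromTypes(Tm[, 3, drop = FALSE], rep(600, 40),
                             seed = 20 + s)$counts
    sel <- selectNumTypes(own, oth, kGrid = 1:4, r = 5, seed = 30 + s)
    chosen <- c(chosen, chosenK(sel))
    z <- sel@zByFold[, paste0("k", max(2L, chosenK(sel)))]
    cvs <- c(cvs, sd(z) / abs(mean(z)))
  }
  expect_equal(as.integer(names(which.max(table(chosen)))), 2L)
  ## near-complete separation: fold Z values nearly equal at the chosen k
  expect_lt(stats::median(cvs), 0.1)
})

test_that("a fully disjoint other class saturates separation at every k", {
  ## when the other class's support is disjoint from the fitted types its
  ## deviances are infinite at every k, separation is total from k = 1,
  ## and the smallest-k rule correctly returns the smallest candidate
  set.seed(77)
  Tm <- matrix(0, 24, 3)
  Tm[1:8, 1] <- runif(8); Tm[9:16, 2] <- runif(8); Tm[17:24, 3] <- runif(8)
  Tm <- sweep(Tm, 2, colSums(Tm), "/")
  own <- simulateFromTypes(Tm[, 1:2], rep(600, 40), seed = 78)$counts
  oth <- simulateFromTypes(Tm[, 3, drop = FALSE], rep(600, 40),
                           seed = 79)$counts
  sel <- selectNumTypes(own, oth, kGrid = 1:4, r = 5, seed = 80)
  expect_equal(length(unique(round(sel@zAll, 6))), 1L)
  expect_equal(chosenK(sel), 1L)
})

test_that("a flat Z_all curve selects the smallest candidate", {
  kGrid <- 1:5
  expect_equal(micronmf:::.smallestKRule(kGrid, rep(0.1, 5), rep(1, 5)), 1L)
  ## within-one-SD rule: 2 is the smallest k inside the band around k=4
  expect_equal(
    micronmf:::.smallestKRule(kGrid, c(0, 2.6, 2.2, 3, 2.9), rep(0.5, 5)),
    2L)
  ## candidates with too many missing folds are excluded
  expect_equal(
    micronmf:::.smallestKRule(kGrid, c(9, 2.6, 2.2, 3, 2.9), rep(0.5, 5),
                              usable = c(FALSE, rep(TRUE, 4))),
    2L)
})

test_that("identically distributed classes give Z_all near 0", {
  Tm <- disjointTypes(16, seed = 3)
  a <- simulateFromTypes(Tm, rep(400, 30), seed = 41)$counts
  b <- simulateFromTypes(Tm, rep(400, 30), seed = 42)$counts
  sel <- selectNumTypes(a, b, kGrid = 1:3, r = 5, seed = 43)
  expect_lt(max(abs(sel@zAll)), 4)
  expect_lte(chosenK(sel), 2L)
})

test_that("selection report invariants hold", {
  Tm <- disjointTypes(14, seed = 8)
  a <- simulateFromTypes(Tm, rep(300, 20), seed = 1)$counts
  b <- simulateFromTypes(Tm[, 2:1], rep(300, 20), seed = 2)$counts
  sel <- selectNumTypes(a, b, kGrid = 1:3, r = 4, seed = 3)
  expect_s4_class(sel, "TypeSelection")
  expect_true(chosenK(sel) %in% sel@kGrid)
  iMax <- which.max(sel@zAll)
  expect_gte(sel@zAll[match(chosenK(sel), sel@kGrid)],
             sel@zAll[iMax] - sel@sdZAll[iMax])
})

test_that("CV-error refinement honors the tie rule and singleton grids", {
  d <- local({
    Tm <- disjointTypes(16, seed = 5)
    X1 <- poissonFrom(Tm[, 1], 500, 12, seed = 6)
    X2 <- poissonFrom(Tm[, 2], 500, 12, seed = 7)
    X <- cbind(X1, X2); colnames(X) <- paste0("s", 1:24)
    list(X = X, lab = factor(rep(c("a", "b"), each = 12)))
  })
  ## separable data: the error curve is flat at 0, so the smallest k wins
  ref <- refineByCVError(d$X, d$lab, fixedK = c(a = 1), hardClass = "b",
                         kGridHard = c(1, 2), r = 3, seed = 9)
  expect_equal(unname(ref$cvMeans), c(0, 0))
  expect_equal(ref$chosenK, 1)
  single <- refineByCVError(d$X, d$lab, fixedK = c(a = 1),
                            hardClass = "b", kGridHard = 3, r = 3,
                            seed = 9)
  expect_equal(single$chosenK, 3)
})

test_that("refinement returns the argmin of the cross-validated errors", {
  tt <- classTypePool(60, c(2, 3), seed = 15)
  X1 <- simulateFromTypes(tt[[1]], rep(5000, 30), seed = 16)$counts
  X2 <- simulateFromTypes(tt[[2]], rep(5000, 30), seed = 17)$counts
  X <- cbind(X1, X2); colnames(X) <- paste0("s", 1:60)
  lab <- factor(rep(c("a", "b"), each = 30))
  ref <- refineByCVError(X, lab, fixedK = c(a = 2), hardClass = "b",
                         kGridHard = 2:4, r = 5, seed = 18)
  expect_equal(names(ref$cvMeans), as.character(2:4))
  expect_equal(ref$chosenK, (2:4)[which.min(ref$cvMeans)])
  expect_error(refineByCVError(X, lab, fixedK = c(a = 2),
                               hardClass = "zz", kGridHard = 2),
               "unknown hard class")
})
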
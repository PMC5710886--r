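test_that("rank normalization maps samples onto [0,1] with average ranks for ties", {
  expect_equal(rankNormalize(c(3.2, 1.1, 5.0)), c(0.5, 0.0, 1.0))
  expect_equal(rankNormalize(c(7, 7, 7)), c(0.5, 0.5, 0.5))
  set.seed(2)
  x <- rnorm(50)
  expect_equal(rankNormalize(exp(x) + 10), rankNormalize(x))  # monotone invariance
  expect_error(rankNormalize(3), "at least 2")
})

test_that("binomial tail matches hand values and the log-space oracle for all n <= 64", {
  expect_equal(binomTail(0, 10), 1)
  expect_equal(binomTail(10, 10), 2^-10)
  expect_equal(binomTail(44, 48), 213053 / 2^48)
  for (n in c(1:10, 31:33, 48, 57, 63, 64)) {
    ks <- 0:n
    got <- vapply(ks, binomTail, numeric(1), n = n)
    want <- vapply(ks, oracleBinomTail, numeric(1), n = n)
    expect_equal(got, want, tolerance = 1e-12)
    # decreasing in k: strictly so wherever the step 2^-n is representable
    # against the tail mass (near 1 the step falls below double epsilon)
    expect_true(all(diff(got) <= 0))
    upper <- got[ks >= floor(n / 2)]
    expect_true(all(diff(upper) < 0))
  }
  # beyond the exact range the log-space branch takes over smoothly
  expect_equal(binomTail(60, 100), oracleBinomTail(60, 100))
})

test_that("pair statistic counts signs, drops ties and fills the exact tail", {
  ser <- pairSeries()
  sig <- fiveGeneSignature()
  ps <- pairStatistic(ser, sig, "si", "sj")
  expect_equal(ps$covered, 5L)
  expect_equal(ps$kPositive, 3L)       # diffs (4, 2, 0, -2, 1)
  expect_equal(ps$nInformative, 4L)    # one tie excluded
  expect_equal(ps$proportion, 0.75)
  expect_equal(ps$pValue, binomTail(3, 4))

  # "against" policy keeps ties in the denominator
  ps2 <- pairStatistic(ser, sig, "si", "sj", tiePolicy = "against")
  expect_equal(ps2$nInformative, 5L)
  expect_equal(ps2$proportion, 3 / 5)

  # identical samples: everything ties, p-value 1 by convention
  m <- cbind(a = 1:5, b = 1:5)
  rownames(m) <- paste0("g", 1:5)
  tied <- pairStatistic(ExpressionSeries("T1", m), sig, "a", "b")
  expect_equal(tied$nInformative, 0L)
  expect_equal(tied$pValue, 1)

  # uniform dominance on all 5 genes: one-sided 2^-5
  m2 <- cbind(a = c(5, 6, 7, 8, 9), b = c(1, 2, 3, 4, 5))
  rownames(m2) <- paste0("g", 1:5)
  dom <- pairStatistic(ExpressionSeries("T2", m2), sig, "a", "b")
  expect_equal(dom$proportion, 1)
  expect_equal(dom$pValue, 2^-5)
  # the orientation flag doubles it
  dom2 <- pairStatistic(ExpressionSeries("T2", m2), sig, "a", "b",
                        orientationCorrection = TRUE)
  expect_equal(dom2$pValue, 2^-4)
})

test_that("orientation antisymmetry: positives of (i,j) plus (j,i) plus ties cover the signature", {
  set.seed(8)
  sig <- GeneSignature(sprintf("g%02d", 1:20))
  for (rep in 1:10) {
    m <- matrix(sample(1:8, 20 * 2, replace = TRUE), 20, 2,
                dimnames = list(sprintf("g%02d", 1:20), c("a", "b")))
    ser <- ExpressionSeries("X", m)
    ij <- pairStatistic(ser, sig, "a", "b")
    ji <- pairStatistic(ser, sig, "b", "a")
    ties <- ij$covered - ij$nInformative
    expect_equal(ij$kPositive + ji$kPositive + ties, ij$covered)
    expect_equal(ij$pValue, ji$pValue)  # same orientation-maximal tail
  }
})

test_that("series scan returns the brute-force best pair in its winning orientation", {
  set.seed(21)
  genes <- sprintf("g%03d", 1:150)
  sig <- GeneSignature(genes[1:57])
  m <- matrix(rnorm(150 * 10), 150, 10,
              dimnames = list(genes, sprintf("s%02d", 1:10)))
  ser <- ExpressionSeries("NOISE", m)
  best <- scanSeries(ser, sig)

  # brute force over ordered pairs on the rank-normalized matrix
  r <- apply(m, 2, rankNormalize)
  rownames(r) <- rownames(m)
  best_p <- Inf
  for (i in colnames(r)) for (j in colnames(r)) {
    if (i == j) next
    d <- r[genes[1:57], i] - r[genes[1:57], j]
    k <- sum(d > 0); n <- sum(d != 0)
    p <- oracleBinomTail(max(k, n - k), n)
    if (p < best_p) best_p <- p
  }
  expect_equal(best$pValue, best_p)

  # a constructed fully coordinated pair dominates and is identified:
  # signature genes occupy the top ranks of s03 and the bottom ranks of
  # s04, so every signed difference is positive for that ordered pair
  m2 <- m
  m2[genes[1:57], "s03"] <- 100 + rnorm(57)
  m2[genes[1:57], "s04"] <- -100 + rnorm(57)
  res2 <- scanSeries(ExpressionSeries("PLANT", m2), sig)
  expect_identical(res2$sampleI, "s03")
  expect_identical(res2$sampleJ, "s04")
  expect_equal(res2$proportion, 1)
  expect_equal(res2$pValue, 2^-57)

  # a 2-sample series returns its single pair in the better orientation
  two <- ExpressionSeries("TWO", m2[, c("s03", "s04")])
  res3 <- scanSeries(two, sig)
  expect_identical(res3$sampleI, "s03")
  expect_equal(res3$proportion, 1)
})

test_that("Holm adjustment reproduces the step-down arithmetic and its properties", {
  expect_equal(holmAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(holmAdjust(0.2), 0.2)
  set.seed(4)
  for (rep in 1:20) {
    p <- runif(sample(2:30, 1))
    adj <- holmAdjust(p)
    expect_equal(adj, oracleHolm(p), tolerance = 1e-12)
    expect_true(all(adj >= p))                    # dominance over raw
    expect_true(all(adj <= pmin(1, length(p) * p)))  # dominated by Bonferroni
    perm <- sample(length(p))
    expect_equal(holmAdjust(p[perm]), adj[perm])  # permutation equivariance
  }
})

test_that("collection scan ranks planted series first and selects exactly them", {
  sim <- simulateSeriesCollection(nSeries = 40, samplesPerSeries = 8,
                                  nGenes = 300, signatureSize = 57,
                                  plantedFraction = 0.25, pairShift = 3,
                                  noiseSd = 1, seed = 19)
  res <- scanCollection(sim$collection, sim$signature, topN = 250)
  tab <- scanTable(res)
  expect_equal(nrow(tab), 40L)
  planted <- sim$truth$seriesId[sim$truth$planted]
  ranks <- match(planted, tab$seriesId)
  expect_true(all(ranks <= length(planted)))
  expect_setequal(selectedSeries(res), planted)
  # the selected planted pairs are the planted pairs themselves
  sel <- tab[tab$selected, ]
  truth <- sim$truth[match(sel$seriesId, sim$truth$seriesId), ]
  expect_identical(sel$sampleI, truth$sampleI)
  # ScanResult ordering and Holm dominance invariants
  expect_false(is.unsorted(tab$pValue))
  expect_true(all(tab$holmAdjusted >= tab$pValue))
  expect_equal(tab$holmAdjusted, holmAdjust(tab$pValue))
})

test_that("single-series collections and unscannable series are handled", {
  sim <- simulateSeriesCollection(nSeries = 3, samplesPerSeries = 4,
                                  nGenes = 100, signatureSize = 20,
                                  plantedFraction = 0, seed = 5)
  one <- SeriesCollection(list(sim$collection[[1]]))
  res <- scanCollection(one, sim$signature, maxP = 1, maxAdjusted = 1,
                        minProportion = 0)
  expect_equal(nrow(scanTable(res)), 1L)
  expect_equal(scanTable(res)$holmAdjusted, scanTable(res)$pValue)

  # a 1-sample series is skipped with a warning, not an error
  m <- exprsMatrix(sim$collection[[2]])[, 1, drop = FALSE]
  small <- ExpressionSeries("TINY", m)
  mixed <- SeriesCollection(list(sim$collection[[1]], small))
  expect_warning(res2 <- scanCollection(mixed, sim$signature,
                                        minProportion = 0, maxP = 1,
                                        maxAdjusted = 1),
                 "fewer than 2")
  expect_identical(scanTable(res2)$seriesId, seriesId(sim$collection[[1]]))

  # low signature coverage excludes a series; with none left the scan
  # refuses to produce a result
  cov_sig <- GeneSignature(c(signatureGenes(sim$signature)[1:10],
                             sprintf("ABSENT%02d", 1:10)))
  expect_warning(
    expect_error(scanCollection(one, cov_sig, minProportion = 0, maxP = 1,
                                maxAdjusted = 1, minCoverage = 0.8),
                 "no scannable"),
    "coverage")
})

test_that("null-only collections select nothing at the published thresholds", {
  sim <- simulateSeriesCollection(nSeries = 30, samplesPerSeries = 8,
                                  nGenes = 300, signatureSize = 57,
                                  plantedFraction = 0, seed = 23)
  res <- scanCollection(sim$collection, sim$signature)
  expect_length(selectedSeries(res), 0L)
})

test_that("the pair statistic is invariant to monotone per-sample distortion end to end", {
  set.seed(31)
  genes <- sprintf("g%03d", 1:80)
  sig <- GeneSignature(genes[1:57])
  m <- matrix(rnorm(80 * 6), 80, 6,
              dimnames = list(genes, sprintf("s%02d", 1:6)))
  warped <- m
  warped[, 1] <- exp(m[, 1])
  warped[, 2] <- m[, 2]^3 + 2
  warped[, 3] <- atan(m[, 3])
  a <- scanSeries(ExpressionSeries("A", m), sig)
  b <- scanSeries(ExpressionSeries("B", warped), sig)
  expect_equal(a$pValue, b$pValue)
  expect_equal(a$kPositive, b$kPositive)
  expect_identical(a[c("sampleI", "sampleJ")], b[c("sampleI", "sampleJ")])
})

test_that("null per-pair proportions have mean 1/2 and variance 1/(4n)", {
  set.seed(41)
  n <- 57
  props <- replicate(3000, {
    d <- rnorm(n) - rnorm(n)
    sum(d > 0) / n
  })
  expect_lt(abs(mean(props) - 0.5), 3 * sd(props) / sqrt(length(props)))
  v <- 1 / (4 * n)
  expect_lt(abs(var(props) - v), 0.15 * v)
})
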
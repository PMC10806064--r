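test_that("Fisher dispersion reproduces direct summation on hand instances", {
  # two 1-D classes {0,2} and {4,6}: within 1 each, between 4 each -> 5
  s <- emgSBL:::newFeatureSet(matrix(c(0, 2, 4, 6), ncol = 1),
                              c("a", "a", "b", "b"))
  expect_equal(fisherDispersion(s), 5)

  # all samples identical -> 0
  same <- emgSBL:::newFeatureSet(matrix(1, 4, 3), c("a", "a", "b", "b"))
  expect_equal(fisherDispersion(same), 0)

  # single class warns and returns the within term only
  one <- emgSBL:::newFeatureSet(matrix(c(0, 2), ncol = 1), c("a", "a"))
  expect_warning(J1 <- fisherDispersion(one), "single class")
  expect_equal(J1, 1)
})

test_that("Fisher dispersion is translation invariant and quadratic in scale", {
  set.seed(5)
  X <- matrix(rnorm(60), ncol = 3)
  y <- rep(c("a", "b", "c"), length.out = 20)
  s <- emgSBL:::newFeatureSet(X, y)
  J <- fisherDispersion(s)
  shifted <- emgSBL:::newFeatureSet(X + rep(c(5, -2, 9), each = 20), y)
  expect_equal(fisherDispersion(shifted), J)
  scaled <- emgSBL:::newFeatureSet(2.5 * X, y)
  expect_equal(fisherDispersion(scaled), 2.5^2 * J)

  # permuting samples and features (mask permuted too) leaves J unchanged
  pS <- sample(20)
  pF <- c(3, 1, 2)
  perm <- emgSBL:::newFeatureSet(X[pS, pF], y[pS])
  mask <- featureMask(c(TRUE, FALSE, TRUE))
  expect_equal(fisherDispersion(perm, featureMask(mask@bits[pF])),
               fisherDispersion(s, mask))
})

test_that("GA selection matches exhaustive search on an enumerable problem", {
  set.seed(6)
  s <- plantedFeatureSet(nPerClass = 10, nClasses = 3, D = 8,
                         informative = 3, sep = 2, seed = 6)
  oracle <- exhaustiveBestMask(s, 3)
  res <- gaSelect(s, 3, gaConfig(populationSize = 40, generations = 60,
                                 seed = 1))
  expect_equal(res$score, oracle$score)
  expect_equal(maskBits(res$mask), oracle$bits)
})

test_that("GA selection respects cardinality, determinism and elitism", {
  s <- plantedFeatureSet(D = 10, seed = 7)
  r1 <- gaSelect(s, 4, gaConfig(populationSize = 20, generations = 15,
                                seed = 3))
  r2 <- gaSelect(s, 4, gaConfig(populationSize = 20, generations = 15,
                                seed = 3))
  expect_identical(maskBits(r1$mask), maskBits(r2$mask))
  expect_equal(maskCardinality(r1$mask), 4L)
  expect_true(all(diff(r1$curve) >= 0))   # elitism: non-decreasing curve

  # d = D reduces to the unmasked score
  rD <- gaSelect(s, 10, gaConfig(populationSize = 10, generations = 2,
                                 seed = 1))
  expect_true(all(maskBits(rD$mask)))
  expect_equal(rD$score, fisherDispersion(s))

  expect_error(gaSelect(s, 11), "d <= D")
})

test_that("GA recovers a planted informative subset across seeds", {
  hits <- sapply(1:10, function(sd) {
    s <- plantedFeatureSet(nPerClass = 15, nClasses = 3, D = 13,
                           informative = 3, sep = 3, seed = sd)
    res <- gaSelect(s, 3, gaConfig(populationSize = 30, generations = 40,
                                   seed = sd))
    all(which(maskBits(res$mask)) == 1:3)
  })
  expect_gte(mean(hits), 0.9)
})

test_that("dimension sweeps tabulate per-d scores; greedy nesting is monotone", {
  s <- plantedFeatureSet(D = 8, seed = 8)
  sw <- dimensionSweep(s, 8, gaConfig(populationSize = 10, generations = 2,
                                      seed = 1))
  expect_equal(sw$score, fisherDispersion(s))

  gr <- dimensionSweep(s, 1:8, method = "greedy")
  expect_true(all(diff(gr$score) >= 0))
  # greedy masks are nested
  for (k in 2:8)
    expect_true(all(maskBits(gr$mask[[k - 1]]) <= maskBits(gr$mask[[k]])))
})

test_that("degenerate masks and empty classes are rejected", {
  expect_error(featureMask(c(FALSE, FALSE)), "at least one")
  s <- plantedFeatureSet(D = 5, seed = 9)
  expect_error(fisherDispersion(s, featureMask(rep(TRUE, 4))), "length")
})
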
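# Independent oracle: direct solve of the full (n+1) x (n+1) KKT system
# with qr.solve, bypassing the package's block-elimination path.
oracleLssvm <- function(X, y, gam, sig2) {
  n <- nrow(X)
  K <- outer(seq_len(n), seq_len(n),
             Vectorize(function(i, j) rbfKernel(X[i, ], X[j, ], sig2)))
  A <- rbind(c(0, y), cbind(y, (y %o% y) * K + diag(1 / gam, n)))
  sol <- qr.solve(A, c(0, rep(1, n)))
  list(b = sol[1], alpha = sol[-1])
}

test_that("the RBF kernel is a proper similarity", {
  expect_equal(rbfKernel(1:3, 1:3, 2), 1)
  x <- c(0, 0)
  z <- c(1, 1)  # squared distance 2
  expect_equal(rbfKernel(x, z, 2), exp(-1))
  set.seed(10)
  for (i in 1:5) {
    a <- rnorm(4)
    b <- rnorm(4)
    expect_equal(rbfKernel(a, b, 1.3), rbfKernel(b, a, 1.3))
    expect_lte(rbfKernel(a, b, 1.3), 1)
    expect_gt(rbfKernel(a, b, 1.3), 0)
  }
  expect_error(rbfKernel(1, 1, 0), "sig2")
  expect_error(rbfKernel(1:2, 1:3, 1), "dimensionality")
})

test_that("binary training solves the dual system exactly", {
  # mirror-symmetric points force zero bias
  Xs <- rbind(c(1, 2), c(-1, -2))
  m <- lssvmTrain(Xs, c(1, -1), gam = 10, sig2 = 1)
  expect_equal(m@b, 0, tolerance = 1e-12)
  f <- lssvmDecision(m, Xs)
  expect_equal(f[1], -f[2], tolerance = 1e-12)
  expect_lte(m@residual, 1e-8)

  # separable toy: alpha, b and decisions match the independent oracle
  set.seed(11)
  X <- rbind(matrix(rnorm(20, -2), ncol = 2), matrix(rnorm(20, 2), ncol = 2))
  y <- rep(c(1, -1), each = 10)
  m2 <- lssvmTrain(X, y, gam = 100, sig2 = 1)
  o <- oracleLssvm(X, y, 100, 1)
  expect_lt(max(abs(m2@alpha - o$alpha)), 1e-6)
  expect_lt(abs(m2@b - o$b), 1e-6)
  expect_equal(mean(lssvmPredict(m2, X) == ifelse(y > 0, "+1", "-1")), 1)
  fOr <- sapply(seq_len(nrow(X)), function(i)
    sum(o$alpha * y * sapply(seq_len(nrow(X)), function(k)
      rbfKernel(X[i, ], X[k, ], 1))) + o$b)
  expect_lt(max(abs(lssvmDecision(m2, X) - fOr)), 1e-6)
  expect_lte(m2@residual, 1e-8)

  expect_error(lssvmTrain(X, rep(1, 20), 1, 1), "both classes")
  expect_error(lssvmTrain(X, y, -1, 1), "gam")
})

test_that("decision values vanish to the bias far from training data", {
  set.seed(12)
  X <- matrix(rnorm(12), ncol = 2)
  m <- lssvmTrain(X, rep(c(1, -1), 3), gam = 10, sig2 = 1)
  far <- c(1e3, 1e3)
  expect_equal(lssvmDecision(m, far), m@b, tolerance = 1e-8)
  expect_error(lssvmDecision(m, c(1, 2, 3)), "mismatch")
})

test_that("training error is non-increasing in gam on a fixed toy", {
  set.seed(15)
  X <- rbind(matrix(rnorm(40, 0, 1.5), ncol = 2),
             matrix(rnorm(40, 1.5, 1.5), ncol = 2))
  y <- rep(c(1, -1), each = 20)
  errs <- sapply(c(0.01, 0.1, 1, 10, 100, 1000), function(g) {
    m <- lssvmTrain(X, y, g, 1)
    mean(sign(lssvmDecision(m, X)) != y)
  })
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("duplicating the training set leaves decisions unchanged", {
  set.seed(14)
  X <- rbind(matrix(rnorm(16, -1), ncol = 2), matrix(rnorm(16, 1), ncol = 2))
  y <- rep(c(1, -1), each = 8)
  # duplicating every sample doubles the squared-error weight, so the
  # same primal solution corresponds to halving gam
  m1 <- lssvmTrain(X, y, gam = 10, sig2 = 2)
  m2 <- lssvmTrain(rbind(X, X), c(y, y), gam = 5, sig2 = 2)
  q <- matrix(rnorm(10), ncol = 2)
  expect_equal(lssvmDecision(m1, q), lssvmDecision(m2, q), tolerance = 1e-6)
})

test_that("one-vs-one assembly has C(C,2) machines and classifies blobs", {
  set.seed(15)
  centers <- rbind(c(0, 0), c(6, 0), c(0, 6))
  X <- do.call(rbind, lapply(1:3, function(i)
    matrix(rnorm(30, mean = rep(centers[i, ], each = 15), sd = 0.4),
           ncol = 2)))
  y <- rep(c("a", "b", "c"), each = 15)
  ens <- lssvmTrainMulticlass(X, y, gam = 100, sig2 = 1)
  expect_length(ens@machines, 3L)
  expect_equal(mean(lssvmPredictMulticlass(ens, X) == y), 1)

  # C = 2 reduces to the binary path
  two <- lssvmTrainMulticlass(X[1:30, ], y[1:30], 100, 1)
  expect_length(two@machines, 1L)
  bin <- lssvmTrain(X[1:30, ], factor(y[1:30]), 100, 1)
  expect_equal(as.character(lssvmPredictMulticlass(two, X[1:30, ])),
               lssvmPredict(bin, X[1:30, ]))

  # C = 6 -> 15 machines
  X6 <- matrix(rnorm(120), ncol = 2)
  y6 <- rep(letters[1:6], each = 10)
  expect_length(lssvmTrainMulticlass(X6, y6, 1, 1)@machines, 15L)

  # score matrix has one column per class
  sc <- lssvmScores(ens, X[1:5, ])
  expect_equal(colnames(sc), c("a", "b", "c"))
})

test_that("model archives round-trip through the text serialization", {
  set.seed(16)
  s <- blobFeatureSet(rbind(c(0, 0, 0), c(4, 4, 0), c(0, 4, 4)),
                      nPerClass = 8, seed = 16)
  mask <- featureMask(c(TRUE, TRUE, TRUE))
  cfg <- sblConfig(bwoa = bwoaConfig(popSize = 4, maxIter = 2, seed = 1),
                   folds = 2, seed = 1)
  model <- sblFit(s, mask, cfg)
  path <- tempfile(fileext = ".txt")
  saveSblModel(model, path)
  back <- loadSblModel(path)
  q <- featureValues(s)[c(1, 9, 17), ]
  expect_equal(lssvmScores(back@ensemble, scale(q, model@center, model@scale)),
               lssvmScores(model@ensemble, scale(q, model@center, model@scale)),
               tolerance = 1e-10)
  expect_equal(back@gam, model@gam)
  expect_equal(back@sig2, model@sig2)
  expect_identical(maskBits(back@mask), maskBits(model@mask))
})
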
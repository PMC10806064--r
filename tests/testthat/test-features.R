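test_that("time-domain features match their closed forms", {
  expect_equal(emgMav(c(1, -1, 1, -1)), 1)
  expect_equal(emgMav(rep(0, 5)), 0)
  expect_equal(emgMav(3), 3)
  expect_equal(emgRms(rep(-2, 10)), 2)
  expect_equal(emgRms(c(3, 4)), sqrt(12.5))
  expect_equal(emgRms(rep(0, 4)), 0)
  expect_equal(emgVar(c(1, 1, 1)), 0)
  expect_equal(emgVar(c(0, 2)), 2)
  expect_equal(emgIemg(c(1, -1, 1, -1)), 4)
  expect_error(emgMav(numeric()), "empty")
  expect_error(emgVar(1), "two samples")

  set.seed(1)
  x <- rnorm(50)
  expect_equal(emgVar(x + 7), emgVar(x))            # shift invariance
  expect_equal(emgIemg(x), length(x) * emgMav(x))   # identity
  # mean-square decomposition bound
  expect_gte(emgRms(x)^2 + 1e-12, emgVar(x) * (length(x) - 1) / length(x))
})

test_that("feature scaling laws hold under amplitude gain", {
  set.seed(2)
  x <- rnorm(512)
  a <- 3.7
  expect_equal(emgMav(a * x), a * emgMav(x))
  expect_equal(emgRms(a * x), a * emgRms(x))
  expect_equal(emgIemg(a * x), a * emgIemg(x))
  expect_equal(emgVar(a * x), a^2 * emgVar(x))
  psa <- powerSpectrum(a * x, 1000)
  ps <- powerSpectrum(x, 1000)
  expect_equal(meanFrequency(psa), meanFrequency(ps))
  expect_equal(medianPowerFrequency(psa), medianPowerFrequency(ps))
})

test_that("the Welch spectrum localizes tones and conserves power", {
  fs <- 1000
  t <- (0:2047) / fs
  tone <- sin(2 * pi * 100 * t)
  ps <- powerSpectrum(tone, fs)
  expect_equal(ps$frequencies[which.max(ps$densities)], 100, tolerance = 2)
  expect_true(all(ps$densities >= 0))
  expect_equal(utils::tail(ps$frequencies, 1), fs / 2)

  # Parseval: sum(density) * df ~ mean square, checked against the
  # time-domain oracle
  set.seed(3)
  x <- rnorm(4096)
  psx <- powerSpectrum(x, fs)
  df <- psx$frequencies[2] - psx$frequencies[1]
  expect_equal(sum(psx$densities) * df, mean(x^2), tolerance = 0.05)

  # white noise: no single bin dominates
  expect_lt(max(psx$densities) / sum(psx$densities), 0.1)

  expect_error(powerSpectrum(rnorm(4), fs), "too short")
})

test_that("mean and median power frequency follow their discrete-sum oracles", {
  single <- list(frequencies = 80, densities = 1)
  expect_equal(meanFrequency(single), 80)
  expect_equal(medianPowerFrequency(single), 80)

  two <- list(frequencies = c(40, 120), densities = c(1, 1))
  expect_equal(meanFrequency(two), 80)
  mpf <- medianPowerFrequency(two)
  expect_gte(mpf, 40)
  expect_lte(mpf, 120)

  # flat spectrum on [0, F]: both land at F/2 within one bin width
  f <- seq(0, 500, by = 2)
  flat <- list(frequencies = f, densities = rep(1, length(f)))
  expect_equal(meanFrequency(flat), 250, tolerance = 2)
  expect_equal(medianPowerFrequency(flat), 250, tolerance = 2)

  expect_error(meanFrequency(list(frequencies = 1, densities = 0)), "zero")
  expect_error(medianPowerFrequency(list(frequencies = 1, densities = 0)),
               "zero")
})

test_that("composite vectors flatten channel-major to channels x 6 and round-trip", {
  set.seed(4)
  ws <- list(windows = list(matrix(rnorm(16 * 256), 16)),
             labels = "LS-FLX", samplingRate = 1000,
             channelLabels = defaultChannelLabels(16))
  fs <- extractFeatures(ws)
  expect_equal(ncol(featureValues(fs)), 96L)
  expect_equal(colnames(featureValues(fs))[1:6],
               paste0("L.deltoid_", featureNames()))

  one <- extractFeatures(list(windows = list(matrix(rnorm(256), 1)),
                              labels = "NM", samplingRate = 1000,
                              channelLabels = "ch01"))
  expect_equal(ncol(featureValues(one)), 6L)

  M <- matrix(rnorm(16 * 6), 16,
              dimnames = list(defaultChannelLabels(16), featureNames()))
  expect_equal(unflattenFeatures(flattenFeatures(M),
                                 defaultChannelLabels(16)), M)

  expect_error(extractFeatures(list(windows = list(), labels = character(),
                                    samplingRate = 1000)), "empty")
})

test_that("zero-signal windows keep time-domain zeros and are flagged invalid", {
  ws <- list(windows = list(matrix(0, 2, 64), matrix(rnorm(128), 2)),
             labels = c("NM", "NM"), samplingRate = 1000,
             channelLabels = c("a", "b"))
  expect_warning(fs <- extractFeatures(ws), "invalid")
  X <- featureValues(fs)
  expect_equal(unname(X[1, c("a_MAV", "a_RMS", "a_iEMG")]), c(0, 0, 0))
  expect_true(anyNA(X[1, ]))
  expect_false(fs@valid[1])
  expect_true(fs@valid[2])
})
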
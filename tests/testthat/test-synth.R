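test_that("the marching schedule lays out 19 three-second sub-movements in 4 phases", {
  sch <- marchingSchedule()
  e <- scheduleEntries(sch)
  expect_equal(nrow(e), 19L)
  expect_equal(length(unique(e$phase)), 4L)
  expect_true(all(e$end - e$start == 3))
  expect_equal(e$label[1], "LS-FLX")
  expect_equal(e$start[1], 0)
  expect_equal(e$order, 1:19)
  expect_true(all(e$label %in% movementLabels()[1:6]))
  # non-overlap, time order
  expect_true(all(e$start[-1] >= e$end[-19]))
})

test_that("overlapping or zero-length schedule entries are rejected", {
  bad <- data.frame(order = 1:2, label = c("LS-FLX", "LE-FLX"),
                    start = c(0, 2), end = c(3, 5), phase = c(1L, 1L))
  expect_error(new("Schedule", entries = bad), "overlap")
  bad2 <- data.frame(order = 1, label = "LS-FLX", start = 3, end = 3,
                     phase = 1L)
  expect_error(new("Schedule", entries = bad2), "duration")
})

test_that("discrete trials are seeded-deterministic, class-shaped and band-limited", {
  cls <- defaultMovementClasses()
  cfg <- synthConfig()
  a <- makeDiscreteTrial(cls[["LS-FLX"]], 4, cfg, seed = 1)
  b <- makeDiscreteTrial(cls[["LS-FLX"]], 4, cfg, seed = 1)
  expect_identical(emgSamples(a), emgSamples(b))
  expect_equal(nChannels(a), 16L)
  expect_equal(nSamples(a), 4000L)

  # rest class emits only noise
  nm <- makeDiscreteTrial(cls[["NM"]], 4, cfg, seed = 2)
  rmsAll <- apply(emgSamples(nm), 1, function(x) sqrt(mean(x^2)))
  expect_true(all(rmsAll <= 2 * cfg$noiseFloor + cfg$restLevel))

  # strongly activated channel carries >= 3x the energy of a rest channel
  S <- emgSamples(a)
  w <- cls[["LS-FLX"]]@activationWeights
  active <- which.max(w)
  rest <- which.min(w)
  mid <- 1000:3000  # hold phase of the burst
  expect_gte(mean(S[active, mid]^2), 3 * mean(S[rest, mid]^2))

  # >= 95 % of spectral power inside the configured band
  ps <- powerSpectrum(S[active, ], cfg$samplingRate)
  inband <- ps$frequencies >= cfg$band[1] & ps$frequencies <= cfg$band[2]
  expect_gte(sum(ps$densities[inband]) / sum(ps$densities), 0.95)

  expect_error(makeDiscreteTrial(cls[["LS-FLX"]], -1), "positive")
})

test_that("discrete datasets have balanced product counts and per-subject gains", {
  cls <- defaultMovementClasses()
  ds <- makeDiscreteDataset(cls[1:2], trialsPerClass = 3, subjects = 2,
                            duration = 1, seed = 4)
  expect_length(ds$recordings, 12L)
  expect_equal(as.vector(table(ds$labels)), c(6L, 6L))
  one <- makeDiscreteDataset(cls[1], trialsPerClass = 1, subjects = 1,
                             duration = 1, seed = 4)
  expect_length(one$recordings, 1L)
  expect_error(makeDiscreteDataset(list(), 1, 1), "non-empty")

  # channelwise RMS ratios differ between subjects (subjectGainSd > 0)
  r1 <- ds$recordings[[which(ds$subject == "S1" & ds$labels == cls[[1]]@name)[1]]]
  r2 <- ds$recordings[[which(ds$subject == "S2" & ds$labels == cls[[1]]@name)[1]]]
  rms1 <- apply(emgSamples(r1), 1, function(x) sqrt(mean(x^2)))
  rms2 <- apply(emgSamples(r2), 1, function(x) sqrt(mean(x^2)))
  ratio <- rms1 / rms2
  expect_gt(stats::sd(ratio), 0.01)
})

test_that("continuous streams carry an exact ground-truth label track", {
  stream <- makeContinuousStream(marchingSchedule(), seed = 1, padding = 2)
  track <- labelTrack(stream)
  expect_setequal(levels(track), movementLabels())
  # total labeled movement time is 19 x 3 s = 57 s
  tt <- table(track)
  expect_equal(sum(tt[names(tt) != "NM"]) / samplingRate(stream), 57)
  # transitions occur exactly at schedule boundaries
  seg <- segments(stream)
  expect_equal(as.character(track[seg$start[1] + 1]), seg$label[1])
  expect_equal(as.character(track[seg$start[1]]), "NM")

  # empty schedule with padding -> all NM
  empty <- new("Schedule", entries = data.frame(
    order = integer(), label = character(), start = numeric(),
    end = numeric(), phase = integer()))
  rest <- makeContinuousStream(empty, seed = 2, padding = 5)
  expect_true(all(labelTrack(rest) == "NM"))

  # seeded determinism
  s2 <- makeContinuousStream(marchingSchedule(), seed = 1, padding = 2)
  expect_identical(emgSamples(stream), emgSamples(s2))
})

test_that("widening the activation gap between classes raises the Fisher dispersion", {
  cfg <- synthConfig(channelCount = 4L)
  mkSet <- function(gap, seed) {
    w1 <- c(0.5 + gap / 2, 0.5 - gap / 2, 0.1, 0.1)
    w2 <- c(0.5 - gap / 2, 0.5 + gap / 2, 0.1, 0.1)
    names(w1) <- names(w2) <- defaultChannelLabels(4L)
    classes <- list(
      A = new("MovementClass", name = "A", activationWeights = pmin(w1, 1)),
      B = new("MovementClass", name = "B", activationWeights = pmin(w2, 1)))
    ds <- makeDiscreteDataset(classes, trialsPerClass = 6, subjects = 1,
                              config = cfg, duration = 1, seed = seed)
    extractTrialFeatures(ds)
  }
  Jnarrow <- mean(sapply(1:3, function(s) fisherDispersion(mkSet(0.2, s))))
  Jwide <- mean(sapply(1:3, function(s) fisherDispersion(mkSet(0.8, s))))
  expect_gt(Jwide, Jnarrow)
})
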
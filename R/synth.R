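#' Synthetic sEMG generator configuration
#'
#' Bundles the signal-model parameters for the synthetic multichannel sEMG
#' generator: channel count, sampling rate, carrier passband, noise floor,
#' powerline interference, baseline drift, rest-level activation and
#' inter-subject gain variability.
#'
#' The generator emulates a 16-channel wireless surface-EMG setup: each
#' channel carries a band-limited Gaussian carrier (unit RMS, band-pass
#' filtered white noise) scaled by a class-specific activation gain and a
#' trapezoidal burst envelope, plus additive white noise, an optional
#' powerline sinusoid and a slow baseline drift.
#'
#' @param channelCount number of channels (default 16).
#' @param samplingRate sampling rate in Hz (default 1000).
#' @param band carrier passband in Hz, length 2 (default c(20, 450)).
#' @param noiseFloor relative amplitude of the additive white noise.
#' @param powerlineHz powerline interference frequency in Hz (default 50).
#' @param powerlineAmp powerline amplitude (default 0.02).
#' @param driftAmp baseline drift amplitude (default 0.01, at 0.4 Hz).
#' @param restLevel activation gain of inactive channels and of the
#'   no-movement class (default 0.05).
#' @param subjectGainSd standard deviation of the per-subject log-normal
#'   channel gain multipliers (default 0.15).
#'
#' @return a validated list of class \code{"SynthConfig"}.
#' @examples
#' cfg <- synthConfig()
#' cfg$samplingRate
#' @export
synthConfig <- function(channelCount = 16L, samplingRate = 1000,
                        band = c(20, 450), noiseFloor = 0.05,
                        powerlineHz = 50, powerlineAmp = 0.02,
                        driftAmp = 0.01, restLevel = 0.05,
                        subjectGainSd = 0.15) {
  stopifnot(channelCount >= 1, samplingRate > 0,
            length(band) == 2L, band[1] > 0, band[1] < band[2],
            noiseFloor >= 0, powerlineAmp >= 0, driftAmp >= 0,
            restLevel > 0, subjectGainSd >= 0)
  if (samplingRate <= 2 * band[2])
    stop("samplingRate must exceed twice the upper band edge")
  structure(list(channelCount = as.integer(channelCount),
                 samplingRate = samplingRate, band = band,
                 noiseFloor = noiseFloor, powerlineHz = powerlineHz,
                 powerlineAmp = powerlineAmp, driftAmp = driftAmp,
                 restLevel = restLevel, subjectGainSd = subjectGainSd),
            class = "SynthConfig")
}

#' Default channel (muscle) labels
#'
#' Sixteen channels: deltoid, biceps brachii, triceps brachii and
#' brachioradialis on each arm; biceps femoris, semitendinosus, adductor
#' magnus and tensor fasciae latae on each leg.
#'
#' @param channelCount number of channels; labels are recycled or truncated
#'   to this length for non-default counts.
#' @return character vector of channel labels.
#' @export
defaultChannelLabels <- function(channelCount = 16L) {
  upper <- c("deltoid", "biceps_brachii", "triceps_brachii", "brachioradialis")
  lower <- c("biceps_femoris", "semitendinosus", "adductor_magnus",
             "tensor_fasciae_latae")
  full <- c(paste0("L.", upper), paste0("R.", upper),
            paste0("L.", lower), paste0("R.", lower))
  if (channelCount == 16L) return(full)
  rep_len(sprintf("ch%02d", seq_len(channelCount)), channelCount)
}

#' Movement class labels
#' @return the six movement labels plus the no-movement label NM.
#' @export
movementLabels <- function() {
  c("LS-FLX", "LE-FLX", "RS-FLX", "RE-FLX", "LH-FLX", "RH-FLX", "NM")
}

#' Default movement class set
#'
#' Builds the seven \linkS4class{MovementClass} objects (six limb movements
#' plus NM) with per-channel activation maps over the default 16-channel
#' muscle layout: shoulder movements load the deltoid of the moving arm,
#' elbow movements the biceps brachii and brachioradialis, hip movements the
#' hamstring group of the moving leg. Inactive channels and the NM class sit
#' at the configured rest level.
#'
#' @param config a \code{\link{synthConfig}}.
#' @return named list of \linkS4class{MovementClass} objects.
#' @examples
#' cls <- defaultMovementClasses()
#' cls[["LS-FLX"]]
#' @export
defaultMovementClasses <- function(config = synthConfig()) {
  nc <- config$channelCount
  labs <- defaultChannelLabels(nc)
  rest <- config$restLevel
  base <- stats::setNames(rep(rest, nc), labs)
  setw <- function(w, ...) {
    upd <- c(...)
    w[names(upd)] <- upd
    w
  }
  maps <- list(
    "LS-FLX" = setw(base, L.deltoid = 0.95, L.biceps_brachii = 0.50,
                    L.triceps_brachii = 0.45),
    "LE-FLX" = setw(base, L.biceps_brachii = 0.95, L.brachioradialis = 0.75,
                    L.triceps_brachii = 0.50, L.deltoid = 0.30),
    "RS-FLX" = setw(base, R.deltoid = 0.95, R.biceps_brachii = 0.50,
                    R.triceps_brachii = 0.45),
    "RE-FLX" = setw(base, R.biceps_brachii = 0.95, R.brachioradialis = 0.75,
                    R.triceps_brachii = 0.50, R.deltoid = 0.30),
    "LH-FLX" = setw(base, L.biceps_femoris = 0.90, L.semitendinosus = 0.80,
                    L.tensor_fasciae_latae = 0.70, L.adductor_magnus = 0.55),
    "RH-FLX" = setw(base, R.biceps_femoris = 0.90, R.semitendinosus = 0.80,
                    R.tensor_fasciae_latae = 0.70, R.adductor_magnus = 0.55),
    "NM" = base
  )
  if (nc != 16L) {
    # non-default layouts: spread each class's activations over a distinct
    # channel block so classes stay distinguishable
    maps <- lapply(seq_along(movementLabels()), function(i) {
      w <- stats::setNames(rep(rest, nc), labs)
      if (movementLabels()[i] != "NM") {
        idx <- ((i - 1L) %% nc) + 1L
        w[idx] <- 0.95
        w[(idx %% nc) + 1L] <- 0.6
      }
      w
    })
    names(maps) <- movementLabels()
  }
  lapply(stats::setNames(names(maps), names(maps)), function(nm)
    new("MovementClass", name = nm, activationWeights = maps[[nm]]))
}

#' The marching-in-place-with-arm-swinging schedule
#'
#' The standard continuous-task schedule used for stream decoding: 19
#' sub-movements in 4 phases, each lasting 3 s, cycling through the six limb
#' movement classes. Entries are half-open \code{[start, start + 3)} second
#' intervals starting at 0 s.
#'
#' @return a \linkS4class{Schedule} with 19 entries.
#' @examples
#' sch <- marchingSchedule()
#' nrow(scheduleEntries(sch))
#' @export
marchingSchedule <- function() {
  labels <- c("LS-FLX", "LE-FLX", "RS-FLX", "RE-FLX", "LH-FLX", "RH-FLX",
              "LH-FLX", "RE-FLX", "RS-FLX", "LE-FLX", "LS-FLX",
              "LE-FLX", "RS-FLX", "RE-FLX", "LH-FLX", "RH-FLX",
              "LH-FLX", "RE-FLX", "RS-FLX")
  phase <- rep(1:4, c(6L, 5L, 5L, 3L))
  k <- seq_along(labels)
  new("Schedule", entries = data.frame(
    order = k, label = labels, start = 3 * (k - 1), end = 3 * k,
    phase = phase, stringsAsFactors = FALSE))
}

#' @rdname Schedule-class
#' @param x a \linkS4class{Schedule}.
#' @export
scheduleEntries <- function(x) {
  stopifnot(is(x, "Schedule"))
  x@entries
}

# Unit-RMS band-limited Gaussian carrier (4th-order zero-phase Butterworth).
bandLimitedCarrier <- function(n, samplingRate, band) {
  bf <- signal::butter(4, band / (samplingRate / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  r <- sqrt(mean(x^2))
  if (r > 0) x / r else x
}

# Trapezoidal burst envelope on [0, duration) seconds, sampled at fs.
burstEnvelope <- function(n, samplingRate, rise, fall) {
  t <- (seq_len(n) - 1) / samplingRate
  dur <- n / samplingRate
  env <- rep(1, n)
  if (rise > 0) env <- pmin(env, t / rise)
  if (fall > 0) env <- pmin(env, (dur - t) / fall)
  pmax(env, 0)
}

# Additive measurement artifacts: white noise + powerline + slow drift.
artifactChannel <- function(n, config) {
  t <- (seq_len(n) - 1) / config$samplingRate
  x <- config$noiseFloor * stats::rnorm(n)
  if (config$powerlineAmp > 0)
    x <- x + config$powerlineAmp *
      sin(2 * pi * config$powerlineHz * t + stats::runif(1, 0, 2 * pi))
  if (config$driftAmp > 0)
    x <- x + config$driftAmp * sin(2 * pi * 0.4 * t + stats::runif(1, 0, 2 * pi))
  x
}

#' Generate one discrete movement trial
#'
#' Synthesizes a single multichannel recording of one movement class: each
#' channel is its activation gain times a trapezoidal burst envelope times a
#' unit-RMS band-limited Gaussian carrier, plus white noise, powerline
#' interference and baseline drift. Deterministic for a fixed seed.
#'
#' @param cls a \linkS4class{MovementClass}.
#' @param duration trial duration in seconds (typically 4-5 s).
#' @param config a \code{\link{synthConfig}}.
#' @param seed RNG seed.
#' @param subjectGains optional per-channel multiplicative gains (defaults
#'   to 1), used for inter-subject variability.
#' @param subjectId subject identifier stored in the recording.
#' @return an \linkS4class{EmgRecording} with one labeled segment spanning
#'   the trial.
#' @examples
#' cls <- defaultMovementClasses()
#' rec <- makeDiscreteTrial(cls[["LS-FLX"]], duration = 4, seed = 1)
#' rec
#' @export
makeDiscreteTrial <- function(cls, duration = 4, config = synthConfig(),
                              seed = NULL, subjectGains = NULL,
                              subjectId = "S1") {
  if (!is(cls, "MovementClass")) stop("cls must be a MovementClass")
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("duration must be a single positive number of seconds")
  w <- cls@activationWeights
  if (length(w) != config$channelCount)
    stop("activation weights do not match config$channelCount")
  subjectGains <- subjectGains %||% rep(1, config$channelCount)
  n <- round(duration * config$samplingRate)
  withSeed(seed, {
    env <- burstEnvelope(n, config$samplingRate,
                         cls@envelope[["rise"]], cls@envelope[["fall"]])
    S <- matrix(0, nrow = config$channelCount, ncol = n)
    for (c in seq_len(config$channelCount)) {
      carrier <- bandLimitedCarrier(n, config$samplingRate, config$band)
      S[c, ] <- subjectGains[c] * w[c] * env * carrier +
        artifactChannel(n, config)
    }
    new("EmgRecording", samples = S, samplingRate = config$samplingRate,
        channelLabels = names(w) %||% defaultChannelLabels(config$channelCount),
        segments = data.frame(start = 0L, end = n, label = cls@name,
                              stringsAsFactors = FALSE),
        subjectId = subjectId)
  })
}

#' Generate a labeled discrete-trial dataset
#'
#' Produces \code{subjects x length(classes) x trialsPerClass} trials with
#' balanced labels. Each subject receives fixed log-normal per-channel gain
#' multipliers (sd \code{config$subjectGainSd}) emulating electrode placement
#' and physiology differences between subjects.
#'
#' @param classes named list of \linkS4class{MovementClass} (default: the
#'   six movements, without NM).
#' @param trialsPerClass trials per class per subject (>= 1).
#' @param subjects number of subjects (>= 1).
#' @param config a \code{\link{synthConfig}}.
#' @param duration trial duration in seconds.
#' @param seed RNG seed.
#' @return list with elements \code{recordings} (list of
#'   \linkS4class{EmgRecording}), \code{labels} (factor) and \code{subject}
#'   (factor), all of length subjects * classes * trialsPerClass.
#' @export
makeDiscreteDataset <- function(classes = defaultMovementClasses()[movementLabels()[1:6]],
                                trialsPerClass = 10L, subjects = 1L,
                                config = synthConfig(), duration = 4,
                                seed = NULL) {
  if (!length(classes)) stop("class set must be non-empty")
  stopifnot(trialsPerClass >= 1, subjects >= 1)
  nTot <- subjects * length(classes) * trialsPerClass
  seeds <- subSeeds(seed, nTot + subjects)
  gainSeeds <- seeds[seq_len(subjects)]
  trialSeeds <- seeds[-seq_len(subjects)]
  recordings <- vector("list", nTot)
  labels <- character(nTot)
  subject <- character(nTot)
  k <- 0L
  for (s in seq_len(subjects)) {
    gains <- withSeed(gainSeeds[s],
      exp(stats::rnorm(config$channelCount, 0, config$subjectGainSd)))
    sid <- sprintf("S%d", s)
    for (cls in classes) {
      for (tr in seq_len(trialsPerClass)) {
        k <- k + 1L
        recordings[[k]] <- makeDiscreteTrial(cls, duration, config,
                                             seed = trialSeeds[k],
                                             subjectGains = gains,
                                             subjectId = sid)
        labels[k] <- cls@name
        subject[k] <- sid
      }
    }
  }
  list(recordings = recordings, labels = factor(labels),
       subject = factor(subject))
}

#' Generate a continuous movement stream with ground truth
#'
#' Synthesizes one long recording following a \linkS4class{Schedule}: each
#' scheduled entry is a burst of its class's activation pattern; everything
#' outside the entries (including lead-in/lead-out padding) is the
#' no-movement rest state. Class transitions occur exactly at schedule
#' boundaries. The ground-truth label track is stored as the recording's
#' segments; \code{\link{labelTrack}} expands it per sample.
#'
#' @param schedule a \linkS4class{Schedule}.
#' @param config a \code{\link{synthConfig}}.
#' @param seed RNG seed.
#' @param classes named list of \linkS4class{MovementClass} covering every
#'   schedule label plus NM.
#' @param padding lead-in/lead-out rest time in seconds (default 2).
#' @param subjectGains optional per-channel gain multipliers.
#' @param subjectId subject identifier.
#' @return an \linkS4class{EmgRecording}; its segments give the scheduled
#'   movement intervals in samples.
#' @examples
#' stream <- makeContinuousStream(marchingSchedule(), seed = 1)
#' table(labelTrack(stream)) / samplingRate(stream)
#' @export
makeContinuousStream <- function(schedule, config = synthConfig(),
                                 seed = NULL,
                                 classes = defaultMovementClasses(config),
                                 padding = 2, subjectGains = NULL,
                                 subjectId = "S1") {
  stopifnot(is(schedule, "Schedule"), padding >= 0)
  validObject(schedule)
  e <- schedule@entries
  if (nrow(e) && !all(e$label %in% names(classes)))
    stop("schedule labels missing from the class set")
  if (!"NM" %in% names(classes))
    stop("class set must include the NM rest class")
  fs <- config$samplingRate
  totalS <- (if (nrow(e)) max(e$end) else 0) + 2 * padding
  n <- round(totalS * fs)
  nc <- config$channelCount
  subjectGains <- subjectGains %||% rep(1, nc)
  withSeed(seed, {
    # per-channel activation gain over time: rest level outside entries,
    # trapezoidal burst of the entry's class inside it
    G <- matrix(config$restLevel, nrow = nc, ncol = n)
    segs <- data.frame(start = integer(), end = integer(),
                       label = character(), stringsAsFactors = FALSE)
    for (i in seq_len(nrow(e))) {
      cls <- classes[[e$label[i]]]
      i0 <- round((e$start[i] + padding) * fs)
      i1 <- round((e$end[i] + padding) * fs)
      len <- i1 - i0
      env <- burstEnvelope(len, fs, cls@envelope[["rise"]],
                           cls@envelope[["fall"]])
      w <- cls@activationWeights
      for (c in seq_len(nc))
        G[c, (i0 + 1):i1] <- config$restLevel +
          (w[c] - config$restLevel) * env
      segs <- rbind(segs, data.frame(start = i0, end = i1,
                                     label = e$label[i],
                                     stringsAsFactors = FALSE))
    }
    S <- matrix(0, nrow = nc, ncol = n)
    for (c in seq_len(nc)) {
      carrier <- bandLimitedCarrier(n, fs, config$band)
      S[c, ] <- subjectGains[c] * G[c, ] * carrier + artifactChannel(n, config)
    }
    new("EmgRecording", samples = S, samplingRate = fs,
        channelLabels = defaultChannelLabels(nc),
        segments = segs, subjectId = subjectId)
  })
}

#' Per-sample ground-truth label track
#'
#' Expands a recording's labeled segments into one label per sample; samples
#' covered by no segment are NM.
#'
#' @param rec an \linkS4class{EmgRecording}.
#' @return factor of length \code{nSamples(rec)}.
#' @export
labelTrack <- function(rec) {
  stopifnot(is(rec, "EmgRecording"))
  lab <- rep("NM", nSamples(rec))
  seg <- rec@segments
  for (i in seq_len(nrow(seg)))
    lab[(seg$start[i] + 1):seg$end[i]] <- seg$label[i]
  factor(lab)
}
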
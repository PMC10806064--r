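#' Preprocessing filter configuration
#'
#' @param highpass high-pass edge in Hz (default 20).
#' @param lowpass low-pass edge in Hz (default 450).
#' @param notch powerline notch frequency in Hz (default 50); NA disables.
#' @param order Butterworth filter order (default 4).
#' @param normalization "global" (one scale for the whole recording so the
#'   overall max-abs is 1, preserving the inter-channel amplitude pattern
#'   that carries the movement information; the default), "peak"
#'   (per-channel max-abs to 1) or "none".
#' @return a validated list of class \code{"FilterConfig"}.
#' @export
filterConfig <- function(highpass = 20, lowpass = 450, notch = 50,
                         order = 4L,
                         normalization = c("global", "peak", "none")) {
  normalization <- match.arg(normalization)
  stopifnot(highpass > 0, lowpass > highpass, order >= 1)
  structure(list(highpass = highpass, lowpass = lowpass, notch = notch,
                 order = as.integer(order), normalization = normalization),
            class = "FilterConfig")
}

replaceSamples <- function(rec, S) {
  initialize(rec, samples = S)
}

#' Remove per-channel DC bias
#'
#' Subtracts each channel's mean so every channel is zero-mean; shape is
#' unchanged.
#'
#' @param rec an \linkS4class{EmgRecording}.
#' @return the bias-removed recording.
#' @export
removeBias <- function(rec) {
  stopifnot(is(rec, "EmgRecording"))
  if (nSamples(rec) == 0L) stop("recording is empty")
  replaceSamples(rec, rec@samples - rowMeans(rec@samples))
}

#' Zero-phase band-pass and notch filtering
#'
#' Applies a zero-phase (forward-backward) Butterworth band-pass between
#' \code{cfg$highpass} and \code{cfg$lowpass}, followed by a band-stop notch
#' around \code{cfg$notch}, independently per channel. Out-of-band
#' sinusoids are attenuated by at least 20 dB.
#'
#' @param rec an \linkS4class{EmgRecording}.
#' @param cfg a \code{\link{filterConfig}} consistent with the recording's
#'   sampling rate.
#' @return the filtered recording.
#' @export
denoiseRecording <- function(rec, cfg = filterConfig()) {
  stopifnot(is(rec, "EmgRecording"), inherits(cfg, "FilterConfig"))
  nyq <- rec@samplingRate / 2
  if (cfg$lowpass >= nyq)
    stop("lowpass cutoff must be below the Nyquist frequency")
  bp <- signal::butter(cfg$order, c(cfg$highpass, cfg$lowpass) / nyq,
                       type = "pass")
  S <- t(apply(rec@samples, 1L, function(x) signal::filtfilt(bp, x)))
  if (!is.na(cfg$notch)) {
    ns <- signal::butter(2, c(cfg$notch - 2, cfg$notch + 2) / nyq,
                         type = "stop")
    S <- t(apply(S, 1L, function(x) signal::filtfilt(ns, x)))
  }
  replaceSamples(rec, S)
}

#' Amplitude normalization
#'
#' \code{"peak"} rescales each channel so its maximum absolute value is 1
#' (all-zero channels untouched). \code{"global"} divides every channel by
#' the single recording-wide maximum absolute value, which removes overall
#' gain while preserving the relative amplitudes between channels — the
#' pattern the movement classes live in. \code{"none"} is the identity.
#' Both scalings are idempotent.
#'
#' @param rec an \linkS4class{EmgRecording}.
#' @param method normalization method.
#' @return the normalized recording.
#' @export
normalizeRecording <- function(rec, method = c("global", "peak", "none")) {
  stopifnot(is(rec, "EmgRecording"))
  method <- match.arg(method)
  if (method == "none") return(rec)
  S <- rec@samples
  if (method == "global") {
    peak <- max(abs(S))
    if (peak > 0) S <- S / peak
    return(replaceSamples(rec, S))
  }
  peaks <- apply(abs(S), 1L, max)
  nz <- peaks > 0
  S[nz, ] <- S[nz, , drop = FALSE] / peaks[nz]
  replaceSamples(rec, S)
}

#' Standard preprocessing chain
#'
#' Bias removal, zero-phase band-pass + notch filtering, then per-channel
#' peak normalization (per \code{cfg$normalization}).
#'
#' @param rec an \linkS4class{EmgRecording}.
#' @param cfg a \code{\link{filterConfig}}.
#' @return the preprocessed recording.
#' @export
preprocessRecording <- function(rec, cfg = filterConfig()) {
  rec <- removeBias(rec)
  rec <- denoiseRecording(rec, cfg)
  normalizeRecording(rec, cfg$normalization)
}

#' Slide labeled analysis windows over a recording
#'
#' Cuts half-open windows of \code{windowS} seconds every \code{stepS}
#' seconds. Each window carries the label of the segment covering its
#' center sample, or NM when no segment does. The window count is
#' \code{floor((T - windowS)/stepS) + 1}.
#'
#' @param rec an \linkS4class{EmgRecording}.
#' @param windowS window length in seconds.
#' @param stepS step between window starts in seconds
#'   (0 < stepS <= windowS).
#' @return list with \code{windows} (list of channels x n matrices),
#'   \code{labels} (factor), \code{starts} (start sample of each window,
#'   0-based), \code{samplingRate} and \code{channelLabels}. A recording
#'   shorter than one window yields an empty set with a warning.
#' @export
segmentRecording <- function(rec, windowS = 0.25, stepS = 0.125) {
  stopifnot(is(rec, "EmgRecording"))
  if (!(stepS > 0 && stepS <= windowS))
    stop("require 0 < stepS <= windowS")
  fs <- rec@samplingRate
  wlen <- round(windowS * fs)
  step <- round(stepS * fs)
  n <- nSamples(rec)
  if (wlen > n) {
    warning("recording shorter than one window; returning empty window set")
    return(list(windows = list(), labels = factor(character()),
                starts = integer(), samplingRate = fs,
                channelLabels = rec@channelLabels))
  }
  nWin <- floor((n - wlen) / step) + 1L
  starts <- (seq_len(nWin) - 1L) * step
  track <- labelTrack(rec)
  windows <- vector("list", nWin)
  labels <- character(nWin)
  for (i in seq_len(nWin)) {
    idx <- (starts[i] + 1):(starts[i] + wlen)
    windows[[i]] <- rec@samples[, idx, drop = FALSE]
    center <- starts[i] + ceiling(wlen / 2)
    labels[i] <- as.character(track[center])
  }
  list(windows = windows, labels = factor(labels), starts = starts,
       samplingRate = fs, channelLabels = rec@channelLabels)
}
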
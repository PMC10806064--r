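#' Time-domain sEMG features
#'
#' The four standard time-domain features of a single-channel window:
#' mean absolute value \code{emgMav} = (1/N) sum |x|; root mean square
#' \code{emgRms} = sqrt((1/N) sum x^2); unbiased sample variance
#' \code{emgVar} (N-1 denominator); integrated EMG \code{emgIemg} =
#' sum |x| = N * MAV.
#'
#' @param window numeric vector of samples.
#' @return a single numeric value.
#' @examples
#' emgMav(c(1, -1, 1, -1))   # 1
#' emgRms(c(3, 4))           # sqrt(12.5)
#' emgIemg(c(1, -1, 1, -1))  # 4
#' @export
emgMav <- function(window) {
  if (!length(window)) stop("empty window")
  mean(abs(window))
}

#' @rdname emgMav
#' @export
emgRms <- function(window) {
  if (!length(window)) stop("empty window")
  sqrt(mean(window^2))
}

#' @rdname emgMav
#' @export
emgVar <- function(window) {
  if (length(window) < 2L) stop("variance needs at least two samples")
  stats::var(window)
}

#' @rdname emgMav
#' @export
emgIemg <- function(window) {
  if (!length(window)) stop("empty window")
  sum(abs(window))
}

#' One-sided Welch power spectral density
#'
#' Welch's averaged-periodogram PSD: Hamming-windowed segments of length
#' \code{min(segLength, N)} with 50 \% overlap, scaled so that
#' \code{sum(density) * df} approximates the window's mean square (one-sided
#' convention).
#'
#' @param window numeric vector, length >= 8.
#' @param samplingRate sampling rate in Hz.
#' @param segLength maximum Welch segment length (default 256).
#' @return list with \code{frequencies} (Hz, ascending to Nyquist) and
#'   \code{densities} (non-negative).
#' @examples
#' t <- seq(0, 1, by = 1/1000)
#' ps <- powerSpectrum(sin(2 * pi * 100 * t), 1000)
#' ps$frequencies[which.max(ps$densities)]   # ~100
#' @export
powerSpectrum <- function(window, samplingRate, segLength = 256L) {
  N <- length(window)
  if (N < 8L) stop("window too short for spectral estimation (need >= 8)")
  L <- min(as.integer(segLength), N)
  step <- max(1L, L %/% 2L)
  starts <- seq(1L, N - L + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(L) - 1) / (L - 1))  # Hamming
  scale <- 1 / (samplingRate * sum(w^2))
  nf <- L %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- window[s:(s + L - 1L)] * w
    P <- abs(stats::fft(seg))^2 * scale
    acc <- acc + P[seq_len(nf)]
  }
  dens <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when L is even)
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (L %% 2L == 0L) dbl[nf] <- 1
  dens <- dens * dbl
  freqs <- (seq_len(nf) - 1) * samplingRate / L
  list(frequencies = freqs, densities = dens)
}

#' Spectral sEMG features
#'
#' \code{meanFrequency} is the power-weighted mean frequency
#' sum(f * P) / sum(P). \code{medianPowerFrequency} is the smallest
#' frequency at which cumulative power reaches half the total, with linear
#' interpolation inside the crossing bin.
#'
#' @param spectrum a list with \code{frequencies} and \code{densities}
#'   as returned by \code{\link{powerSpectrum}}.
#' @return frequency in Hz.
#' @export
meanFrequency <- function(spectrum) {
  P <- spectrum$densities
  tot <- sum(P)
  if (tot <= 0) stop("zero total power: mean frequency undefined")
  sum(spectrum$frequencies * P) / tot
}

#' @rdname meanFrequency
#' @export
medianPowerFrequency <- function(spectrum) {
  f <- spectrum$frequencies
  P <- spectrum$densities
  tot <- sum(P)
  if (tot <= 0) stop("zero total power: median power frequency undefined")
  cs <- cumsum(P)
  half <- tot / 2
  j <- which(cs >= half)[1L]
  if (j == 1L) return(f[1L])
  # linear interpolation between the cumulative sums at bins j-1 and j
  f[j - 1L] + (f[j] - f[j - 1L]) * (half - cs[j - 1L]) / (cs[j] - cs[j - 1L])
}

#' Feature names in their fixed order
#' @return c("MAV", "RMS", "VAR", "iEMG", "MF", "MPF")
#' @export
featureNames <- function() c("MAV", "RMS", "VAR", "iEMG", "MF", "MPF")

# channels x 6 feature matrix for one multichannel window;
# spectral features are NA (and ok = FALSE) for zero-power channels.
windowFeatureMatrix <- function(W, samplingRate) {
  nc <- nrow(W)
  M <- matrix(NA_real_, nrow = nc, ncol = 6L,
              dimnames = list(rownames(W), featureNames()))
  ok <- TRUE
  for (c in seq_len(nc)) {
    x <- W[c, ]
    M[c, 1:4] <- c(emgMav(x), emgRms(x), emgVar(x), emgIemg(x))
    if (all(x == 0)) {
      ok <- FALSE
      next
    }
    ps <- powerSpectrum(x, samplingRate)
    if (sum(ps$densities) <= 0) {
      ok <- FALSE
      next
    }
    M[c, 5] <- meanFrequency(ps)
    M[c, 6] <- medianPowerFrequency(ps)
  }
  attr(M, "ok") <- ok
  M
}

#' Flatten a channels x features matrix channel-major
#'
#' \code{flattenFeatures} turns a channels x 6 matrix into a length
#' channels*6 vector named \code{<channel>_<feature>} (channel-major order);
#' \code{unflattenFeatures} reverses it exactly.
#'
#' @param M channels x 6 feature matrix with dimnames.
#' @return named numeric vector of length channels * 6.
#' @export
flattenFeatures <- function(M) {
  v <- as.vector(t(M))
  names(v) <- as.vector(t(outer(rownames(M), colnames(M), paste, sep = "_")))
  v
}

#' @rdname flattenFeatures
#' @param v flattened vector from \code{flattenFeatures}.
#' @param channelLabels channel names.
#' @export
unflattenFeatures <- function(v, channelLabels) {
  nf <- length(featureNames())
  M <- matrix(v, nrow = length(channelLabels), ncol = nf, byrow = TRUE,
              dimnames = list(channelLabels, featureNames()))
  M
}

#' Extract the six-feature composite vectors from a window set
#'
#' Computes the channels x 6 feature matrix (MAV, RMS, VAR, iEMG, MF, MPF)
#' for every window and flattens each channel-major into a D-dimensional
#' composite vector (D = channels * 6; 96 for 16 channels). Windows with a
#' zero-power channel get NA spectral features and are flagged invalid.
#'
#' @param windowSet a window set from \code{\link{segmentRecording}}, or any
#'   list with \code{windows}, \code{labels}, \code{samplingRate},
#'   \code{channelLabels}.
#' @return a \linkS4class{LabeledFeatureSet} with empirical class priors.
#' @export
extractFeatures <- function(windowSet) {
  ws <- windowSet$windows
  if (!length(ws)) stop("empty window set")
  nc <- vapply(ws, nrow, integer(1))
  if (length(unique(nc)) != 1L)
    stop("channel count differs across windows")
  labs <- windowSet$channelLabels %||% sprintf("ch%02d", seq_len(nc[1]))
  rows <- vector("list", length(ws))
  ok <- logical(length(ws))
  for (i in seq_along(ws)) {
    W <- ws[[i]]
    rownames(W) <- labs
    M <- windowFeatureMatrix(W, windowSet$samplingRate)
    ok[i] <- attr(M, "ok")
    rows[[i]] <- flattenFeatures(M)
  }
  X <- do.call(rbind, rows)
  y <- factor(windowSet$labels)
  if (any(!ok))
    warning(sum(!ok), " window(s) had zero-power channels; flagged invalid")
  newFeatureSet(X, y, valid = ok)
}

# Construct a LabeledFeatureSet with empirical priors.
newFeatureSet <- function(X, y, priors = NULL, valid = NULL) {
  y <- droplevels(factor(y))
  if (is.null(priors)) {
    tab <- table(y)
    priors <- as.numeric(tab) / sum(tab)
    names(priors) <- names(tab)
  }
  new("LabeledFeatureSet", X = X, y = y, priors = priors,
      valid = valid %||% rep(TRUE, nrow(X)))
}

#' Extract one composite feature vector per discrete trial
#'
#' Treats each whole trial as a single analysis window (the discrete
#' protocol yields one composite vector per movement instance) and stacks
#' the flattened vectors into a \linkS4class{LabeledFeatureSet}.
#'
#' @param dataset output of \code{\link{makeDiscreteDataset}}, or a list
#'   with \code{recordings} and \code{labels}.
#' @param cfg a \code{\link{filterConfig}} applied to every trial.
#' @return a \linkS4class{LabeledFeatureSet}.
#' @export
extractTrialFeatures <- function(dataset, cfg = filterConfig()) {
  recs <- dataset$recordings
  if (!length(recs)) stop("empty dataset")
  pre <- lapply(recs, preprocessRecording, cfg = cfg)
  ws <- list(windows = lapply(pre, emgSamples),
             labels = dataset$labels,
             samplingRate = samplingRate(pre[[1]]),
             channelLabels = channelLabels(pre[[1]]))
  extractFeatures(ws)
}
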
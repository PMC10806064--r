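#' @import methods
NULL

#' Multichannel surface EMG recording
#'
#' The central signal container: a channels x samples matrix in arbitrary
#' signal units together with its sampling rate, channel (muscle) labels,
#' optional labeled segments and a subject identifier. Segments use 0-based,
#' half-open sample intervals \code{[start, end)}.
#'
#' @slot samples numeric matrix, channels x time samples.
#' @slot samplingRate sampling rate in Hz.
#' @slot channelLabels character vector, one muscle name per channel.
#' @slot segments data.frame with columns \code{start}, \code{end} (sample
#'   indices, 0-based half-open) and \code{label}; may have zero rows.
#' @slot subjectId subject identifier.
#'
#' @export
setClass("EmgRecording",
  representation(
    samples = "matrix",
    samplingRate = "numeric",
    channelLabels = "character",
    segments = "data.frame",
    subjectId = "character"
  ),
  prototype(
    segments = data.frame(start = integer(), end = integer(),
                          label = character()),
    subjectId = "S1"
  ),
  validity = function(object) {
    msg <- character()
    if (anyNA(object@samples))
      msg <- c(msg, "samples must not contain missing values")
    if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
      msg <- c(msg, "samplingRate must be a single positive number")
    if (length(object@channelLabels) != nrow(object@samples))
      msg <- c(msg, "channelLabels length must equal the channel count")
    seg <- object@segments
    if (nrow(seg)) {
      if (!all(c("start", "end", "label") %in% names(seg)))
        msg <- c(msg, "segments needs columns start, end, label")
      else if (any(seg$start < 0) || any(seg$end > ncol(object@samples)) ||
               any(seg$end <= seg$start))
        msg <- c(msg, "segments must lie within [0, n_samples) with end > start")
    }
    if (length(msg)) msg else TRUE
  }
)

#' A movement class with its muscle activation pattern
#'
#' Describes one movement (e.g. left-shoulder flexion/extension, LS-FLX) by a
#' per-channel activation gain in (0, 1] and a trapezoidal burst envelope
#' (rise/fall times in seconds). The no-movement class NM carries only the
#' configured rest-level gain on every channel.
#'
#' @slot name class label.
#' @slot activationWeights per-channel gain in (0, 1].
#' @slot envelope named numeric with \code{rise} and \code{fall} seconds.
#'
#' @export
setClass("MovementClass",
  representation(
    name = "character",
    activationWeights = "numeric",
    envelope = "numeric"
  ),
  prototype(envelope = c(rise = 0.3, fall = 0.3)),
  validity = function(object) {
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
      msg <- c(msg, "name must be a single non-empty string")
    w <- object@activationWeights
    if (!length(w) || any(w <= 0) || any(w > 1))
      msg <- c(msg, "activationWeights must lie in (0, 1]")
    if (!all(c("rise", "fall") %in% names(object@envelope)) ||
        any(object@envelope < 0))
      msg <- c(msg, "envelope needs non-negative 'rise' and 'fall' entries")
    if (length(msg)) msg else TRUE
  }
)

#' An ordered movement schedule for continuous streams
#'
#' Ordered, non-overlapping timed entries (class label, start s, end s)
#' grouped into phases; gaps between entries are implicitly no-movement.
#'
#' @slot entries data.frame with columns \code{order}, \code{label},
#'   \code{start}, \code{end} (seconds) and \code{phase}.
#'
#' @export
setClass("Schedule",
  representation(entries = "data.frame"),
  validity = function(object) {
    e <- object@entries
    msg <- character()
    need <- c("order", "label", "start", "end", "phase")
    if (!all(need %in% names(e)))
      return(paste("entries needs columns:", paste(need, collapse = ", ")))
    if (nrow(e)) {
      if (any(e$end <= e$start))
        msg <- c(msg, "every entry must have positive duration")
      if (is.unsorted(e$start, strictly = TRUE))
        msg <- c(msg, "entries must be time-ordered")
      if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)]))
        msg <- c(msg, "entries must not overlap")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Labeled feature set
#'
#' Samples x D feature matrix with class labels and class prior weights;
#' the container consumed by the separability scoring, feature selection
#' and classification stages. Column names follow
#' \code{<channel>_<feature>} in channel-major flatten order, so 16 channels
#' with the six standard features give D = 96.
#'
#' @slot X numeric matrix, samples x D.
#' @slot y factor of class labels, length nrow(X).
#' @slot priors named numeric class priors, non-negative, summing to 1.
#' @slot valid logical per-sample flag; FALSE marks degenerate windows
#'   (e.g. zero signal, where spectral features are undefined).
#'
#' @export
setClass("LabeledFeatureSet",
  representation(
    X = "matrix",
    y = "factor",
    priors = "numeric",
    valid = "logical"
  ),
  validity = function(object) {
    msg <- character()
    if (nrow(object@X) != length(object@y))
      msg <- c(msg, "nrow(X) must equal length(y)")
    if (length(object@valid) != nrow(object@X))
      msg <- c(msg, "valid flag must have one entry per sample")
    p <- object@priors
    if (length(p)) {
      if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
        msg <- c(msg, "priors must be non-negative and sum to 1")
      if (!setequal(names(p), levels(object@y)))
        msg <- c(msg, "priors must be named by the class levels")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Binary feature-selection mask
#'
#' A binary vector over the D feature dimensions with fixed cardinality d:
#' the output of the genetic-algorithm subset search under the Fisher
#' dispersion criterion.
#'
#' @slot bits logical vector of length D.
#'
#' @export
setClass("FeatureMask",
  representation(bits = "logical"),
  validity = function(object) {
    if (!length(object@bits)) return("mask must have length >= 1")
    if (anyNA(object@bits)) return("mask bits must not be NA")
    if (!any(object@bits)) return("mask must select at least one dimension")
    TRUE
  }
)

#' One trained binary least squares SVM
#'
#' Dual coefficients and bias solving the LSSVM classifier system
#' \eqn{[0, y'; y, \Omega + I/\gamma][b; \alpha] = [0; 1]} with
#' \eqn{\Omega_{kl} = y_k y_l K(x_k, x_l)} and RBF kernel
#' \eqn{K(x,z) = \exp(-\|x-z\|^2 / sig2)}.
#'
#' @slot alpha dual coefficients, one per training sample.
#' @slot b bias.
#' @slot gam regularization parameter (> 0).
#' @slot sig2 RBF squared-bandwidth parameter (> 0).
#' @slot X training inputs, samples x dims.
#' @slot y training labels in -1/+1.
#' @slot classPair the two original class labels mapped to (+1, -1).
#' @slot residual relative residual of the defining linear system.
#'
#' @export
setClass("TrainedLssvm",
  representation(
    alpha = "numeric", b = "numeric", gam = "numeric", sig2 = "numeric",
    X = "matrix", y = "numeric", classPair = "character",
    residual = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    if (object@gam <= 0) msg <- c(msg, "gam must be > 0")
    if (object@sig2 <= 0) msg <- c(msg, "sig2 must be > 0")
    if (!all(object@y %in% c(-1, 1)))
      msg <- c(msg, "y must be coded -1/+1")
    if (length(object@alpha) != nrow(object@X))
      msg <- c(msg, "alpha must have one entry per training sample")
    if (length(msg)) msg else TRUE
  }
)

#' One-vs-one multiclass LSSVM ensemble
#'
#' @slot machines list of \linkS4class{TrainedLssvm}, one per unordered
#'   class pair (C classes give C(C-1)/2 machines).
#' @slot classes ordered class labels.
#'
#' @export
setClass("MulticlassLssvm",
  representation(machines = "list", classes = "character"),
  validity = function(object) {
    C <- length(object@classes)
    if (C < 2) return("need at least two classes")
    if (length(object@machines) != C * (C - 1) / 2)
      return("expected one machine per unordered class pair")
    TRUE
  }
)

#' Fitted SBL model
#'
#' The end-to-end sine-BWOA-tuned LSSVM: the one-vs-one ensemble, the
#' feature mask it was trained under, the tuned (gam, sig2) pair and the
#' optimizer's best-fitness history.
#'
#' @slot ensemble a \linkS4class{MulticlassLssvm}.
#' @slot mask a \linkS4class{FeatureMask} over the full feature dimension.
#' @slot gam tuned regularization.
#' @slot sig2 tuned RBF parameter.
#' @slot center,scale per-dimension standardization of the masked training
#'   features, applied to every query before the kernel (the six features
#'   live on very different scales).
#' @slot history per-iteration best cross-validation error of the tuner.
#'
#' @export
setClass("SblModel",
  representation(
    ensemble = "MulticlassLssvm",
    mask = "FeatureMask",
    gam = "numeric", sig2 = "numeric",
    center = "numeric", scale = "numeric",
    history = "numeric"
  )
)

#' Classification evaluation report
#'
#' Confusion matrix (predicted x true), per-class and overall accuracy in
#' percent, and macro one-vs-rest ROC/AUC.
#'
#' @slot confusion integer matrix, predicted classes in rows, true in columns.
#' @slot perClassAccuracy named numeric, percent.
#' @slot overallAccuracy numeric, percent.
#' @slot auc macro one-vs-rest AUC (NA when scores are unavailable).
#' @slot roc list of per-class ROC point data.frames (fpr, tpr).
#'
#' @export
setClass("EvaluationReport",
  representation(
    confusion = "matrix",
    perClassAccuracy = "numeric",
    overallAccuracy = "numeric",
    auc = "numeric",
    roc = "list"
  ),
  validity = function(object) {
    cm <- object@confusion
    msg <- character()
    if (any(cm < 0)) msg <- c(msg, "confusion entries must be >= 0")
    if (!identical(rownames(cm), colnames(cm)))
      msg <- c(msg, "confusion row/column label sets must match")
    acc <- c(object@perClassAccuracy, object@overallAccuracy)
    if (any(acc < -1e-9 | acc > 100 + 1e-9, na.rm = TRUE))
      msg <- c(msg, "accuracies must lie in [0, 100] percent")
    if (length(msg)) msg else TRUE
  }
)
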
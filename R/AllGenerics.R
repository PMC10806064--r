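#' @rdname EmgRecording-class
#' @param object,x an object.
#' @export
setGeneric("emgSamples", function(x) standardGeneric("emgSamples"))

#' @rdname EmgRecording-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname EmgRecording-class
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname EmgRecording-class
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname EmgRecording-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname EmgRecording-class
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))

#' @rdname LabeledFeatureSet-class
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname LabeledFeatureSet-class
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname LabeledFeatureSet-class
#' @export
setGeneric("classPriors", function(x) standardGeneric("classPriors"))

#' @rdname FeatureMask-class
#' @export
setGeneric("maskBits", function(x) standardGeneric("maskBits"))

#' @rdname FeatureMask-class
#' @export
setGeneric("maskCardinality", function(x) standardGeneric("maskCardinality"))

setMethod("emgSamples", "EmgRecording", function(x) x@samples)
setMethod("samplingRate", "EmgRecording", function(x) x@samplingRate)
setMethod("channelLabels", "EmgRecording", function(x) x@channelLabels)
setMethod("nChannels", "EmgRecording", function(x) nrow(x@samples))
setMethod("nSamples", "EmgRecording", function(x) ncol(x@samples))
setMethod("segments", "EmgRecording", function(x) x@segments)

setMethod("featureValues", "LabeledFeatureSet", function(x) x@X)
setMethod("classLabels", "LabeledFeatureSet", function(x) x@y)
setMethod("classPriors", "LabeledFeatureSet", function(x) x@priors)

setMethod("maskBits", "FeatureMask", function(x) x@bits)
setMethod("maskCardinality", "FeatureMask", function(x) sum(x@bits))

setMethod("show", "EmgRecording", function(object) {
  cat(sprintf("EmgRecording: %d channel(s) x %d samples @ %g Hz (%.2f s)\n",
              nChannels(object), nSamples(object), object@samplingRate,
              nSamples(object) / object@samplingRate))
  cat(sprintf("  subject: %s; labeled segments: %d\n",
              object@subjectId, nrow(object@segments)))
})

setMethod("show", "Schedule", function(object) {
  e <- object@entries
  cat(sprintf("Schedule: %d entries in %d phase(s), %g-%g s\n",
              nrow(e), length(unique(e$phase)),
              if (nrow(e)) min(e$start) else 0,
              if (nrow(e)) max(e$end) else 0))
})

setMethod("show", "LabeledFeatureSet", function(object) {
  cat(sprintf("LabeledFeatureSet: %d sample(s) x %d feature(s), %d class(es)\n",
              nrow(object@X), ncol(object@X), nlevels(object@y)))
  print(table(object@y))
})

setMethod("show", "FeatureMask", function(object) {
  cat(sprintf("FeatureMask: %d of %d dimension(s) selected\n",
              sum(object@bits), length(object@bits)))
})

setMethod("show", "TrainedLssvm", function(object) {
  cat(sprintf(
    "TrainedLssvm (%s vs %s): n = %d, gam = %g, sig2 = %g, residual = %.2e\n",
    object@classPair[1], object@classPair[2], nrow(object@X),
    object@gam, object@sig2, object@residual))
})

setMethod("show", "MulticlassLssvm", function(object) {
  cat(sprintf("MulticlassLssvm: %d classes, %d one-vs-one machine(s)\n",
              length(object@classes), length(object@machines)))
})

setMethod("show", "SblModel", function(object) {
  cat(sprintf("SblModel: gam = %g, sig2 = %g, mask %d/%d, %d tuning iteration(s)\n",
              object@gam, object@sig2, sum(object@mask@bits),
              length(object@mask@bits), length(object@history)))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport: overall accuracy %.2f %%",
              object@overallAccuracy))
  if (!is.na(object@auc)) cat(sprintf(", macro AUC %.4f", object@auc))
  cat("\nConfusion matrix (rows = predicted, cols = true):\n")
  print(object@confusion)
})
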
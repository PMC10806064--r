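#' End-to-end SBL pipeline configuration
#'
#' Bundles the hyperparameter search space (log10 boxes for gam and sig2,
#' chosen wide enough to contain typical optima), the optimizer settings,
#' the cross-validation fold count, the train/test split fraction, the
#' continuous-decoding window geometry and the preprocessing filter.
#'
#' @param gamRange log10 search range of the regularization gam
#'   (default c(-2, 4), i.e. gam in [1e-2, 1e4]).
#' @param sig2Range log10 search range of the RBF parameter sig2
#'   (default c(-2, 3)).
#' @param bwoa a \code{\link{bwoaConfig}} for the tuner.
#' @param folds stratified CV folds of the tuning objective (default 5).
#' @param trainFrac train fraction of the discrete split (default 0.7).
#' @param windowS,stepS decoding window length and step in seconds
#'   (defaults 0.25 and 0.125).
#' @param filter a \code{\link{filterConfig}}.
#' @param seed RNG seed for splits and tuning.
#' @return a validated list of class \code{"SblConfig"}.
#' @export
sblConfig <- function(gamRange = c(-2, 4), sig2Range = c(-2, 3),
                      bwoa = bwoaConfig(), folds = 5L, trainFrac = 0.7,
                      windowS = 0.25, stepS = 0.125,
                      filter = filterConfig(), seed = NULL) {
  stopifnot(trainFrac > 0, trainFrac < 1, folds >= 2,
            length(gamRange) == 2L, length(sig2Range) == 2L)
  structure(list(gamRange = gamRange, sig2Range = sig2Range, bwoa = bwoa,
                 folds = as.integer(folds), trainFrac = trainFrac,
                 windowS = windowS, stepS = stepS, filter = filter,
                 seed = seed),
            class = "SblConfig")
}

#' Mask the columns of a feature set
#'
#' @param set a \linkS4class{LabeledFeatureSet}.
#' @param mask a \linkS4class{FeatureMask} matching the set's dimension.
#' @return the set restricted to the selected dimensions.
#' @export
applyMask <- function(set, mask) {
  stopifnot(is(set, "LabeledFeatureSet"), is(mask, "FeatureMask"))
  if (length(mask@bits) != ncol(set@X))
    stop("mask length does not match the feature dimension")
  new("LabeledFeatureSet", X = set@X[, mask@bits, drop = FALSE],
      y = set@y, priors = set@priors, valid = set@valid)
}

#' Stratified train/test split of a feature set
#'
#' Splits samples class by class (deterministically under the seed) so the
#' split is stratified; each class keeps at least one sample on each side
#' when it has two or more.
#'
#' @param set a \linkS4class{LabeledFeatureSet}.
#' @param trainFrac train fraction in (0, 1).
#' @param seed RNG seed.
#' @return list with \code{train} and \code{test} feature sets.
#' @export
splitFeatureSet <- function(set, trainFrac = 0.7, seed = NULL) {
  stopifnot(is(set, "LabeledFeatureSet"), trainFrac > 0, trainFrac < 1)
  y <- set@y
  withSeed(seed, {
    trainIdx <- integer()
    for (l in levels(y)) {
      idx <- which(y == l)
      nTr <- max(1L, min(length(idx) - 1L,
                         round(trainFrac * length(idx))))
      if (length(idx) == 1L) nTr <- 1L
      trainIdx <- c(trainIdx, sample(idx, nTr))
    }
    trainIdx <- sort(trainIdx)
    testIdx <- setdiff(seq_along(y), trainIdx)
    list(train = newFeatureSet(set@X[trainIdx, , drop = FALSE], y[trainIdx],
                               valid = set@valid[trainIdx]),
         test = newFeatureSet(set@X[testIdx, , drop = FALSE], y[testIdx],
                              valid = set@valid[testIdx]))
  })
}

# Stratified fold assignment, deterministic under the current RNG state.
stratifiedFolds <- function(y, k) {
  fold <- integer(length(y))
  for (l in levels(y)) {
    idx <- sample(which(y == l))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# k-fold CV misclassification rate of a one-vs-one LSSVM at (gam, sig2).
cvError <- function(X, y, gam, sig2, fold) {
  k <- max(fold)
  wrong <- 0L
  for (f in seq_len(k)) {
    tr <- fold != f
    if (nlevels(droplevels(y[tr])) < 2L) next
    ens <- lssvmTrainMulticlass(X[tr, , drop = FALSE], droplevels(y[tr]),
                                gam, sig2)
    pred <- lssvmPredictMulticlass(ens, X[!tr, , drop = FALSE])
    wrong <- wrong + sum(as.character(pred) != as.character(y[!tr]))
  }
  wrong / length(y)
}

#' Tune the LSSVM hyperparameters with the sine-chaotic black widow optimizer
#'
#' Minimizes the stratified k-fold cross-validation misclassification rate
#' of the one-vs-one LSSVM over the (gam, sig2) box, searching in log10
#' space. The fold assignment is fixed once per call so the objective is
#' deterministic.
#'
#' @param set a \linkS4class{LabeledFeatureSet} (the training set).
#' @param cfg an \code{\link{sblConfig}}; classes smaller than the fold
#'   count reduce the fold count with a warning.
#' @return list with \code{gam}, \code{sig2}, \code{cvError} and
#'   \code{history} (per-iteration best CV error).
#' @export
sblTune <- function(set, cfg = sblConfig()) {
  stopifnot(is(set, "LabeledFeatureSet"))
  y <- droplevels(set@y)
  if (nlevels(y) < 2L) stop("tuning needs at least two classes")
  k <- cfg$folds
  minClass <- min(table(y))
  if (minClass < k) {
    k <- max(2L, as.integer(minClass))
    warning("smallest class has ", minClass,
            " samples; folds reduced to ", k)
  }
  seeds <- subSeeds(cfg$seed, 2L)
  fold <- withSeed(seeds[1], stratifiedFolds(y, k))
  X <- set@X
  objective <- function(p) cvError(X, y, 10^p[1], 10^p[2], fold)
  space <- searchSpace(c(cfg$gamRange[1], cfg$sig2Range[1]),
                       c(cfg$gamRange[2], cfg$sig2Range[2]))
  bw <- cfg$bwoa
  bw$seed <- seeds[2]
  res <- bwoaOptimize(objective, space, bw)
  list(gam = 10^res$par[1], sig2 = 10^res$par[2],
       cvError = res$value, history = res$history)
}

#' Fit the full SBL model
#'
#' Applies the feature mask, standardizes each retained dimension to zero
#' mean and unit variance (the six features live on very different scales,
#' which a single RBF bandwidth cannot absorb), tunes (gam, sig2) by
#' cross-validated sine-BWOA search, then trains the final one-vs-one LSSVM
#' ensemble on the whole training set at the tuned parameters. The
#' standardization is stored in the model and applied to every query.
#'
#' @param set the training \linkS4class{LabeledFeatureSet} (unmasked).
#' @param mask a \linkS4class{FeatureMask} over the full dimension.
#' @param cfg an \code{\link{sblConfig}}.
#' @return an \linkS4class{SblModel}.
#' @export
sblFit <- function(set, mask, cfg = sblConfig()) {
  stopifnot(is(set, "LabeledFeatureSet"), is(mask, "FeatureMask"))
  masked <- applyMask(set, mask)
  center <- colMeans(masked@X)
  scale <- apply(masked@X, 2L, stats::sd)
  scale[!is.finite(scale) | scale <= 0] <- 1
  Z <- scale(masked@X, center = center, scale = scale)
  zset <- newFeatureSet(Z, masked@y, valid = masked@valid)
  tuned <- sblTune(zset, cfg)
  ens <- lssvmTrainMulticlass(Z, masked@y, tuned$gam, tuned$sig2)
  new("SblModel", ensemble = ens, mask = mask, gam = tuned$gam,
      sig2 = tuned$sig2, center = unname(center), scale = unname(scale),
      history = tuned$history)
}

# Mask + standardize query features with a model's stored scaling.
modelFeatures <- function(model, set) {
  masked <- applyMask(set, model@mask)
  Z <- scale(masked@X, center = model@center, scale = model@scale)
  list(X = unname(Z), y = masked@y, valid = masked@valid)
}

# Build an EvaluationReport from predictions, truths and optional
# per-class score matrix (for macro one-vs-rest ROC/AUC via pROC).
buildReport <- function(pred, truth, scores = NULL) {
  classes <- sort(union(levels(factor(pred)), levels(factor(truth))))
  pred <- factor(as.character(pred), levels = classes)
  truth <- factor(as.character(truth), levels = classes)
  cm <- table(predicted = pred, true = truth)
  cm <- matrix(as.integer(cm), nrow = length(classes),
               dimnames = list(classes, classes))
  perClass <- 100 * diag(cm) / pmax(colSums(cm), 1L)
  perClass[colSums(cm) == 0L] <- NA_real_
  overall <- 100 * sum(diag(cm)) / sum(cm)
  auc <- NA_real_
  roc <- list()
  if (!is.null(scores)) {
    aucs <- c()
    for (cl in colnames(scores)) {
      isPos <- truth == cl
      if (any(isPos) && any(!isPos)) {
        r <- pROC::roc(response = as.integer(isPos),
                       predictor = scores[, cl],
                       levels = c(0, 1), direction = "<", quiet = TRUE)
        aucs[cl] <- as.numeric(pROC::auc(r))
        roc[[cl]] <- data.frame(fpr = 1 - r$specificities,
                                tpr = r$sensitivities)
      }
    }
    if (length(aucs)) auc <- mean(aucs)
  }
  new("EvaluationReport", confusion = cm,
      perClassAccuracy = perClass, overallAccuracy = overall,
      auc = auc, roc = roc)
}

#' Evaluate an SBL model on a discrete test set
#'
#' Applies the model's mask, predicts every test sample, and builds the
#' confusion matrix (predicted x true), per-class and overall accuracy in
#' percent, and the macro one-vs-rest AUC from the ensemble's per-class
#' decision-value scores.
#'
#' @param model an \linkS4class{SblModel}.
#' @param testSet an unmasked \linkS4class{LabeledFeatureSet}; its labels
#'   must all be known to the model.
#' @return an \linkS4class{EvaluationReport}.
#' @export
evaluateDiscrete <- function(model, testSet) {
  stopifnot(is(model, "SblModel"), is(testSet, "LabeledFeatureSet"))
  unseen <- setdiff(levels(droplevels(testSet@y)), model@ensemble@classes)
  if (length(unseen))
    stop("test set contains labels unseen in training: ",
         paste(unseen, collapse = ", "))
  q <- modelFeatures(model, testSet)
  pred <- lssvmPredictMulticlass(model@ensemble, q$X)
  scores <- lssvmScores(model@ensemble, q$X)
  buildReport(pred, factor(q$y, levels = model@ensemble@classes), scores)
}

#' Window features of a continuous stream
#'
#' The shared feature path for continuous-stream work: bias removal and
#' zero-phase filtering per \code{cfg$filter}, sliding windows of
#' \code{cfg$windowS} every \code{cfg$stepS} labeled from the stream's
#' ground-truth segments, then composite feature extraction. No
#' per-recording amplitude normalization is applied on this path: a causal
#' decoder cannot know a stream's future maximum, and whole-recording
#' rescaling misbehaves on low-activity streams; amplitude consistency
#' between training and decoding instead comes from the feature
#' standardization stored in the fitted model. Use this same function to
#' build the training windows of a continuous model.
#'
#' @param stream an \linkS4class{EmgRecording} with ground-truth segments.
#' @param cfg an \code{\link{sblConfig}}.
#' @return a \linkS4class{LabeledFeatureSet} of window features.
#' @export
streamFeatures <- function(stream, cfg = sblConfig()) {
  stopifnot(is(stream, "EmgRecording"))
  fcfg <- cfg$filter
  fcfg$normalization <- "none"
  pre <- preprocessRecording(stream, fcfg)
  pre@segments <- stream@segments
  extractFeatures(segmentRecording(pre, cfg$windowS, cfg$stepS))
}

# Movement segments plus the complementary NM gap segments of a stream.
fullSegmentTable <- function(rec) {
  seg <- rec@segments
  seg <- seg[order(seg$start), , drop = FALSE]
  n <- nSamples(rec)
  out <- data.frame(start = integer(), end = integer(), label = character(),
                    stringsAsFactors = FALSE)
  cursor <- 0L
  for (i in seq_len(nrow(seg))) {
    if (seg$start[i] > cursor)
      out <- rbind(out, data.frame(start = cursor, end = seg$start[i],
                                   label = "NM"))
    out <- rbind(out, seg[i, c("start", "end", "label")])
    cursor <- seg$end[i]
  }
  if (cursor < n)
    out <- rbind(out, data.frame(start = cursor, end = n, label = "NM"))
  rownames(out) <- NULL
  out
}

#' Decode a continuous stream
#'
#' Preprocesses the stream, slides labeled windows, extracts the composite
#' features, classifies every window with the SBL model (which must include
#' the NM rest class), then aggregates window predictions to one label per
#' ground-truth segment by majority vote (ties resolve to NM). Gap
#' intervals between scheduled movements are scored as NM segments.
#'
#' @param model an \linkS4class{SblModel} trained with an NM class.
#' @param stream an \linkS4class{EmgRecording} whose segments carry the
#'   ground truth.
#' @param cfg an \code{\link{sblConfig}} providing window geometry and the
#'   preprocessing filter.
#' @return list with \code{windowLabels} (factor of per-window predictions),
#'   \code{windowTruth}, \code{segments} (data.frame with true and
#'   predicted label per segment) and \code{report} (segment-level
#'   \linkS4class{EvaluationReport}).
#' @export
decodeContinuous <- function(model, stream, cfg = sblConfig()) {
  stopifnot(is(model, "SblModel"), is(stream, "EmgRecording"))
  if (!"NM" %in% model@ensemble@classes)
    stop("continuous decoding requires a model trained with the NM class")
  if (nSamples(stream) < round(cfg$windowS * samplingRate(stream)))
    stop("stream shorter than one analysis window")
  feats <- streamFeatures(stream, cfg)
  q <- modelFeatures(model, feats)
  pred <- lssvmPredictMulticlass(model@ensemble, q$X)
  wlen <- round(cfg$windowS * samplingRate(stream))
  step <- round(cfg$stepS * samplingRate(stream))
  nWin <- nrow(q$X)
  centers <- (seq_len(nWin) - 1L) * step + ceiling(wlen / 2)
  segTab <- fullSegmentTable(stream)
  segPred <- character(nrow(segTab))
  for (i in seq_len(nrow(segTab))) {
    inSeg <- centers >= segTab$start[i] & centers < segTab$end[i]
    if (!any(inSeg)) {
      segPred[i] <- "NM"
      next
    }
    tab <- table(as.character(pred[inSeg]))
    top <- names(tab)[tab == max(tab)]
    segPred[i] <- if (length(top) == 1L) top else "NM"
  }
  segTab$predicted <- segPred
  report <- buildReport(factor(segPred, levels = model@ensemble@classes),
                        factor(segTab$label, levels = model@ensemble@classes))
  list(windowLabels = pred, windowTruth = q$y,
       segments = segTab, report = report)
}

#' Compare the SBL model against standard classifiers
#'
#' Fits the requested baseline classifiers on exactly the same masked
#' training features and scores them on the same test set as the SBL model:
#' SVM (e1071), a single-hidden-layer backpropagation network (nnet),
#' k-nearest neighbours (class), random forest (randomForest) and a
#' decision tree (rpart). An empty baseline list yields the SBL row alone,
#' with a warning.
#'
#' @param model a fitted \linkS4class{SblModel}.
#' @param trainSet,testSet unmasked \linkS4class{LabeledFeatureSet}s.
#' @param baselines subset of c("svm", "bpnn", "knn", "rf", "dt").
#' @param seed RNG seed for the stochastic baselines.
#' @return data.frame with columns \code{method} and \code{accuracy}
#'   (percent), SBL first.
#' @export
compareBaselines <- function(model, trainSet, testSet,
                             baselines = c("svm", "bpnn", "knn", "rf", "dt"),
                             seed = NULL) {
  stopifnot(is(model, "SblModel"))
  if (!length(baselines)) {
    warning("no baselines requested; returning the SBL row only")
  } else {
    baselines <- match.arg(baselines, several.ok = TRUE)
  }
  tr <- modelFeatures(model, trainSet)
  te <- modelFeatures(model, testSet)
  acc <- function(pred) 100 * mean(as.character(pred) == as.character(te$y))
  out <- data.frame(method = "SBL",
                    accuracy = evaluateDiscrete(model, testSet)@overallAccuracy)
  Xtr <- tr$X
  Xte <- te$X
  ytr <- droplevels(tr$y)
  withSeed(seed, {
    for (b in baselines) {
      a <- switch(b,
        svm = {
          requireNamespace("e1071", quietly = TRUE)
          fit <- e1071::svm(Xtr, ytr)
          acc(predict(fit, Xte))
        },
        bpnn = {
          requireNamespace("nnet", quietly = TRUE)
          fit <- nnet::nnet(Xtr, nnet::class.ind(ytr), size = 10,
                            maxit = 300, decay = 1e-3, trace = FALSE)
          pr <- predict(fit, Xte)
          acc(levels(ytr)[max.col(pr)])
        },
        knn = {
          requireNamespace("class", quietly = TRUE)
          acc(class::knn(Xtr, Xte, ytr, k = min(5L, min(table(ytr)))))
        },
        rf = {
          requireNamespace("randomForest", quietly = TRUE)
          fit <- randomForest::randomForest(Xtr, ytr)
          acc(predict(fit, Xte))
        },
        dt = {
          requireNamespace("rpart", quietly = TRUE)
          df <- data.frame(y = ytr, Xtr)
          fit <- rpart::rpart(y ~ ., data = df, method = "class",
                              control = rpart::rpart.control(
                                minsplit = 4L, cp = 1e-3))
          acc(predict(fit, data.frame(Xte), type = "class"))
        })
      out <- rbind(out, data.frame(method = b, accuracy = a))
    }
  })
  rownames(out) <- NULL
  out
}
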
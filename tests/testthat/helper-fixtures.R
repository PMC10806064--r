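# Shared in-code fixtures: small Gaussian-blob and planted-signal feature
# sets, built deterministically from a seed.

# nPerClass samples per class around the rows of `centers` (classes x D).
blobFeatureSet <- function(centers, nPerClass = 10, sd = 0.3, seed = 1,
                           labels = NULL) {
  set.seed(seed)
  C <- nrow(centers)
  D <- ncol(centers)
  labels <- labels %||% paste0("C", seq_len(C))
  X <- do.call(rbind, lapply(seq_len(C), function(i)
    matrix(rnorm(nPerClass * D, mean = rep(centers[i, ], each = nPerClass),
                 sd = sd), ncol = D)))
  colnames(X) <- paste0("f", seq_len(D))
  emgSBL:::newFeatureSet(X, rep(labels, each = nPerClass))
}

# D dims of unit noise; the first `informative` dims get class-dependent
# mean offsets of size `sep`.
plantedFeatureSet <- function(nPerClass = 15, nClasses = 3, D = 13,
                              informative = 3, sep = 3, seed = 1) {
  set.seed(seed)
  n <- nPerClass * nClasses
  X <- matrix(rnorm(n * D), ncol = D)
  y <- rep(paste0("C", seq_len(nClasses)), each = nPerClass)
  for (j in seq_len(informative)) {
    offs <- sep * seq_len(nClasses)
    X[, j] <- X[, j] + offs[rep(seq_len(nClasses), each = nPerClass)]
  }
  colnames(X) <- paste0("f", seq_len(D))
  emgSBL:::newFeatureSet(X, y)
}

# Exhaustive best Fisher dispersion over all cardinality-d masks.
exhaustiveBestMask <- function(set, d) {
  D <- ncol(featureValues(set))
  combos <- utils::combn(D, d, simplify = FALSE)
  best <- -Inf
  bestMask <- NULL
  for (cb in combos) {
    bits <- rep(FALSE, D)
    bits[cb] <- TRUE
    J <- fisherDispersion(set, featureMask(bits))
    if (J > best) {
      best <- J
      bestMask <- bits
    }
  }
  list(score = best, bits = bestMask)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
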
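#' RBF kernel
#'
#' \eqn{K(x, z) = \exp(-\|x - z\|^2 / sig2)}; symmetric, values in (0, 1].
#'
#' @param x,z numeric vectors of equal length.
#' @param sig2 squared-bandwidth parameter (> 0).
#' @return kernel value.
#' @examples
#' rbfKernel(1:3, 1:3, 2)   # 1
#' @export
rbfKernel <- function(x, z, sig2) {
  if (sig2 <= 0) stop("sig2 must be > 0")
  if (length(x) != length(z)) stop("x and z must have equal dimensionality")
  exp(-sum((x - z)^2) / sig2)
}

# Full RBF Gram matrix between rows of A and rows of B.
rbfGram <- function(A, B, sig2) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  D2 <- outer(an, bn, `+`) - 2 * tcrossprod(A, B)
  exp(-pmax(D2, 0) / sig2)
}

#' Train a binary LSSVM classifier
#'
#' Solves the least squares SVM classifier dual
#' \deqn{\begin{bmatrix} 0 & y^\top \\ y & \Omega + I/\gamma \end{bmatrix}
#'   \begin{bmatrix} b \\ \alpha \end{bmatrix} =
#'   \begin{bmatrix} 0 \\ 1 \end{bmatrix}}
#' with \eqn{\Omega_{kl} = y_k y_l K(x_k, x_l)} in closed form by block
#' elimination on the symmetric positive-definite matrix
#' \eqn{H = \Omega + I/\gamma}. When H is numerically singular (reciprocal
#' condition below 1e-12) a pseudo-inverse fallback is used with a warning.
#'
#' @param X training inputs, samples x dims.
#' @param y labels in -1/+1 (or a two-level factor; the first level maps
#'   to +1).
#' @param gam regularization parameter (> 0).
#' @param sig2 RBF parameter (> 0).
#' @param classPair optional character pair naming the (+1, -1) classes.
#' @return a \linkS4class{TrainedLssvm}; its \code{residual} slot holds the
#'   relative residual of the defining system (<= 1e-8 for healthy solves).
#' @export
lssvmTrain <- function(X, y, gam, sig2, classPair = NULL) {
  X <- as.matrix(X)
  if (is.factor(y) || is.character(y)) {
    y <- factor(y)
    if (nlevels(y) != 2L) stop("binary training needs exactly two classes")
    classPair <- classPair %||% levels(y)
    y <- ifelse(y == levels(y)[1L], 1, -1)
  }
  if (!all(y %in% c(-1, 1))) stop("y must be coded -1/+1")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  n <- nrow(X)
  if (n < 2L) stop("need at least two training samples")
  if (gam <= 0 || sig2 <= 0) stop("gam and sig2 must be > 0")
  classPair <- classPair %||% c("+1", "-1")
  K <- rbfGram(X, X, sig2)
  H <- (y %o% y) * K + diag(1 / gam, n)
  solveH <- function(Bmat) {
    rc <- rcond(H)
    if (is.finite(rc) && rc > 1e-12) {
      solve(H, Bmat)
    } else {
      warning("ill-conditioned LSSVM system (rcond ", format(rc),
              "); using pseudo-inverse")
      MASS::ginv(H) %*% Bmat
    }
  }
  sol <- solveH(cbind(y, rep(1, n)))
  eta <- sol[, 1]  # H^{-1} y
  nu <- sol[, 2]   # H^{-1} 1
  s <- sum(y * eta)
  if (!is.finite(s) || abs(s) < .Machine$double.eps)
    stop("singular LSSVM system: y' H^{-1} y = ", format(s))
  b <- sum(y * nu) / s
  alpha <- nu - b * eta
  # relative residual of the full (n+1) system
  r1 <- sum(y * alpha)
  r2 <- y * b + H %*% alpha - 1
  res <- sqrt(r1^2 + sum(r2^2)) / sqrt(n + 1)
  new("TrainedLssvm", alpha = as.numeric(alpha), b = b, gam = gam,
      sig2 = sig2, X = X, y = as.numeric(y),
      classPair = as.character(classPair), residual = res)
}

#' LSSVM decision values and predictions
#'
#' \code{lssvmDecision} evaluates \eqn{f(x) = \sum_k \alpha_k y_k
#' K(x, x_k) + b}; \code{lssvmPredict} returns the sign as a class label,
#' with f = 0 mapped to the pair's first (+1) class.
#'
#' @param model a \linkS4class{TrainedLssvm}.
#' @param X query points, samples x dims (a vector is one point).
#' @return decision values, or class labels.
#' @export
lssvmDecision <- function(model, X) {
  stopifnot(is(model, "TrainedLssvm"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != ncol(model@X)) stop("dimension mismatch with training data")
  K <- rbfGram(as.matrix(X), model@X, model@sig2)
  as.numeric(K %*% (model@alpha * model@y) + model@b)
}

#' @rdname lssvmDecision
#' @export
lssvmPredict <- function(model, X) {
  f <- lssvmDecision(model, X)
  ifelse(f >= 0, model@classPair[1L], model@classPair[2L])
}

#' Train a one-vs-one multiclass LSSVM ensemble
#'
#' Trains one binary machine per unordered class pair (C classes give
#' C(C-1)/2 machines), all sharing (gam, sig2).
#'
#' @param X training inputs, samples x dims.
#' @param y class labels (factor or character), C >= 2 classes, every class
#'   with at least one sample.
#' @param gam,sig2 shared LSSVM hyperparameters.
#' @return a \linkS4class{MulticlassLssvm}.
#' @export
lssvmTrainMulticlass <- function(X, y, gam, sig2) {
  X <- as.matrix(X)
  y <- droplevels(factor(y))
  classes <- levels(y)
  if (length(classes) < 2L) stop("need at least two classes")
  if (any(table(y) < 1L)) stop("every class needs at least one sample")
  pairs <- utils::combn(classes, 2L, simplify = FALSE)
  machines <- lapply(pairs, function(p) {
    idx <- y %in% p
    lssvmTrain(X[idx, , drop = FALSE],
               ifelse(y[idx] == p[1L], 1, -1),
               gam, sig2, classPair = p)
  })
  new("MulticlassLssvm", machines = machines, classes = classes)
}

#' Predict with a one-vs-one ensemble
#'
#' Majority vote over the pairwise machines; ties break toward the largest
#' summed absolute decision value among the tied classes, then class order.
#' \code{lssvmScores} returns the per-class summed signed decision values
#' (the score of a class accumulates +|f| from machines voting for it),
#' used for ROC analysis.
#'
#' @param ensemble a \linkS4class{MulticlassLssvm}.
#' @param X query points, samples x dims.
#' @return factor of predicted labels, or a samples x classes score matrix.
#' @export
lssvmPredictMulticlass <- function(ensemble, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  classes <- ensemble@classes
  votes <- matrix(0L, nrow = nrow(X), ncol = length(classes),
                  dimnames = list(NULL, classes))
  mag <- matrix(0, nrow = nrow(X), ncol = length(classes),
                dimnames = list(NULL, classes))
  for (m in ensemble@machines) {
    f <- lssvmDecision(m, X)
    win <- ifelse(f >= 0, m@classPair[1L], m@classPair[2L])
    for (i in seq_along(f)) {
      votes[i, win[i]] <- votes[i, win[i]] + 1L
      mag[i, win[i]] <- mag[i, win[i]] + abs(f[i])
    }
  }
  pred <- character(nrow(X))
  for (i in seq_len(nrow(X))) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1L) {
      top <- top[mag[i, top] == max(mag[i, top])]
    }
    pred[i] <- classes[top[1L]]
  }
  factor(pred, levels = classes)
}

#' @rdname lssvmPredictMulticlass
#' @export
lssvmScores <- function(ensemble, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  classes <- ensemble@classes
  sc <- matrix(0, nrow = nrow(X), ncol = length(classes),
               dimnames = list(NULL, classes))
  for (m in ensemble@machines) {
    f <- lssvmDecision(m, X)
    sc[, m@classPair[1L]] <- sc[, m@classPair[1L]] + f
    sc[, m@classPair[2L]] <- sc[, m@classPair[2L]] - f
  }
  sc
}
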
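#' Create a feature mask
#'
#' @param bits logical (or 0/1) vector over the feature dimensions.
#' @return a \linkS4class{FeatureMask}.
#' @export
featureMask <- function(bits) new("FeatureMask", bits = as.logical(bits))

#' Multi-class Fisher dispersion of a masked feature subset
#'
#' The separability criterion
#' \deqn{J_d = \sum_i P_i \left[ \frac{1}{n_i} \sum_k \|x_k^{(i)} - m_i\|^2
#'   + \|m_i - m\|^2 \right]}
#' computed on the masked dimensions, where \eqn{m_i} is the class-i mean
#' vector, \eqn{m = \sum_i P_i m_i} the prior-weighted overall mean and
#' \eqn{P_i} the class priors (empirical frequencies by default). Larger
#' values indicate better separability. With a single class only the
#' within-class term remains (with a warning).
#'
#' @param set a \linkS4class{LabeledFeatureSet}.
#' @param mask a \linkS4class{FeatureMask} over the columns of the set, or
#'   NULL for all dimensions.
#' @return the non-negative dispersion score.
#' @examples
#' X <- matrix(c(0, 2, 4, 6), ncol = 1)
#' s <- emgSBL:::newFeatureSet(X, c("a", "a", "b", "b"))
#' fisherDispersion(s)   # 5
#' @export
fisherDispersion <- function(set, mask = NULL) {
  stopifnot(is(set, "LabeledFeatureSet"))
  X <- set@X
  if (!is.null(mask)) {
    stopifnot(is(mask, "FeatureMask"), length(mask@bits) == ncol(X))
    X <- X[, mask@bits, drop = FALSE]
  }
  y <- set@y
  if (any(table(y) < 1L)) stop("every class needs at least one sample")
  if (nlevels(y) < 2L)
    warning("single class: only the within-class term is meaningful")
  P <- set@priors[levels(y)]
  classMeans <- lapply(levels(y), function(l)
    colMeans(X[y == l, , drop = FALSE]))
  m <- Reduce(`+`, Map(`*`, classMeans, P))
  J <- 0
  for (i in seq_along(levels(y))) {
    Xi <- X[y == levels(y)[i], , drop = FALSE]
    within <- mean(rowSums((Xi - rep(classMeans[[i]],
                                     each = nrow(Xi)))^2))
    between <- sum((classMeans[[i]] - m)^2)
    J <- J + P[i] * (within + between)
  }
  unname(J)
}

#' Genetic-algorithm configuration for feature selection
#'
#' @param populationSize GA population size (default 50).
#' @param generations number of generations (default 100).
#' @param crossoverRate probability of uniform crossover per pair.
#' @param mutationRate per-bit flip probability; NA means 1/D.
#' @param elitism number of elite individuals carried over (default 1).
#' @param seed RNG seed.
#' @return a validated list of class \code{"GaConfig"}.
#' @export
gaConfig <- function(populationSize = 50L, generations = 100L,
                     crossoverRate = 0.9, mutationRate = NA,
                     elitism = 1L, seed = NULL) {
  stopifnot(populationSize >= 2, generations >= 1,
            crossoverRate >= 0, crossoverRate <= 1,
            is.na(mutationRate) || (mutationRate >= 0 && mutationRate <= 1),
            elitism >= 0)
  structure(list(populationSize = as.integer(populationSize),
                 generations = as.integer(generations),
                 crossoverRate = crossoverRate,
                 mutationRate = mutationRate,
                 elitism = as.integer(elitism), seed = seed),
            class = "GaConfig")
}

# Repair a bit vector to exactly d ones by flipping random surplus/deficit
# positions.
repairCardinality <- function(bits, d) {
  k <- sum(bits)
  if (k > d) {
    on <- which(bits)
    bits[sample(on, k - d)] <- FALSE
  } else if (k < d) {
    off <- which(!bits)
    bits[sample(off, d - k)] <- TRUE
  }
  bits
}

# TRUE when mask a is lexicographically smaller than b (earlier selected
# dimension wins); used to break exact fitness ties reproducibly.
lexSmaller <- function(a, b) {
  d <- which(a != b)
  if (!length(d)) return(FALSE)
  !a[d[1L]]
}

#' Select a d-dimensional feature subset with a genetic algorithm
#'
#' Maximizes the Fisher dispersion \code{\link{fisherDispersion}} over
#' binary masks of fixed cardinality d using a GA with binary-tournament
#' selection, uniform crossover, per-bit mutation (rate 1/D by default),
#' cardinality repair and elitism. Exact fitness ties break toward the
#' lexicographically smallest mask; runs are deterministic under a fixed
#' seed.
#'
#' @param set a \linkS4class{LabeledFeatureSet}.
#' @param d target subset size, 1 <= d <= D.
#' @param cfg a \code{\link{gaConfig}}.
#' @return list with \code{mask} (a \linkS4class{FeatureMask}),
#'   \code{score} (its dispersion) and \code{curve} (per-generation best
#'   score, non-decreasing under elitism).
#' @export
gaSelect <- function(set, d, cfg = gaConfig()) {
  stopifnot(is(set, "LabeledFeatureSet"))
  D <- ncol(set@X)
  if (!(d >= 1 && d <= D)) stop("require 1 <= d <= D")
  pmut <- if (is.na(cfg$mutationRate)) 1 / D else cfg$mutationRate
  score <- function(bits) fisherDispersion(set, featureMask(bits))
  withSeed(cfg$seed, {
    pop <- replicate(cfg$populationSize,
                     repairCardinality(rep(FALSE, D), d),
                     simplify = FALSE)
    fit <- vapply(pop, score, numeric(1))
    bestIdx <- which.max(fit)
    best <- pop[[bestIdx]]
    bestFit <- fit[bestIdx]
    curve <- numeric(cfg$generations)
    for (g in seq_len(cfg$generations)) {
      tournament <- function() {
        ij <- sample.int(cfg$populationSize, 2L)
        if (fit[ij[1]] >= fit[ij[2]]) pop[[ij[1]]] else pop[[ij[2]]]
      }
      newPop <- vector("list", cfg$populationSize)
      k <- 0L
      if (cfg$elitism > 0L) {
        ord <- order(fit, decreasing = TRUE)
        for (e in seq_len(min(cfg$elitism, cfg$populationSize))) {
          k <- k + 1L
          newPop[[k]] <- pop[[ord[e]]]
        }
      }
      while (k < cfg$populationSize) {
        p1 <- tournament()
        p2 <- tournament()
        if (stats::runif(1) < cfg$crossoverRate) {
          swap <- stats::runif(D) < 0.5
          c1 <- ifelse(swap, p2, p1)
          c2 <- ifelse(swap, p1, p2)
        } else {
          c1 <- p1
          c2 <- p2
        }
        for (child in list(c1, c2)) {
          if (k >= cfg$populationSize) break
          flip <- stats::runif(D) < pmut
          child <- xor(child, flip)
          child <- repairCardinality(child, d)
          k <- k + 1L
          newPop[[k]] <- child
        }
      }
      pop <- newPop
      fit <- vapply(pop, score, numeric(1))
      gi <- which.max(fit)
      if (fit[gi] > bestFit ||
          (fit[gi] == bestFit && lexSmaller(pop[[gi]], best))) {
        best <- pop[[gi]]
        bestFit <- fit[gi]
      }
      curve[g] <- bestFit
    }
    list(mask = featureMask(best), score = bestFit, curve = curve)
  })
}

#' Sweep the selection dimension
#'
#' Runs the subset search for each dimension in \code{dGrid} and tabulates
#' the best dispersion per dimension, the tool for choosing the operating
#' dimensionality (e.g. 48 of 96). \code{method = "greedy"} uses nested
#' forward selection (masks grow by one dimension at a time), whose best
#' score is monotone non-decreasing in d; \code{method = "ga"} runs an
#' independent GA per dimension.
#'
#' @param set a \linkS4class{LabeledFeatureSet}.
#' @param dGrid integer vector of dimensions within [1, D].
#' @param cfg a \code{\link{gaConfig}} (GA method only).
#' @param method "ga" or "greedy".
#' @return data.frame with columns \code{d}, \code{score} and a list column
#'   \code{mask}.
#' @export
dimensionSweep <- function(set, dGrid, cfg = gaConfig(),
                           method = c("ga", "greedy")) {
  method <- match.arg(method)
  D <- ncol(set@X)
  stopifnot(length(dGrid) >= 1, all(dGrid >= 1), all(dGrid <= D))
  if (method == "greedy") {
    sel <- logical(D)
    scores <- numeric(max(dGrid))
    masks <- vector("list", max(dGrid))
    for (k in seq_len(max(dGrid))) {
      cand <- which(!sel)
      sc <- vapply(cand, function(j) {
        b <- sel
        b[j] <- TRUE
        fisherDispersion(set, featureMask(b))
      }, numeric(1))
      sel[cand[which.max(sc)]] <- TRUE
      scores[k] <- max(sc)
      masks[[k]] <- featureMask(sel)
    }
    out <- data.frame(d = dGrid, score = scores[dGrid])
    out$mask <- masks[dGrid]
    return(out)
  }
  seeds <- subSeeds(cfg$seed, length(dGrid))
  rows <- lapply(seq_along(dGrid), function(i) {
    cfgI <- cfg
    cfgI$seed <- seeds[i]
    r <- gaSelect(set, dGrid[i], cfgI)
    list(d = dGrid[i], score = r$score, mask = r$mask)
  })
  out <- data.frame(d = vapply(rows, `[[`, numeric(1), "d"),
                    score = vapply(rows, `[[`, numeric(1), "score"))
  out$mask <- lapply(rows, `[[`, "mask")
  out
}
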
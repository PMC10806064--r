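#' Box search space for the optimizer
#'
#' @param lower,upper numeric vectors of per-dimension bounds,
#'   lower <= upper in every dimension (equal bounds collapse that
#'   dimension to a point).
#' @return a validated list of class \code{"SearchSpace"}.
#' @export
searchSpace <- function(lower, upper) {
  stopifnot(length(lower) == length(upper), all(lower <= upper))
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper),
                 dim = length(lower)),
            class = "SearchSpace")
}

#' Black widow optimizer configuration
#'
#' Population metaheuristic settings: population size, iteration budget,
#' procreating rate PP (fraction of the population that breeds), cannibalism
#' rate CR (fraction of each family discarded), mutation rate PM, the
#' movement-branch and pheromone thresholds (both 0.3), the linear-movement
#' multiplier range m in [0.4, 0.9], the spiral-movement parameter range
#' beta in [-1, 1], the sine-map parameter a in (0, 1], and the epsilon
#' guard of the pheromone formula.
#'
#' @param popSize population size (default 20, >= 2).
#' @param maxIter iterations (default 100).
#' @param PP procreating rate (default 0.8).
#' @param CR cannibalism rate (default 0.5).
#' @param PM mutation rate (default 0.4).
#' @param branchProb probability threshold of the linear movement branch
#'   (default 0.3).
#' @param pheromoneThreshold replacement threshold (default 0.3).
#' @param mRange range of the linear multiplier m (default c(0.4, 0.9)).
#' @param betaRange range of beta (default c(-1, 1)).
#' @param a sine chaotic map parameter in (0, 1] (default 1).
#' @param eps small constant guarding the pheromone denominator
#'   (default 1e-8).
#' @param seed RNG seed.
#' @return a validated list of class \code{"BwoaConfig"}.
#' @export
bwoaConfig <- function(popSize = 20L, maxIter = 100L, PP = 0.8, CR = 0.5,
                       PM = 0.4, branchProb = 0.3, pheromoneThreshold = 0.3,
                       mRange = c(0.4, 0.9), betaRange = c(-1, 1), a = 1,
                       eps = 1e-8, seed = NULL) {
  stopifnot(popSize >= 2, maxIter >= 1,
            PP >= 0, PP <= 1, CR >= 0, CR <= 1, PM >= 0, PM <= 1,
            branchProb >= 0, branchProb <= 1, eps > 0,
            length(mRange) == 2L, length(betaRange) == 2L)
  if (!(a > 0 && a <= 1))
    stop("sine map parameter a must lie in (0, 1]")
  structure(list(popSize = as.integer(popSize), maxIter = as.integer(maxIter),
                 PP = PP, CR = CR, PM = PM, branchProb = branchProb,
                 pheromoneThreshold = pheromoneThreshold, mRange = mRange,
                 betaRange = betaRange, a = a, eps = eps, seed = seed),
            class = "BwoaConfig")
}

#' Sine-chaotic population initialization
#'
#' Iterates the sine chaotic map \eqn{x_{k+1} = a \sin(\pi x_k)} per
#' dimension from a seeded start in (0, 1) and maps the chaotic values
#' affinely onto the box bounds (0 maps to the lower bound, 1 to the
#' upper). Orbits hitting the absorbing point 0 are reseeded from the RNG
#' to preserve coverage.
#'
#' @param space a \code{\link{searchSpace}}.
#' @param popSize number of positions (>= 2).
#' @param a map parameter in (0, 1].
#' @param seed RNG seed.
#' @return popSize x dim matrix of in-bounds positions.
#' @export
sineChaoticInit <- function(space, popSize, a = 1, seed = NULL) {
  stopifnot(inherits(space, "SearchSpace"), popSize >= 2)
  if (!(a > 0 && a <= 1)) stop("sine map parameter a must lie in (0, 1]")
  withSeed(seed, {
    P <- matrix(0, nrow = popSize, ncol = space$dim)
    for (j in seq_len(space$dim)) {
      x <- stats::runif(1)
      for (i in seq_len(popSize)) {
        x <- sineMapStep(x, a)
        if (x < 1e-12) x <- stats::runif(1)  # escape the absorbing point
        P[i, j] <- space$lower[j] + x * (space$upper[j] - space$lower[j])
      }
    }
    P
  })
}

#' @rdname sineChaoticInit
#' @param x current chaotic value.
#' @export
sineMapStep <- function(x, a = 1) a * sin(pi * x)

#' One movement-stage position update
#'
#' The hunting movement: with probability \code{branchProb} the linear form
#' \eqn{x^* - m x_{r1}} (m uniform in [0.4, 0.9], r1 a random index other
#' than i), otherwise the spiral form \eqn{x^* - \cos(2\pi\beta) x_i}
#' (beta uniform in [-1, 1]). The candidate is clamped to the bounds.
#' The random draws can be forced for testing.
#'
#' @param i index of the moving individual.
#' @param positions popSize x dim matrix.
#' @param best current best position \eqn{x^*}.
#' @param space a \code{\link{searchSpace}}.
#' @param cfg a \code{\link{bwoaConfig}}.
#' @param rand,m,beta,r1 optional forced values of the random draws.
#' @return candidate position (clamped).
#' @export
movementUpdate <- function(i, positions, best, space, cfg = bwoaConfig(),
                           rand = NULL, m = NULL, beta = NULL, r1 = NULL) {
  npop <- nrow(positions)
  stopifnot(npop >= 2)
  rand <- rand %||% stats::runif(1)
  if (rand <= cfg$branchProb) {
    m <- m %||% stats::runif(1, cfg$mRange[1], cfg$mRange[2])
    r1 <- r1 %||% sample(setdiff(seq_len(npop), i), 1L)
    cand <- best - m * positions[r1, ]
  } else {
    beta <- beta %||% stats::runif(1, cfg$betaRange[1], cfg$betaRange[2])
    cand <- best - cos(2 * pi * beta) * positions[i, ]
  }
  clampToBounds(cand, space$lower, space$upper)
}

#' Pheromone deposition rates
#'
#' For a minimization population, maps fitness values onto [0, 1] via
#' \deqn{pheromone_i = \frac{fitness_{max} - fitness_i}
#'   {fitness_{max} - fitness_{min}}}
#' where \eqn{fitness_{max}} is the worst and \eqn{fitness_{min}} the best
#' value: the best individual gets exactly 1 and the worst exactly 0.
#' When the spread falls below \code{eps} (uniform population) all
#' pheromones are 0 by convention, avoiding a zero division.
#'
#' @param fitnesses numeric vector (length >= 2), lower is better.
#' @param eps guard constant (default 1e-8).
#' @return pheromone vector in [0, 1].
#' @examples
#' pheromoneRates(c(0.2, 0.5, 0.8))   # 1.0 0.5 0.0
#' @export
pheromoneRates <- function(fitnesses, eps = 1e-8) {
  stopifnot(length(fitnesses) >= 2)
  fmax <- max(fitnesses)
  fmin <- min(fitnesses)
  if (fmax - fmin < eps) return(rep(0, length(fitnesses)))
  (fmax - fitnesses) / (fmax - fmin)
}

#' Pheromone-triggered replacement position
#'
#' Replaces a low-pheromone (abandoned) individual by
#' \eqn{x^* + \tfrac{1}{2}[x_{r1} - (-1)^\sigma x_{r2}]} with distinct
#' random indices r1, r2 and a random binary sigma, clamped to bounds.
#' With fewer than three individuals the movement update is used instead,
#' with a warning.
#'
#' @param i index of the replaced individual.
#' @param positions popSize x dim matrix.
#' @param best current best position.
#' @param space a \code{\link{searchSpace}}.
#' @param cfg a \code{\link{bwoaConfig}}.
#' @param r1,r2,sigma optional forced draws.
#' @return replacement position (clamped).
#' @export
pheromoneReplace <- function(i, positions, best, space, cfg = bwoaConfig(),
                             r1 = NULL, r2 = NULL, sigma = NULL) {
  npop <- nrow(positions)
  if (npop < 3L) {
    warning("population too small for pheromone replacement; ",
            "falling back to a movement update")
    return(movementUpdate(i, positions, best, space, cfg))
  }
  if (is.null(r1) || is.null(r2)) {
    rr <- sample.int(npop, 2L)
    r1 <- r1 %||% rr[1L]
    r2 <- r2 %||% rr[2L]
  }
  sigma <- sigma %||% sample(0:1, 1L)
  cand <- best + 0.5 * (positions[r1, ] - (-1)^sigma * positions[r2, ])
  clampToBounds(cand, space$lower, space$upper)
}

#' Procreation building blocks
#'
#' \code{bwoaOffspring} produces the complementary offspring pair
#' \eqn{y_1 = \alpha \circ x_1 + (1-\alpha) \circ x_2} and
#' \eqn{y_2 = (1-\alpha) \circ x_1 + \alpha \circ x_2} from two parents
#' with a per-dimension mixing vector alpha. \code{bwoaMutateSwap} swaps
#' two coordinates of a position (a no-op in one dimension or when the
#' coordinates are equal).
#'
#' @param x1,x2 parent positions.
#' @param alpha per-dimension mixing weights in [0, 1].
#' @return list of the two offspring positions.
#' @export
bwoaOffspring <- function(x1, x2, alpha) {
  stopifnot(length(x1) == length(x2), length(alpha) == length(x1))
  list(alpha * x1 + (1 - alpha) * x2,
       (1 - alpha) * x1 + alpha * x2)
}

#' @rdname bwoaOffspring
#' @param x a position.
#' @param idx the two coordinate indices to swap (random by default).
#' @export
bwoaMutateSwap <- function(x, idx = NULL) {
  if (length(x) < 2L) return(x)
  idx <- idx %||% sample.int(length(x), 2L)
  x[rev(idx)] <- x[idx]
  x
}

# Evaluate the objective, mapping non-finite values to a worst-rank
# sentinel (with a warning).
safeObjective <- function(objective, x) {
  v <- tryCatch(objective(x), error = function(e) NaN)
  if (!is.finite(v)) {
    warning("objective returned a non-finite value; assigned worst rank")
    return(Inf)
  }
  v
}

#' Procreation, cannibalism and mutation stage
#'
#' The top PP fraction of the population (by fitness) pair up; each pair
#' produces a complementary offspring pair. Within each family (parents +
#' offspring) the worst CR fraction is cannibalized (at least the single
#' best survives). A PM fraction of the retained individuals then has two
#' random coordinates swapped. Survivors are pooled with the current
#' population and the best \code{popSize} individuals survive (elitist
#' population update).
#'
#' @param positions popSize x dim matrix.
#' @param fitnesses current fitness vector (lower is better).
#' @param objective the objective function.
#' @param space a \code{\link{searchSpace}}.
#' @param cfg a \code{\link{bwoaConfig}}.
#' @return list with updated \code{positions} and \code{fitnesses}.
#' @export
procreateCannibalizeMutate <- function(positions, fitnesses, objective,
                                       space, cfg = bwoaConfig()) {
  npop <- nrow(positions)
  nParents <- floor(cfg$PP * npop)
  if (nParents < 2L) {
    warning("PP too small for reproduction; stage skipped")
    return(list(positions = positions, fitnesses = fitnesses))
  }
  ord <- order(fitnesses)
  parents <- ord[seq_len(nParents)]
  keepPos <- list()
  keepFit <- numeric()
  for (p in seq_len(nParents %/% 2L)) {
    i1 <- parents[2L * p - 1L]
    i2 <- parents[2L * p]
    alpha <- stats::runif(space$dim)
    off <- bwoaOffspring(positions[i1, ], positions[i2, ], alpha)
    fam <- rbind(positions[i1, ], positions[i2, ],
                 clampToBounds(off[[1]], space$lower, space$upper),
                 clampToBounds(off[[2]], space$lower, space$upper))
    famFit <- c(fitnesses[i1], fitnesses[i2],
                safeObjective(objective, fam[3, ]),
                safeObjective(objective, fam[4, ]))
    nKeep <- max(1L, round((1 - cfg$CR) * nrow(fam)))
    sel <- order(famFit)[seq_len(nKeep)]
    keepPos <- c(keepPos, lapply(sel, function(k) fam[k, ]))
    keepFit <- c(keepFit, famFit[sel])
  }
  # mutation: a PM fraction of the retained individuals get a coordinate swap
  nMut <- round(cfg$PM * length(keepPos))
  if (nMut > 0L && space$dim >= 2L) {
    mi <- sample.int(length(keepPos), nMut)
    for (k in mi) {
      keepPos[[k]] <- clampToBounds(bwoaMutateSwap(keepPos[[k]]),
                                    space$lower, space$upper)
      keepFit[k] <- safeObjective(objective, keepPos[[k]])
    }
  }
  pool <- rbind(positions, do.call(rbind, keepPos))
  poolFit <- c(fitnesses, keepFit)
  sel <- order(poolFit)[seq_len(npop)]
  list(positions = pool[sel, , drop = FALSE], fitnesses = poolFit[sel])
}

#' Run the sine-chaotic black widow optimizer
#'
#' Minimizes \code{objective} over a box: sine-chaotic initialization, then
#' per iteration a movement stage (candidates accepted when fitter), a
#' pheromone stage (individuals with pheromone <= 0.3 are replaced), and
#' the procreation/cannibalism/mutation stage with elitist population
#' update. The best-so-far history is monotone non-increasing and the whole
#' run is deterministic under a fixed seed.
#'
#' @param objective function of a position vector returning a scalar;
#'   non-finite values are assigned worst rank with a warning.
#' @param space a \code{\link{searchSpace}}.
#' @param cfg a \code{\link{bwoaConfig}}.
#' @return list with \code{par} (best position), \code{value} (best
#'   fitness) and \code{history} (per-iteration best fitness, length
#'   \code{cfg$maxIter}).
#' @examples
#' sp <- searchSpace(c(-5, -5), c(5, 5))
#' res <- bwoaOptimize(function(x) sum(x^2), sp,
#'                     bwoaConfig(popSize = 10, maxIter = 20, seed = 1))
#' res$value
#' @export
bwoaOptimize <- function(objective, space, cfg = bwoaConfig()) {
  stopifnot(inherits(space, "SearchSpace"), inherits(cfg, "BwoaConfig"))
  withSeed(cfg$seed, {
    P <- sineChaoticInit(space, cfg$popSize, cfg$a, seed = NULL)
    fit <- apply(P, 1L, function(x) safeObjective(objective, x))
    bestI <- which.min(fit)
    best <- P[bestI, ]
    bestFit <- fit[bestI]
    history <- numeric(cfg$maxIter)
    for (t in seq_len(cfg$maxIter)) {
      # movement stage: greedy acceptance keeps the walk productive
      for (i in seq_len(cfg$popSize)) {
        cand <- movementUpdate(i, P, best, space, cfg)
        cf <- safeObjective(objective, cand)
        if (cf < fit[i]) {
          P[i, ] <- cand
          fit[i] <- cf
        }
      }
      # pheromone stage: replace abandoned individuals (never the leader)
      ph <- pheromoneRates(fit, cfg$eps)
      leader <- which.min(fit)
      for (i in seq_len(cfg$popSize)) {
        if (i != leader && ph[i] <= cfg$pheromoneThreshold) {
          P[i, ] <- pheromoneReplace(i, P, best, space, cfg)
          fit[i] <- safeObjective(objective, P[i, ])
        }
      }
      # procreation / cannibalism / mutation with elitist update
      st <- procreateCannibalizeMutate(P, fit, objective, space, cfg)
      P <- st$positions
      fit <- st$fitnesses
      if (min(fit) < bestFit) {
        bestFit <- min(fit)
        best <- P[which.min(fit), ]
      }
      history[t] <- bestFit
    }
    list(par = best, value = bestFit, history = history)
  })
}
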
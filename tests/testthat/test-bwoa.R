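sphere <- function(x) sum(x^2)
rastrigin <- function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x))

test_that("the sine chaotic map and its initialization behave as specified", {
  expect_equal(sineMapStep(0.5, 1), 1)
  expect_equal(sineMapStep(0.5, 0.7), 0.7)

  sp <- searchSpace(c(-2, 10), c(2, 20))
  P <- sineChaoticInit(sp, 30, seed = 1)
  expect_equal(dim(P), c(30L, 2L))
  expect_true(all(P[, 1] >= -2 & P[, 1] <= 2))
  expect_true(all(P[, 2] >= 10 & P[, 2] <= 20))
  expect_identical(P, sineChaoticInit(sp, 30, seed = 1))

  # coverage: 50 draws on the unit interval occupy >= 8 of 10 bins
  u <- sineChaoticInit(searchSpace(0, 1), 50, seed = 3)[, 1]
  expect_gte(length(unique(cut(u, seq(0, 1, 0.1)))), 8L)
  # and beat a degenerate constant init
  expect_gt(stats::sd(u), 0)

  expect_error(sineChaoticInit(sp, 10, a = 1.5), "a must")
  expect_error(bwoaConfig(a = 0), "a must")
})

test_that("movement updates follow the linear and spiral forms", {
  sp <- searchSpace(c(-100, -100), c(100, 100))
  P <- rbind(c(1, 2), c(3, 4), c(5, 6))
  best <- c(10, 10)
  # spiral branch, beta = 0: cos(0) = 1 -> x* - x_i
  expect_equal(movementUpdate(1, P, best, sp, rand = 0.9, beta = 0),
               best - P[1, ])
  # beta = 0.25 -> cos(pi/2) = 0 -> exactly x*
  expect_equal(movementUpdate(2, P, best, sp, rand = 0.5, beta = 0.25),
               best)
  expect_equal(movementUpdate(2, P, best, sp, rand = 0.5, beta = -0.25),
               best)
  # linear branch with forced m and r1
  expect_equal(movementUpdate(1, P, best, sp, rand = 0.1, m = 0.4, r1 = 3),
               best - 0.4 * P[3, ])
  # clamping
  tight <- searchSpace(c(0, 0), c(1, 1))
  out <- movementUpdate(1, P, best, tight, rand = 0.1, m = 0.4, r1 = 3)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("pheromone rates normalize any population onto [0, 1]", {
  expect_equal(pheromoneRates(c(0.2, 0.5, 0.8)), c(1, 0.5, 0))
  expect_equal(pheromoneRates(rep(3, 5)), rep(0, 5))  # epsilon guard
  set.seed(17)
  for (i in 1:5) {
    f <- rnorm(10)
    ph <- pheromoneRates(f)
    expect_true(all(ph >= 0 & ph <= 1))
    expect_equal(ph[which.min(f)], 1)   # best individual
    expect_equal(ph[which.max(f)], 0)   # worst individual
  }
})

test_that("pheromone replacement substitutes the documented forms", {
  sp <- searchSpace(c(-100, -100), c(100, 100))
  P <- rbind(c(1, 1), c(2, 4), c(6, 2))
  best <- c(0, 0)
  expect_equal(pheromoneReplace(1, P, best, sp, r1 = 2, r2 = 3, sigma = 0),
               best + 0.5 * (P[2, ] - P[3, ]))
  expect_equal(pheromoneReplace(1, P, best, sp, r1 = 2, r2 = 3, sigma = 1),
               best + 0.5 * (P[2, ] + P[3, ]))
  # r1 = r2 with sigma = 0 collapses to x*
  expect_equal(pheromoneReplace(1, P, best, sp, r1 = 2, r2 = 2, sigma = 0),
               best)
  expect_warning(
    pheromoneReplace(1, P[1:2, , drop = FALSE], best, sp),
    "too small")
})

test_that("procreation mixes parents, cannibalism prunes, mutation swaps", {
  al <- c(0.3, 0.8)
  off <- bwoaOffspring(c(1, 2), c(1, 2), al)
  expect_equal(off[[1]], c(1, 2))   # identical parents -> identical offspring
  expect_equal(off[[2]], c(1, 2))
  off2 <- bwoaOffspring(c(0, 0), c(1, 1), al)
  expect_equal(off2[[1]], 1 - al)
  expect_equal(off2[[2]], al)

  expect_equal(bwoaMutateSwap(c(5, 5), c(1, 2)), c(5, 5))  # swap no-op
  expect_equal(bwoaMutateSwap(c(1, 2, 3), c(1, 3)), c(3, 2, 1))
  expect_equal(bwoaMutateSwap(7), 7)  # 1-D no-op

  # CR = 1: only the best of each family survives cannibalism, but the
  # elitist pool still returns a full population
  sp <- searchSpace(c(-5, -5), c(5, 5))
  set.seed(18)
  P <- matrix(runif(12, -5, 5), ncol = 2)
  fit <- apply(P, 1, sphere)
  st <- procreateCannibalizeMutate(P, fit, sphere, sp,
                                   bwoaConfig(popSize = 6, CR = 1))
  expect_equal(dim(st$positions), dim(P))
  expect_lte(min(st$fitnesses), min(fit))  # elitist

  expect_warning(
    procreateCannibalizeMutate(P, fit, sphere, sp,
                               bwoaConfig(popSize = 6, PP = 0)),
    "skipped")
})

test_that("the optimizer is elitist, bounded, seeded and handles bad objectives", {
  sp <- searchSpace(c(-5.12, -5.12), c(5.12, 5.12))
  cfg <- bwoaConfig(popSize = 10, maxIter = 25, seed = 5)
  r1 <- bwoaOptimize(sphere, sp, cfg)
  r2 <- bwoaOptimize(sphere, sp, cfg)
  expect_identical(r1$history, r2$history)
  expect_true(all(diff(r1$history) <= 0))
  expect_length(r1$history, 25L)
  expect_true(all(r1$par >= sp$lower & r1$par <= sp$upper))
  expect_lt(r1$value, 0.1)

  # constant objective: flat history, any in-bounds position
  rc <- bwoaOptimize(function(x) 1, sp,
                     bwoaConfig(popSize = 6, maxIter = 5, seed = 1))
  expect_true(all(rc$history == 1))

  # non-finite objective values are demoted, not fatal
  nasty <- function(x) if (x[1] > 0) NaN else sum(x^2)
  expect_warning(
    rn <- bwoaOptimize(nasty, sp,
                       bwoaConfig(popSize = 8, maxIter = 5, seed = 2)),
    "non-finite")
  expect_true(is.finite(rn$value))
})

test_that("a modest budget already solves the classic benchmarks", {
  sp <- searchSpace(c(-5.12, -5.12), c(5.12, 5.12))
  v <- bwoaOptimize(sphere, sp,
                    bwoaConfig(popSize = 14, maxIter = 40, seed = 1))$value
  expect_lte(v, 1e-3)
  vr <- bwoaOptimize(rastrigin, sp,
                     bwoaConfig(popSize = 14, maxIter = 40, seed = 1))$value
  expect_lte(vr, 1)
})
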
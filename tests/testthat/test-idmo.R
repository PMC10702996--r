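sphere <- benchmarkObjective("sphere")

test_that("population initialization is uniform, bounded and reproducible", {
  cfg <- idmoConfig(n = 30L, seed = 4L)
  set.seed(cfg$seed)
  pop <- initPopulation(sphere, rep(0, 3), rep(1, 3), cfg)
  X <- positions(pop)
  expect_true(all(X >= 0 & X <= 1))
  expect_identical(evaluationCount(pop), 30L)
  set.seed(cfg$seed)
  pop2 <- initPopulation(sphere, rep(0, 3), rep(1, 3), cfg)
  expect_identical(positions(pop2), X)
  expect_error(initPopulation(sphere, c(0, 1), c(1, 1), cfg), "lower")
  # law of large numbers: mean of uniform draws on [0,1] near 1/2
  cfgBig <- idmoConfig(n = 2000L, seed = 9L)
  set.seed(cfgBig$seed)
  big <- initPopulation(function(x) sum(x), rep(0, 5), rep(1, 5), cfgBig)
  expect_lt(abs(mean(positions(big)) - 0.5), 0.02)
})

test_that("alpha selection is the tie-broken argmin", {
  cfg <- idmoConfig(n = 4L, seed = 1L)
  set.seed(1)
  pop <- initPopulation(sphere, rep(-1, 2), rep(1, 2), cfg)
  pop@fitness <- c(3, 1, 2, 5)
  expect_identical(selectAlpha(pop), 2L)
  pop@fitness <- c(5, 5, 5, 5)
  expect_identical(selectAlpha(pop), 1L)
  set.seed(2)
  pop@fitness <- runif(4)
  expect_identical(selectAlpha(pop), which(pop@fitness == min(pop@fitness))[1])
  pop@fitness[2] <- NaN
  expect_error(selectAlpha(pop), "NaN")
})

test_that("schedule factors take their endpoint values", {
  expect_equal(omegaFactor(0, 100), 1)
  expect_equal(omegaFactor(100, 100), exp(-4), tolerance = 1e-12)
  expect_equal(exp(-4), 0.0183, tolerance = 1e-3)
  expect_equal(babysitterCF(0, 100), 1)
  expect_equal(babysitterCF(100, 100), 0)
})

test_that("phases keep bounds, degenerate cases and monotone best fitness", {
  cfg <- idmoConfig(n = 12L, maxIter = 10L, seed = 3L)
  set.seed(cfg$seed)
  pop <- initPopulation(sphere, rep(-5, 3), rep(5, 3), cfg)
  before <- min(fitnessValues(pop))
  for (it in 1:3) {
    pop@cIter <- it
    pop <- alphaPhase(pop, cfg, sphere)
    expect_true(all(positions(pop) >= -5 & positions(pop) <= 5))
    expect_lte(min(fitnessValues(pop)), before)
    pop <- scoutPhase(pop, cfg, sphere)
    expect_lte(min(fitnessValues(pop)), before)
    before <- min(fitnessValues(pop))
  }
  # collapsed population: every candidate equals alpha, nothing changes
  popC <- pop
  popC@X <- matrix(rep(positions(pop)[alphaIndex(pop), ], each = 12), 12, 3)
  popC@fitness <- rep(fitnessValues(pop)[alphaIndex(pop)], 12)
  popC@alphaIndex <- 1L
  moved <- alphaPhase(popC, cfg, sphere)
  expect_equal(positions(moved), positions(popC), tolerance = 1e-14)
  # NaN objective names the offending position
  expect_error(alphaPhase(pop, cfg, function(x) NaN), "position")
})

test_that("babysitter exchanges follow the countdown schedule", {
  cfg <- idmoConfig(n = 9L, maxIter = 12L, timerReset = 3L, br = 0,
                    seed = 5L)
  set.seed(cfg$seed)
  pop <- initPopulation(sphere, rep(-2, 2), rep(2, 2), cfg)
  exchanges <- c()
  for (it in 1:10) {
    pop@cIter <- it
    timerBefore <- pop@babysitterTimer
    pop <- babysitterPhase(pop, cfg, sphere)
    if (pop@babysitterTimer == cfg$timerReset && timerBefore == 1L) {
      exchanges <- c(exchanges, it)
    }
  }
  expect_identical(exchanges, c(3L, 6L, 9L))
  # br = 0 keeps babysitter positions unchanged at the exchange
  set.seed(cfg$seed)
  pop <- initPopulation(sphere, rep(-2, 2), rep(2, 2), cfg)
  X0 <- positions(pop)
  for (it in 1:3) { pop@cIter <- it; pop <- babysitterPhase(pop, cfg, sphere) }
  expect_equal(positions(pop), X0, tolerance = 1e-14)
})

test_that("optimizer satisfies trace, budget, determinism and convergence", {
  cfg <- idmoConfig(n = 30L, maxIter = 100L, seed = 1L)
  r <- idmoOptimize(sphere, rep(-5, 5), rep(5, 5), cfg)
  expect_identical(nrow(r$trace), 101L)
  expect_true(all(diff(r$trace$bestFitness) <= 0))
  expect_lte(r$evaluations, 30L * (2L * 100L + 1L))
  expect_identical(r$trace$evaluations[101], r$evaluations)
  expect_lt(r$bestFitness, 1e-2)
  r2 <- idmoOptimize(sphere, rep(-5, 5), rep(5, 5), cfg)
  expect_identical(r$trace, r2$trace)
  expect_identical(r$bestX, r2$bestX)
  # constant objective: best fitness never moves from its initial value
  rc <- idmoOptimize(function(x) 7, rep(0, 2), rep(1, 2),
                     idmoConfig(n = 6L, maxIter = 5L, seed = 2L))
  expect_true(all(rc$trace$bestFitness == 7))
  expect_true(all(rc$bestX >= 0 & rc$bestX <= 1))
})

test_that("scout displacement is symmetric for a symmetric phi range", {
  # candidate - alpha over many draws has mean within 3 s.e. of 0
  set.seed(11)
  n <- 10000L
  phi <- runif(n, -1, 1)
  r <- runif(n)
  diffs <- matrix(rnorm(2 * n), n, 2)
  step <- phi * r * (diffs[, 1] - diffs[, 2]) / 2
  se <- sd(step) / sqrt(n)
  expect_lt(abs(mean(step)), 3 * se)
})

test_that("IDMO beats budget-matched random search on the Rastrigin surface", {
  rast <- benchmarkObjective("rastrigin")
  idmoBest <- rsBest <- numeric(20)
  for (s in 1:20) {
    ri <- idmoOptimize(rast, rep(-5.12, 2), rep(5.12, 2),
                       idmoConfig(n = 30L, maxIter = 200L, seed = s))
    rs <- randomSearch(rast, rep(-5.12, 2), rep(5.12, 2), ri$evaluations,
                       seed = s + 1000L)
    idmoBest[s] <- ri$bestFitness
    rsBest[s] <- rs$bestFitness
  }
  expect_lt(median(idmoBest), median(rsBest))
})
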
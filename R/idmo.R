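# Improved Dwarf Mongoose Optimization (IDMO): a population metaheuristic
# for bound-constrained continuous minimization. Each iteration runs three
# phases — alpha (foraging around the current best), scout (diversification
# from random peer differences) and babysitter (periodic exchange of the
# worst reserve individuals) — with greedy per-individual acceptance in the
# first two and full trace logging.

#' Construct an IDMO configuration
#'
#' @param n population size (>= 4; default 30).
#' @param maxIter iteration budget (default 100).
#' @param phiRange interval of the step-scale draw phi (default `[-1, 1]`).
#' @param useOmega apply the iteration-decaying damper
#'   `omega = exp(-4 (C_iter/Max_iter)^2)` in the alpha phase and the
#'   collapse factor CF in the babysitter phase (default TRUE).
#' @param babysitterCount reserve individuals (default `round(n / 3)`).
#' @param timerReset babysitter exchange countdown reset value (default 6).
#' @param br fixed birthrate in `[0, 1]`, or `NULL` (default) to draw it
#'   uniformly per update.
#' @param boundHandling `"clip"` (default) or `"resample"` for candidates
#'   leaving the box.
#' @param seed RNG seed for the whole run.
#' @return A validated list of class `idmoConfig`.
#' @export
idmoConfig <- function(n = 30L, maxIter = 100L, phiRange = c(-1, 1),
                       useOmega = TRUE, babysitterCount = NULL,
                       timerReset = 6L, br = NULL,
                       boundHandling = c("clip", "resample"), seed = 1L) {
  n <- as.integer(n)
  if (n < 4L) stop("pdfusenet: population size must be >= 4", call. = FALSE)
  if (is.null(babysitterCount)) babysitterCount <- max(1L, round(n / 3))
  babysitterCount <- as.integer(babysitterCount)
  if (babysitterCount >= n) {
    stop("pdfusenet: babysitterCount must be < n", call. = FALSE)
  }
  if (length(phiRange) != 2L || phiRange[1] > phiRange[2]) {
    stop("pdfusenet: phiRange must be an increasing interval", call. = FALSE)
  }
  if (!is.null(br) && (br < 0 || br > 1)) {
    stop("pdfusenet: br must be in [0, 1] or NULL", call. = FALSE)
  }
  structure(list(n = n, maxIter = as.integer(maxIter), phiRange = phiRange,
                 useOmega = isTRUE(useOmega), babysitterCount = babysitterCount,
                 timerReset = as.integer(timerReset), br = br,
                 boundHandling = match.arg(boundHandling),
                 seed = as.integer(seed)),
            class = "idmoConfig")
}

#' Alpha-phase step damper
#'
#' `omega = exp(-4 (cIter / maxIter)^2)`: 1 at the start of the run,
#' `exp(-4)` at the end.
#'
#' @param cIter,maxIter current iteration and iteration budget.
#' @return The damping factor.
#' @export
omegaFactor <- function(cIter, maxIter) exp(-4 * (cIter / maxIter)^2)

#' Babysitter collapse factor
#'
#' `CF = (1 - cIter/maxIter)^(2 cIter/maxIter)`: 1 at the start, 0 at the
#' final iteration.
#'
#' @inheritParams omegaFactor
#' @return The collapse factor.
#' @export
babysitterCF <- function(cIter, maxIter) {
  r <- cIter / maxIter
  (1 - r)^(2 * r)
}

evalObjective <- function(objective, x) {
  f <- objective(x)
  if (!is.numeric(f) || length(f) != 1L || is.na(f)) {
    stop("pdfusenet: objective returned NaN/NA at position (",
         paste(signif(x, 6), collapse = ", "), ")", call. = FALSE)
  }
  f
}

# sample k elements of v, safe for length-1 v (unlike sample())
pickFrom <- function(v, k) v[sample.int(length(v), k)]

applyBounds <- function(x, lower, upper, handling) {
  if (handling == "clip") return(pmin(pmax(x, lower), upper))
  out <- x
  bad <- which(x < lower | x > upper)
  if (length(bad)) {
    out[bad] <- lower[bad] + stats::runif(length(bad)) * (upper[bad] - lower[bad])
  }
  out
}

#' Initialize the mongoose population
#'
#' Positions drawn uniformly inside the box `X[i, j] = rand (U - L) + L`;
#' the objective is evaluated once per individual and the alpha (best)
#' selected.
#'
#' @param objective function of a length-d numeric vector returning a finite
#'   scalar (minimized).
#' @param lower,upper finite per-dimension bounds with `lower < upper`.
#' @param config an [idmoConfig()]. The caller (or [idmoOptimize()]) is
#'   responsible for seeding the RNG.
#' @return A [MongoosePopulation-class].
#' @export
initPopulation <- function(objective, lower, upper, config = idmoConfig()) {
  d <- length(lower)
  if (length(upper) != d) stop("pdfusenet: bound lengths differ", call. = FALSE)
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    stop("pdfusenet: bounds must be finite", call. = FALSE)
  }
  if (any(lower >= upper)) {
    stop("pdfusenet: lower must be < upper in every dimension", call. = FALSE)
  }
  n <- config$n
  X <- matrix(stats::runif(n * d), n, d)
  X <- sweep(sweep(X, 2L, upper - lower, "*"), 2L, lower, "+")
  fit <- apply(X, 1L, function(x) evalObjective(objective, x))
  new("MongoosePopulation", X = X, fitness = fit, lower = as.numeric(lower),
      upper = as.numeric(upper), alphaIndex = which.min(fit),
      cIter = 0L, maxIter = config$maxIter,
      babysitterCount = config$babysitterCount,
      babysitterTimer = config$timerReset, timerReset = config$timerReset,
      evaluations = n)
}

#' Select the alpha (best individual)
#'
#' Minimization convention: the alpha is the argmin of the fitness vector;
#' ties break to the lowest index.
#'
#' @param population a [MongoosePopulation-class].
#' @return Integer index of the alpha.
#' @export
selectAlpha <- function(population) {
  fit <- fitnessValues(population)
  if (anyNA(fit)) stop("pdfusenet: NaN/NA fitness in population", call. = FALSE)
  which.min(fit)
}

# worst-fitness babysitterCount individuals, never including the alpha
babysitterIndices <- function(population) {
  k <- population@babysitterCount
  if (k < 1L) return(integer())
  ord <- order(population@fitness, decreasing = TRUE)
  ord <- ord[ord != population@alphaIndex]
  ord[seq_len(min(k, length(ord)))]
}

#' Alpha phase: foraging led by the best individual
#'
#' Every non-babysitter a proposes
#' `candidate = alpha + omega * phi * rand * (X_a - X_u)` with
#' `phi ~ U(phiRange)` and `rand ~ U(0, 1)` drawn independently per
#' dimension and a random peer `u != a` from the whole population
#' (omega only when `useOmega`). Candidates are clipped to the box and
#' accepted greedily (kept only if the fitness improves); the alpha is
#' re-selected afterward.
#'
#' @param population a [MongoosePopulation-class].
#' @param config an [idmoConfig()].
#' @param objective the objective being minimized.
#' @return The updated population.
#' @export
alphaPhase <- function(population, config, objective) {
  bs <- babysitterIndices(population)
  forage <- setdiff(seq_len(nrow(population@X)), bs)
  if (length(forage) < 2L) {
    stop("pdfusenet: alpha phase needs >= 2 non-babysitters", call. = FALSE)
  }
  om <- if (config$useOmega) {
    omegaFactor(population@cIter, population@maxIter)
  } else 1
  all <- seq_len(nrow(population@X))
  d <- ncol(population@X)
  alphaX <- population@X[population@alphaIndex, ]
  for (a in forage) {
    u <- pickFrom(setdiff(all, a), 1L)
    phi <- stats::runif(d, config$phiRange[1], config$phiRange[2])
    r <- stats::runif(d)
    cand <- alphaX + om * phi * r * (population@X[a, ] - population@X[u, ])
    cand <- applyBounds(cand, population@lower, population@upper,
                        config$boundHandling)
    f <- evalObjective(objective, cand)
    population@evaluations <- population@evaluations + 1L
    if (f < population@fitness[a]) {
      population@X[a, ] <- cand
      population@fitness[a] <- f
    }
  }
  population@alphaIndex <- selectAlpha(population)
  population
}

#' Scout phase: diversification toward unexplored regions
#'
#' Every non-babysitter a proposes
#' `candidate = alpha + phi * rand * (X_u - X_v) / 2` with distinct random
#' peers u, v; same clip/greedy-acceptance contract as [alphaPhase()].
#'
#' @inheritParams alphaPhase
#' @return The updated population.
#' @export
scoutPhase <- function(population, config, objective) {
  bs <- babysitterIndices(population)
  forage <- setdiff(seq_len(nrow(population@X)), bs)
  if (length(forage) < 3L) {
    stop("pdfusenet: scout phase needs >= 3 non-babysitters", call. = FALSE)
  }
  all <- seq_len(nrow(population@X))
  d <- ncol(population@X)
  alphaX <- population@X[population@alphaIndex, ]
  for (a in forage) {
    uv <- pickFrom(setdiff(all, a), 2L)
    phi <- stats::runif(d, config$phiRange[1], config$phiRange[2])
    r <- stats::runif(d)
    cand <- alphaX + phi * r * (population@X[uv[1L], ] - population@X[uv[2L], ]) / 2
    cand <- applyBounds(cand, population@lower, population@upper,
                        config$boundHandling)
    f <- evalObjective(objective, cand)
    population@evaluations <- population@evaluations + 1L
    if (f < population@fitness[a]) {
      population@X[a, ] <- cand
      population@fitness[a] <- f
    }
  }
  population@alphaIndex <- selectAlpha(population)
  population
}

#' Babysitter phase: periodic exchange of the reserve
#'
#' The countdown decrements each call; when it reaches zero every babysitter
#' b (the worst-fitness third, never the alpha) is replaced by
#' `X_b + rand * (alpha - (X_u + X_v)/2) * br` (times the collapse factor CF
#' when `useOmega`), with u, v random non-babysitters and the birthrate br
#' drawn uniformly unless fixed in the config; the timer then resets.
#'
#' @inheritParams alphaPhase
#' @return The updated population.
#' @export
babysitterPhase <- function(population, config, objective) {
  if (population@babysitterCount < 1L) return(population)
  population@babysitterTimer <- population@babysitterTimer - 1L
  if (population@babysitterTimer > 0L) return(population)
  bs <- babysitterIndices(population)
  others <- setdiff(seq_len(nrow(population@X)), bs)
  cf <- if (config$useOmega) {
    babysitterCF(population@cIter, population@maxIter)
  } else 1
  alphaX <- population@X[population@alphaIndex, ]
  d <- ncol(population@X)
  for (b in bs) {
    uv <- if (length(others) >= 2L) pickFrom(others, 2L) else rep(others, 2L)
    r <- stats::runif(d)
    br <- if (is.null(config$br)) stats::runif(1) else config$br
    cand <- population@X[b, ] +
      r * (alphaX - (population@X[uv[1L], ] + population@X[uv[2L], ]) / 2) * br * cf
    cand <- applyBounds(cand, population@lower, population@upper,
                        config$boundHandling)
    f <- evalObjective(objective, cand)
    population@evaluations <- population@evaluations + 1L
    population@X[b, ] <- cand
    population@fitness[b] <- f
  }
  population@babysitterTimer <- population@timerReset
  population@alphaIndex <- selectAlpha(population)
  population
}

#' Run the IDMO optimizer
#'
#' Seeds the RNG from the config, initializes the population and runs
#' exactly `maxIter` iterations of alpha -> scout -> babysitter. The
#' best-so-far fitness is monotone non-increasing, every position stays in
#' the box, the total number of objective evaluations is at most
#' `n * (2 * maxIter + 1)`, and identical configs give identical traces.
#'
#' @param objective function of a length-d numeric vector returning a finite
#'   scalar, minimized over the box.
#' @param lower,upper finite per-dimension bounds.
#' @param config an [idmoConfig()].
#' @return List with `bestX`, `bestFitness`, `trace` (data frame
#'   `iteration, bestFitness, meanFitness, evaluations`, one row per
#'   iteration plus the initial state), `population` and `evaluations`.
#' @export
idmoOptimize <- function(objective, lower, upper, config = idmoConfig()) {
  set.seed(config$seed)
  pop <- initPopulation(objective, lower, upper, config)
  bestIdx <- alphaIndex(pop)
  bestX <- pop@X[bestIdx, ]
  bestFit <- pop@fitness[bestIdx]
  trace <- data.frame(iteration = 0L, bestFitness = bestFit,
                      meanFitness = mean(pop@fitness),
                      evaluations = pop@evaluations)
  for (iter in seq_len(config$maxIter)) {
    pop@cIter <- iter
    pop <- alphaPhase(pop, config, objective)
    pop <- scoutPhase(pop, config, objective)
    pop <- babysitterPhase(pop, config, objective)
    curIdx <- alphaIndex(pop)
    if (pop@fitness[curIdx] < bestFit) {
      bestFit <- pop@fitness[curIdx]
      bestX <- pop@X[curIdx, ]
    }
    trace <- rbind(trace, data.frame(iteration = iter, bestFitness = bestFit,
                                     meanFitness = mean(pop@fitness),
                                     evaluations = pop@evaluations))
  }
  list(bestX = bestX, bestFitness = bestFit, trace = trace, population = pop,
       evaluations = pop@evaluations)
}

#' Standard benchmark objectives
#'
#' `"sphere"`: `sum(x^2)`; `"rastrigin"`:
#' `10 d + sum(x^2 - 10 cos(2 pi x))`; `"rosenbrock"`: the banana valley.
#' All are minimized at known optima.
#'
#' @param name benchmark name.
#' @return A function of a numeric vector.
#' @export
benchmarkObjective <- function(name = c("sphere", "rastrigin", "rosenbrock")) {
  switch(match.arg(name),
    sphere = function(x) sum(x^2),
    rastrigin = function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x)),
    rosenbrock = function(x) {
      n <- length(x)
      sum(100 * (x[-1] - x[-n]^2)^2 + (1 - x[-n])^2)
    })
}

#' Budget-matched pure random search baseline
#'
#' Draws `nEval` uniform points in the box and returns the best; used as the
#' evaluation-budget-matched comparison for the optimizer.
#'
#' @param objective function to minimize.
#' @param lower,upper box bounds.
#' @param nEval number of uniform draws.
#' @param seed RNG seed.
#' @return List with `bestX` and `bestFitness`.
#' @export
randomSearch <- function(objective, lower, upper, nEval, seed = 1L) {
  withSeed(seed, {
    d <- length(lower)
    bestF <- Inf
    bestX <- NULL
    for (i in seq_len(nEval)) {
      x <- lower + stats::runif(d) * (upper - lower)
      f <- evalObjective(objective, x)
      if (f < bestF) {
        bestF <- f
        bestX <- x
      }
    }
    list(bestX = bestX, bestFitness = bestF)
  })
}
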
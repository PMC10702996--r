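#' @import methods
NULL

# ---------------------------------------------------------------- PhantomSpec

#' PhantomSpec: parameters of one synthetic brain phantom
#'
#' Describes a single synthetic 2-D brain-like slice: image size, severity
#' class, ventricular enlargement, texture and noise amplitudes, the
#' multiplicative illumination gradient, and the seed that makes the phantom
#' reproducible. Severity is encoded geometrically: the ventricle scale grows
#' and the cortical band thins from mild to severe, so the class signal
#' survives intensity-space preprocessing.
#'
#' @slot imageSize integer, square side in pixels (>= 32).
#' @slot classLabel integer in 0:2 (0 = mild, 1 = moderate, 2 = severe).
#' @slot ventricleScale positive multiplier on the ventricle semi-axes.
#' @slot corticalThickness cortical band thickness as a fraction of the brain
#'   semi-axis, in (0, 0.3].
#' @slot textureSigma sd of the smoothed intra-brain texture field.
#' @slot noiseSigma sd of the additive Gaussian pixel noise.
#' @slot illuminationGradient amplitude of the multiplicative shading in
#'   `[0, 0.6]`.
#' @slot seed integer RNG seed.
#' @seealso [phantomSpec()], [generatePhantom()]
#' @export
setClass("PhantomSpec", representation(
  imageSize = "integer",
  classLabel = "integer",
  ventricleScale = "numeric",
  corticalThickness = "numeric",
  textureSigma = "numeric",
  noiseSigma = "numeric",
  illuminationGradient = "numeric",
  seed = "integer"
))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@imageSize < 32L) msg <- c(msg, "imageSize must be >= 32")
  if (!(object@classLabel %in% 0:2)) {
    msg <- c(msg, "classLabel must be 0 (mild), 1 (moderate) or 2 (severe)")
  }
  if (object@ventricleScale <= 0) msg <- c(msg, "ventricleScale must be > 0")
  if (object@corticalThickness <= 0 || object@corticalThickness > 0.3) {
    msg <- c(msg, "corticalThickness must be in (0, 0.3]")
  }
  if (object@textureSigma < 0) msg <- c(msg, "textureSigma must be >= 0")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (object@illuminationGradient < 0 || object@illuminationGradient > 0.6) {
    msg <- c(msg, "illuminationGradient must be in [0, 0.6]")
  }
  if (length(msg)) msg else TRUE
})

# --------------------------------------------------------------- FusionConfig

#' FusionConfig: constants and choices of the fusion preprocessing stage
#'
#' Houses the brightness-transform constants, the exposure-ratio search
#' interval, the illumination-weight smoothing, the box mean-filter window,
#' the multi-scale morphological gradient (MSMG) construction and the blend
#' rule used to fuse the contrast-enhanced and the mean-filtered copies.
#'
#' @slot btfA,btfB camera-response constants of the brightness transform
#'   `g(P, k) = exp(btfB * (1 - k^btfA)) * P^(k^btfA)`.
#' @slot kRange numeric length-2, search interval for the exposure ratio k.
#' @slot underexposedThreshold weight below which a pixel counts as
#'   underexposed for the entropy search.
#' @slot weightSmoothingSigma Gaussian sigma (pixels) for the illumination
#'   weight map.
#' @slot weightExponent exponent mu of the smoothed luminance.
#' @slot meanFilterWindow odd box window (pixels) of the mean filter.
#' @slot msmgScales number of MSMG scales N.
#' @slot blendMode `"soft"` (logistic weighting of the two MSMG maps) or
#'   `"hard"` (per-pixel argmax selection).
#' @slot softSharpness logistic slope of the soft blend.
#' @slot fusePartner `"filtered"` (default) or `"original"`: the image fused
#'   against the enhanced copy.
#' @seealso [fusionConfig()], [enhance()], [msmg()], [fuseImages()]
#' @export
setClass("FusionConfig", representation(
  btfA = "numeric",
  btfB = "numeric",
  kRange = "numeric",
  underexposedThreshold = "numeric",
  weightSmoothingSigma = "numeric",
  weightExponent = "numeric",
  meanFilterWindow = "integer",
  msmgScales = "integer",
  blendMode = "character",
  softSharpness = "numeric",
  fusePartner = "character"
))

setValidity("FusionConfig", function(object) {
  msg <- character()
  if (length(object@kRange) != 2 || any(object@kRange <= 0) ||
      object@kRange[1] > object@kRange[2]) {
    msg <- c(msg, "kRange must be a positive, increasing length-2 interval")
  }
  w <- object@meanFilterWindow
  if (w < 3L || w %% 2L == 0L) msg <- c(msg, "meanFilterWindow must be odd and >= 3")
  if (object@msmgScales < 1L) msg <- c(msg, "msmgScales must be >= 1")
  if (!object@blendMode %in% c("soft", "hard")) {
    msg <- c(msg, "blendMode must be 'soft' or 'hard'")
  }
  if (!object@fusePartner %in% c("filtered", "original")) {
    msg <- c(msg, "fusePartner must be 'filtered' or 'original'")
  }
  if (object@weightSmoothingSigma <= 0) msg <- c(msg, "weightSmoothingSigma must be > 0")
  if (object@weightExponent <= 0) msg <- c(msg, "weightExponent must be > 0")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------- EnhancementResult

#' EnhancementResult: output of exposure-fusion contrast enhancement
#'
#' The enhanced image R is the per-pixel convex combination
#' `R = W * P + (1 - W) * g(P, k)` of the input P and its synthetic
#' re-exposure `g(P, k)`, weighted by the illumination weight map W. The
#' object stores every term so the combination identity can be re-checked.
#'
#' @slot enhanced the enhanced image R.
#' @slot weightMap the illumination weight map W in `[0, 1]`.
#' @slot exposureRatio the selected exposure ratio k.
#' @slot syntheticExposure the synthetic exposure `g(P, k)`.
#' @slot input the input image P.
#' @seealso [enhance()]
#' @export
setClass("EnhancementResult", representation(
  enhanced = "matrix",
  weightMap = "matrix",
  exposureRatio = "numeric",
  syntheticExposure = "matrix",
  input = "matrix"
))

setValidity("EnhancementResult", function(object) {
  msg <- character()
  dims <- dim(object@enhanced)
  if (!identical(dim(object@weightMap), dims) ||
      !identical(dim(object@syntheticExposure), dims) ||
      !identical(dim(object@input), dims)) {
    msg <- c(msg, "all image slots must share one shape")
  } else {
    recon <- object@weightMap * object@input +
      (1 - object@weightMap) * object@syntheticExposure
    if (max(abs(recon - object@enhanced)) > 1e-10) {
      msg <- c(msg, "enhanced != W*P + (1-W)*g(P,k) beyond 1e-10")
    }
  }
  if (object@exposureRatio <= 0) msg <- c(msg, "exposureRatio must be > 0")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------- GradientMap

#' GradientMap: multi-scale morphological gradient of an image
#'
#' Per-pixel non-negative contrast measure
#' `M = sum_t w_t * (dilate(f, SE_t) - erode(f, SE_t))` with scale weights
#' `w_t = 1/(2t + 1)` and `SE_t` the base structuring element dilated
#' `t - 1` times.
#'
#' @slot values the gradient map M (non-negative).
#' @slot scalesUsed number of scales N.
#' @slot perScale optional list of the single-scale gradients `G_t`.
#' @seealso [msmg()]
#' @export
setClass("GradientMap", representation(
  values = "matrix",
  scalesUsed = "integer",
  perScale = "list"
))

setValidity("GradientMap", function(object) {
  msg <- character()
  if (min(object@values) < -1e-12) msg <- c(msg, "gradient values must be >= 0")
  if (object@scalesUsed < 1L) msg <- c(msg, "scalesUsed must be >= 1")
  if (length(msg)) msg else TRUE
})

# --------------------------------------------------------- MongoosePopulation

#' MongoosePopulation: state of the IDMO search population
#'
#' The n-by-d position matrix of candidate solutions inside the box
#' `[lower, upper]`, their fitness under the objective, the index of the
#' current alpha (the best individual), iteration counters and the babysitter
#' bookkeeping (reserve individuals exchanged on a timer).
#'
#' @slot X numeric n-by-d position matrix.
#' @slot fitness numeric length-n objective values.
#' @slot lower,upper numeric length-d box bounds.
#' @slot alphaIndex integer index of the best (minimum-fitness) individual.
#' @slot cIter,maxIter current iteration and iteration budget.
#' @slot babysitterCount number of reserve individuals.
#' @slot babysitterTimer countdown until the next exchange.
#' @slot timerReset value the countdown is reset to after an exchange.
#' @slot evaluations objective evaluations spent so far.
#' @seealso [initPopulation()], [idmoOptimize()]
#' @export
setClass("MongoosePopulation", representation(
  X = "matrix",
  fitness = "numeric",
  lower = "numeric",
  upper = "numeric",
  alphaIndex = "integer",
  cIter = "integer",
  maxIter = "integer",
  babysitterCount = "integer",
  babysitterTimer = "integer",
  timerReset = "integer",
  evaluations = "integer"
))

setValidity("MongoosePopulation", function(object) {
  msg <- character()
  n <- nrow(object@X); d <- ncol(object@X)
  if (length(object@fitness) != n) msg <- c(msg, "fitness length must equal nrow(X)")
  if (length(object@lower) != d || length(object@upper) != d) {
    msg <- c(msg, "bounds must have one entry per dimension")
  } else if (any(object@lower >= object@upper)) {
    msg <- c(msg, "lower must be < upper in every dimension")
  } else {
    tol <- 1e-9
    if (any(sweep(object@X, 2, object@lower, "-") < -tol) ||
        any(sweep(object@X, 2, object@upper, "-") > tol)) {
      msg <- c(msg, "positions must lie inside [lower, upper]")
    }
  }
  if (n > 0 && !anyNA(object@fitness)) {
    if (abs(object@fitness[object@alphaIndex] - min(object@fitness)) > 0) {
      msg <- c(msg, "fitness[alphaIndex] must equal min(fitness)")
    }
  }
  if (object@babysitterCount >= n) msg <- c(msg, "babysitterCount must be < n")
  if (length(msg)) msg else TRUE
})

# ------------------------------------------------------------- show methods

setMethod("show", "PhantomSpec", function(object) {
  lab <- c("mild", "moderate", "severe")[object@classLabel + 1L]
  cat("PhantomSpec:", object@imageSize, "x", object@imageSize,
      "| class", object@classLabel, paste0("(", lab, ")"),
      "| ventricleScale", format(object@ventricleScale, digits = 3),
      "| seed", object@seed, "\n")
})

setMethod("show", "FusionConfig", function(object) {
  cat("FusionConfig: BTF(a =", object@btfA, ", b =", object@btfB, ")",
      "| k in [", object@kRange[1], ",", object@kRange[2], "]",
      "| mean window", object@meanFilterWindow,
      "| MSMG scales", object@msmgScales,
      "| blend", object@blendMode, "\n")
})

setMethod("show", "EnhancementResult", function(object) {
  cat("EnhancementResult:", nrow(object@enhanced), "x", ncol(object@enhanced),
      "| k =", format(object@exposureRatio, digits = 4),
      "| mean W =", format(mean(object@weightMap), digits = 4), "\n")
})

setMethod("show", "GradientMap", function(object) {
  cat("GradientMap:", nrow(object@values), "x", ncol(object@values),
      "| N =", object@scalesUsed,
      "| mean M =", format(mean(object@values), digits = 4), "\n")
})

setMethod("show", "MongoosePopulation", function(object) {
  cat("MongoosePopulation: n =", nrow(object@X), ", d =", ncol(object@X),
      "| iter", object@cIter, "/", object@maxIter,
      "| best fitness", format(min(object@fitness), digits = 6),
      "| evaluations", object@evaluations, "\n")
})
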
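#' @title Internal utilities
#' @description Small shared helpers: clipping, validation, seeded evaluation.
#' @name pdfusenet-utils
#' @keywords internal
NULL

# clip values into [lo, hi]
clip01 <- function(x, lo = 0, hi = 1) {
  x[x < lo] <- lo
  x[x > hi] <- hi
  x
}

stopIfNot01 <- function(image, what = "image") {
  if (!is.numeric(image) || !is.matrix(image)) {
    stop("pdfusenet: ", what, " must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(image)) {
    stop("pdfusenet: ", what, " contains NA/NaN pixels", call. = FALSE)
  }
  if (min(image) < -1e-12 || max(image) > 1 + 1e-12) {
    stop("pdfusenet: ", what, " intensities must lie in [0, 1]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the previous state so seeded building blocks never perturb the
#' RNG stream of the code that calls them.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# derive a stage seed from a master seed; stays below 2^31 - 1
deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(index)) %% 2147483647)
}

# reflect-pad a matrix by p pixels on every side (edge pixel not duplicated,
# i.e. "symmetric about the border pixel" style used by the box mean filter)
padReflect <- function(x, p) {
  if (p == 0) return(x)
  H <- nrow(x); W <- ncol(x)
  if (p >= H || p >= W) stop("pdfusenet: padding exceeds image size", call. = FALSE)
  ridx <- c((p + 1):2, 1:H, (H - 1):(H - p))
  cidx <- c((p + 1):2, 1:W, (W - 1):(W - p))
  x[ridx, cidx, drop = FALSE]
}

# constant-pad a matrix by p pixels with `value` (used by morphology: -Inf/+Inf)
padConst <- function(x, p, value) {
  if (p == 0) return(x)
  H <- nrow(x); W <- ncol(x)
  out <- matrix(value, H + 2 * p, W + 2 * p)
  out[(p + 1):(p + H), (p + 1):(p + W)] <- x
  out
}
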
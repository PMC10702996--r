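# Fusion preprocessing: exposure-fusion contrast enhancement via a
# camera-response brightness transform, box-mean denoising, and a blend of
# the two preprocessed copies driven by the multi-scale morphological
# gradient (MSMG) used as a per-pixel focus/contrast measure.

#' Construct a fusion configuration
#'
#' @param btfA,btfB brightness-transform constants (defaults 0.3293 and
#'   1.158). The transform is `g(P, k) = exp(btfB * (1 - k^btfA)) *
#'   P^(k^btfA)`; the camera-response literature also uses the negative-a
#'   parameterization, selectable here.
#' @param kRange search interval for the exposure ratio k (default `[1, 8]`).
#' @param underexposedThreshold weight below which a pixel is treated as
#'   underexposed (default 0.5).
#' @param weightSmoothingSigma Gaussian sigma in pixels for the illumination
#'   weight map (default 5).
#' @param weightExponent exponent mu applied to the smoothed luminance
#'   (default 0.5).
#' @param meanFilterWindow odd box window of the mean filter (default 3).
#' @param msmgScales number of MSMG scales (default 3), with scale weights
#'   `w_t = 1/(2t + 1)`.
#' @param blendMode `"soft"` (logistic MSMG weighting, default) or `"hard"`
#'   (per-pixel selection, ties to the enhanced copy).
#' @param softSharpness logistic slope of the soft blend (default 4).
#' @param fusePartner `"filtered"` (default) or `"original"`: which copy is
#'   fused against the enhanced one in [preprocessImage()].
#' @return A [FusionConfig-class] object.
#' @export
fusionConfig <- function(btfA = 0.3293, btfB = 1.158, kRange = c(1, 8),
                         underexposedThreshold = 0.5,
                         weightSmoothingSigma = 5, weightExponent = 0.5,
                         meanFilterWindow = 3L, msmgScales = 3L,
                         blendMode = c("soft", "hard"), softSharpness = 4,
                         fusePartner = c("filtered", "original")) {
  new("FusionConfig",
      btfA = btfA, btfB = btfB, kRange = as.numeric(kRange),
      underexposedThreshold = underexposedThreshold,
      weightSmoothingSigma = weightSmoothingSigma,
      weightExponent = weightExponent,
      meanFilterWindow = as.integer(meanFilterWindow),
      msmgScales = as.integer(msmgScales),
      blendMode = match.arg(blendMode), softSharpness = softSharpness,
      fusePartner = match.arg(fusePartner))
}

#' Brightness transform function (BTF)
#'
#' The beta-gamma camera-response transform
#' `g(P, k) = beta * P^gamma` with `beta = exp(b * (1 - k^a))` and
#' `gamma = k^a`, applied pixelwise and clipped to `[0, 1]`.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param k exposure ratio (> 0); `k = 1` is the identity.
#' @param config a [FusionConfig-class] providing the constants a, b.
#' @return The re-exposed image, same shape, in `[0, 1]`.
#' @export
btf <- function(image, k, config = fusionConfig()) {
  stopIfNot01(image)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0) {
    stop("pdfusenet: exposure ratio k must be a positive scalar", call. = FALSE)
  }
  gamma <- k^config@btfA
  beta <- exp(config@btfB * (1 - gamma))
  clip01(beta * image^gamma)
}

#' Illumination weight map
#'
#' Per-pixel weight `W = smooth(P)^mu` in `[0, 1]`: the Gaussian-smoothed
#' local luminance raised to a positive exponent, high where the image is
#' well exposed and low where it is underexposed.
#'
#' @inheritParams btf
#' @return Weight matrix W, same shape as `image`, in `[0, 1]`.
#' @export
illuminationWeight <- function(image, config = fusionConfig()) {
  stopIfNot01(image)
  clip01(gaussianSmooth(image, config@weightSmoothingSigma))^config@weightExponent
}

# Shannon entropy (bits) of intensities quantized to 256 levels
intensityEntropy <- function(v) {
  counts <- tabulate(pmin(floor(v * 256), 255) + 1L, 256L)
  p <- counts[counts > 0] / length(v)
  -sum(p * log2(p))
}

#' Find the optimal exposure ratio
#'
#' Maximizes the Shannon entropy of the re-exposed underexposed pixels
#' `g(Q, k)`, where `Q = {P : W < underexposedThreshold}`, over the
#' configured k interval. Search is a coarse grid followed by fine-grid
#' refinement to a resolution of 1e-3; ties are broken toward the smallest
#' k. When no pixel is underexposed, `k = 1`.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param W the illumination weight map from [illuminationWeight()].
#' @param config a [FusionConfig-class].
#' @return The selected exposure ratio k.
#' @export
findExposureRatio <- function(image, W, config = fusionConfig()) {
  if (length(image) == 0L) stop("pdfusenet: empty image", call. = FALSE)
  stopIfNot01(image)
  Q <- image[W < config@underexposedThreshold]
  if (length(Q) == 0L) return(1)
  lo <- config@kRange[1]; hi <- config@kRange[2]
  ent <- function(k) intensityEntropy(btf(matrix(Q, ncol = 1L), k, config))
  coarse <- seq(lo, hi, by = 0.1)
  if (coarse[length(coarse)] < hi) coarse <- c(coarse, hi)
  eC <- vapply(coarse, ent, numeric(1))
  iBest <- which.max(eC) # first maximum: smallest k on plateaus
  fine <- seq(max(lo, coarse[iBest] - 0.1), min(hi, coarse[iBest] + 0.1),
              by = 1e-3)
  eF <- vapply(fine, ent, numeric(1))
  fine[which.max(eF)]
}

#' Exposure-fusion contrast enhancement
#'
#' Composes [illuminationWeight()], [findExposureRatio()] and [btf()] into
#' the enhanced image `R = W * P + (1 - W) * g(P, k)`: well-exposed pixels
#' keep their original value, underexposed pixels are replaced by their
#' synthetic re-exposure.
#'
#' @inheritParams btf
#' @return An [EnhancementResult-class] holding R, W, k and `g(P, k)`.
#' @export
enhance <- function(image, config = fusionConfig()) {
  stopIfNot01(image)
  W <- illuminationWeight(image, config)
  k <- findExposureRatio(image, W, config)
  g <- btf(image, k, config)
  R <- W * image + (1 - W) * g
  new("EnhancementResult", enhanced = R, weightMap = W, exposureRatio = k,
      syntheticExposure = g, input = image)
}

#' Box mean filter
#'
#' The standard spatial-domain denoiser: each pixel is replaced by the mean
#' of the `window x window` neighborhood, with reflect padding at the
#' borders.
#'
#' @param image numeric matrix.
#' @param window odd window size >= 3.
#' @return The filtered image, same shape.
#' @export
meanFilter <- function(image, window = 3L) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("pdfusenet: image must be a numeric matrix", call. = FALSE)
  }
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) {
    stop("pdfusenet: mean-filter window must be odd and >= 3", call. = FALSE)
  }
  r <- (window - 1L) %/% 2L
  H <- nrow(image); W <- ncol(image)
  xp <- padReflect(image, r)
  out <- matrix(0, H, W)
  for (dy in 0:(window - 1L)) {
    for (dx in 0:(window - 1L)) {
      out <- out + xp[(1L + dy):(H + dy), (1L + dx):(W + dx), drop = FALSE]
    }
  }
  out / (window * window)
}

# structuring elements SE_t: the base disk dilated (t-1) times
msmgSEs <- function(nScales) {
  base <- baseDisk()
  ses <- vector("list", nScales)
  ses[[1L]] <- base
  if (nScales > 1L) {
    for (t in 2:nScales) ses[[t]] <- dilateSE(ses[[t - 1L]], base)
  }
  ses
}

#' Multi-scale morphological gradient (MSMG)
#'
#' Per-scale gradients `G_t = dilate(f, SE_t) - erode(f, SE_t)` with flat
#' structuring elements `SE_t` (the radius-1 discrete disk dilated `t - 1`
#' times), combined as the weighted total `M = sum_t w_t G_t` with
#' `w_t = 1/(2t + 1)`. M is a non-negative per-pixel contrast/focus measure.
#'
#' @param image numeric matrix.
#' @param config a [FusionConfig-class]; `msmgScales` sets N.
#' @param keepPerScale keep the individual `G_t` maps in the result.
#' @return A [GradientMap-class].
#' @export
msmg <- function(image, config = fusionConfig(), keepPerScale = FALSE) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("pdfusenet: image must be a numeric matrix", call. = FALSE)
  }
  N <- config@msmgScales
  ses <- msmgSEs(N)
  M <- matrix(0, nrow(image), ncol(image))
  per <- list()
  for (t in seq_len(N)) {
    G <- grayMorph(image, ses[[t]], "max") - grayMorph(image, ses[[t]], "min")
    M <- M + G / (2 * t + 1)
    if (keepPerScale) per[[t]] <- G
  }
  new("GradientMap", values = M, scalesUsed = N, perScale = per)
}

#' MSMG scale weights
#'
#' @param nScales number of scales N.
#' @return `1/(2t + 1)` for `t = 1..N`.
#' @export
msmgWeights <- function(nScales) 1 / (2 * seq_len(nScales) + 1)

#' Fuse two preprocessed copies using MSMG as focus measure
#'
#' Computes the MSMG map of each input and blends per pixel: in soft mode
#' the blend weight is `rho = logistic(sharpness * (M_a - M_b))`, in hard
#' mode the pixel with the larger MSMG wins (ties go to the first input).
#'
#' @param imageA,imageB numeric matrices of one shape in `[0, 1]` (by
#'   convention the enhanced and the filtered copies).
#' @param config a [FusionConfig-class] (`blendMode`, `softSharpness`,
#'   `msmgScales`).
#' @return The fused image in `[0, 1]`.
#' @export
fuseImages <- function(imageA, imageB, config = fusionConfig()) {
  stopIfNot01(imageA, "imageA"); stopIfNot01(imageB, "imageB")
  if (!identical(dim(imageA), dim(imageB))) {
    stop("pdfusenet: images to fuse must share one shape", call. = FALSE)
  }
  Ma <- gradientValues(msmg(imageA, config))
  Mb <- gradientValues(msmg(imageB, config))
  rho <- if (config@blendMode == "hard") {
    (Ma >= Mb) * 1
  } else {
    stats::plogis(config@softSharpness * (Ma - Mb))
  }
  clip01(rho * imageA + (1 - rho) * imageB)
}

#' Full preprocessing of one image
#'
#' Creates the two copies — exposure-fusion enhanced and box-mean filtered —
#' and fuses them via [fuseImages()]. With `fusePartner = "original"` the
#' enhanced copy is fused against the unfiltered input instead.
#'
#' @inheritParams btf
#' @return A list with `fused` (the preprocessed image), `k` (exposure
#'   ratio), `meanW` (mean illumination weight) and `meanM` (mean MSMG of
#'   the fused image).
#' @export
preprocessImage <- function(image, config = fusionConfig()) {
  enh <- enhance(image, config)
  partner <- if (config@fusePartner == "filtered") {
    meanFilter(image, config@meanFilterWindow)
  } else {
    image
  }
  fused <- fuseImages(enhancedImage(enh), clip01(partner), config)
  list(fused = fused, k = exposureRatio(enh),
       meanW = mean(weightMap(enh)),
       meanM = mean(gradientValues(msmg(fused, config))))
}
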
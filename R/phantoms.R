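# Synthetic brain phantoms with class-dependent morphology.
#
# The generator emulates the statistical structure of axial T1-weighted
# slices at the level a severity classifier cares about: an elliptical brain
# on a dark background, a bright cortical band whose thickness shrinks with
# severity, paired dark lateral ventricles whose area grows with severity,
# smooth intra-brain texture, a multiplicative illumination gradient and
# additive Gaussian noise. The class signal is geometric (ventricle area and
# cortical thinning), never a mean-intensity shift, so intensity-space
# preprocessing cannot trivially create or destroy it.

.classNames <- c("mild", "moderate", "severe")
.defaultVentricleScale <- c(1.0, 1.4, 1.8)
.defaultCorticalThickness <- c(0.12, 0.09, 0.06)

#' Construct a phantom specification
#'
#' @param classLabel severity class: 0/1/2 or `"mild"`/`"moderate"`/`"severe"`.
#' @param imageSize square image side in pixels (>= 32).
#' @param ventricleScale multiplier on the ventricle semi-axes; defaults to
#'   the class-dependent schedule 1.0 / 1.4 / 1.8 (mild / moderate / severe).
#' @param corticalThickness cortical band thickness as a fraction of the
#'   brain semi-axis; defaults to 0.12 / 0.09 / 0.06 by class.
#' @param textureSigma sd of the smoothed intra-brain texture (intensity units).
#' @param noiseSigma sd of the additive Gaussian noise (intensity units).
#' @param illuminationGradient amplitude of the multiplicative shading,
#'   in `[0, 0.6]`.
#' @param seed integer RNG seed; the phantom is a deterministic function of
#'   its spec.
#' @return A [PhantomSpec-class] object.
#' @examples
#' spec <- phantomSpec("moderate", seed = 7)
#' img <- generatePhantom(spec)
#' range(img)
#' @export
phantomSpec <- function(classLabel, imageSize = 128L, ventricleScale = NULL,
                        corticalThickness = NULL, textureSigma = 0.04,
                        noiseSigma = 0.03, illuminationGradient = 0.3,
                        seed = 1L) {
  if (is.character(classLabel)) {
    idx <- match(classLabel, .classNames)
    if (is.na(idx)) {
      stop("pdfusenet: invalid class label '", classLabel,
           "' (expected mild/moderate/severe)", call. = FALSE)
    }
    classLabel <- idx - 1L
  }
  if (!is.numeric(classLabel) || length(classLabel) != 1L ||
      !(classLabel %in% 0:2)) {
    stop("pdfusenet: invalid class label (expected 0, 1 or 2)", call. = FALSE)
  }
  classLabel <- as.integer(classLabel)
  if (is.null(ventricleScale)) ventricleScale <- .defaultVentricleScale[classLabel + 1L]
  if (is.null(corticalThickness)) {
    corticalThickness <- .defaultCorticalThickness[classLabel + 1L]
  }
  new("PhantomSpec",
      imageSize = as.integer(imageSize), classLabel = classLabel,
      ventricleScale = ventricleScale, corticalThickness = corticalThickness,
      textureSigma = textureSigma, noiseSigma = noiseSigma,
      illuminationGradient = illuminationGradient, seed = as.integer(seed))
}

#' Generate one synthetic brain phantom
#'
#' Deterministic for a fixed spec: the same seed yields a bit-identical
#' image. The returned matrix carries the attributes `label` (integer class),
#' `ventricleArea` (pixel count of the ventricle mask before rendering) and
#' `brainArea`.
#'
#' @param spec a [PhantomSpec-class], e.g. from [phantomSpec()].
#' @return A numeric `imageSize x imageSize` matrix with values in `[0, 1]`.
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  S <- spec@imageSize
  ax <- seq(-1, 1, length.out = S)
  xx <- matrix(rep(ax, each = S), S, S)   # column coordinate
  yy <- matrix(rep(ax, times = S), S, S)  # row coordinate

  brain <- (xx / 0.62)^2 + (yy / 0.78)^2 <= 1
  th <- spec@corticalThickness
  inner <- (xx / (0.62 * (1 - th)))^2 + (yy / (0.78 * (1 - th)))^2 <= 1
  vs <- spec@ventricleScale
  vent <- ((xx - 0.16) / (0.10 * vs))^2 + ((yy + 0.08) / (0.24 * vs))^2 <= 1 |
          ((xx + 0.16) / (0.10 * vs))^2 + ((yy + 0.08) / (0.24 * vs))^2 <= 1
  vent <- vent & inner

  img <- matrix(0, S, S)
  img[brain] <- 0.55
  img[brain & !inner] <- 0.85
  img[vent] <- 0.12

  withSeed(spec@seed, {
    if (spec@textureSigma > 0) {
      tex <- gaussianSmooth(matrix(stats::rnorm(S * S), S, S), 2)
      tex <- tex / stats::sd(tex)
      img[brain] <- img[brain] + spec@textureSigma * tex[brain]
    }
    if (spec@illuminationGradient > 0) {
      theta <- stats::runif(1, 0, 2 * pi)
      field <- 1 + spec@illuminationGradient *
        (xx * cos(theta) + yy * sin(theta)) / 2
      img <- img * field
    }
    if (spec@noiseSigma > 0) {
      img <- img + matrix(stats::rnorm(S * S, sd = spec@noiseSigma), S, S)
    }
  })

  img <- clip01(img)
  attr(img, "label") <- spec@classLabel
  attr(img, "ventricleArea") <- sum(vent)
  attr(img, "brainArea") <- sum(brain)
  img
}

#' Generate a stratified labeled phantom dataset
#'
#' Draws `nPerClass` phantoms for each of the three severity classes, with
#' per-image morphological jitter (log-normal on the ventricle scale and the
#' cortical thickness) so that class distributions overlap realistically, and
#' splits each class into train/test with `round(splitFraction * nPerClass)`
#' training images. Identical seeds give identical manifests and images.
#'
#' @param nPerClass phantoms per class (>= 2, and both splits must be
#'   non-empty).
#' @param specDefaults a [PhantomSpec-class] holding the shared defaults
#'   (image size, noise, texture, illumination); class label and seed are
#'   overridden per image.
#' @param splitFraction training fraction in (0, 1); default 0.8.
#' @param seed master seed for the dataset.
#' @param dir optional directory; when given, 8-bit grayscale PNGs and a
#'   `manifest.csv` (`path,label,split,seed`) are written there.
#' @param jitterSd sd of the log-normal morphological jitter (0 disables).
#' @return A list with elements `train` and `test` (each a list of `images`
#'   — matrices — and integer `labels`) plus the `manifest` data frame.
#' @export
generateDataset <- function(nPerClass, specDefaults = phantomSpec(0L),
                            splitFraction = 0.8, seed = 1L, dir = NULL,
                            jitterSd = 0.06) {
  if (nPerClass < 2L) stop("pdfusenet: nPerClass must be >= 2", call. = FALSE)
  if (splitFraction <= 0 || splitFraction >= 1) {
    stop("pdfusenet: splitFraction must be in (0, 1)", call. = FALSE)
  }
  nTrain <- round(splitFraction * nPerClass)
  nTest <- nPerClass - nTrain
  if (nTrain < 1L || nTest < 1L) {
    stop("pdfusenet: nPerClass too small to populate both splits", call. = FALSE)
  }
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)

  images <- list(train = list(), test = list())
  labels <- list(train = integer(), test = integer())
  manifest <- NULL
  for (cls in 0:2) {
    for (i in seq_len(nPerClass)) {
      imgSeed <- deriveSeed(seed, cls * 1000003 + i)
      jit <- withSeed(deriveSeed(imgSeed, 1L), {
        exp(stats::rnorm(2L, 0, jitterSd))
      })
      spec <- phantomSpec(
        cls, imageSize = specDefaults@imageSize,
        ventricleScale = .defaultVentricleScale[cls + 1L] * jit[1L],
        corticalThickness = min(0.3, .defaultCorticalThickness[cls + 1L] * jit[2L]),
        textureSigma = specDefaults@textureSigma,
        noiseSigma = specDefaults@noiseSigma,
        illuminationGradient = specDefaults@illuminationGradient,
        seed = deriveSeed(imgSeed, 2L))
      img <- generatePhantom(spec)
      split <- if (i <= nTrain) "train" else "test"
      path <- NA_character_
      if (!is.null(dir)) {
        path <- file.path(dir, sprintf("phantom_c%d_%03d.png", cls, i))
        writeGrayPNG(img, path)
        img <- readGrayPNG(path) # bit-exact 8-bit round trip
        attr(img, "label") <- cls
      }
      images[[split]] <- c(images[[split]], list(img))
      labels[[split]] <- c(labels[[split]], cls)
      manifest <- rbind(manifest, data.frame(
        path = path, label = cls, split = split, seed = spec@seed,
        stringsAsFactors = FALSE))
    }
  }
  if (!is.null(dir)) {
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(train = list(images = images$train, labels = labels$train),
       test = list(images = images$test, labels = labels$test),
       manifest = manifest)
}

#' Write / read an 8-bit grayscale PNG
#'
#' Intensities are quantized to 8 bits (`round(x * 255) / 255`) before
#' writing, so a write-read round trip is bit-exact.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param path file path.
#' @return `writeGrayPNG` returns the path invisibly; `readGrayPNG` returns
#'   a numeric matrix in `[0, 1]`.
#' @export
writeGrayPNG <- function(image, path) {
  stopIfNot01(image)
  png::writePNG(round(image * 255) / 255, path)
  invisible(path)
}

#' @rdname writeGrayPNG
#' @export
readGrayPNG <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  x
}
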
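# End-to-end orchestration: phantom generation -> fusion preprocessing ->
# (optional PCFAN pretraining) -> classifier training -> (optional IDMO
# hyperparameter tuning) -> evaluation, with derived per-stage seeds, a
# canonical JSON report and separately returned wall-clock timings.

#' Default hyperparameter search space
#'
#' Five dimensions: log10 learning rate in `[-4, -1]`; batch size from
#' `{8, 16, 32}` via a rounded index in `[0, 2]`; log10 L2 weight decay in
#' `[-6, -2]`; dropout in `[0, 0.5]`; width multiplier in `[0.25, 1]`.
#'
#' @return Data frame with columns `name, transform, low, high` and a
#'   `gridValues` attribute.
#' @export
defaultSearchSpace <- function() {
  sp <- data.frame(
    name = c("lr", "batchSize", "weightDecay", "dropout", "widthMultiplier"),
    transform = c("log10", "grid", "log10", "linear", "linear"),
    low = c(-4, 0, -6, 0, 0.25),
    high = c(-1, 2, -2, 0.5, 1),
    stringsAsFactors = FALSE)
  attr(sp, "gridValues") <- list(batchSize = c(8L, 16L, 32L))
  sp
}

#' Decode / encode a point of the search space
#'
#' `decodeTheta` maps a raw vector inside the box to named hyperparameter
#' values (`10^x` for log10 dimensions, the nearest grid value for grid
#' dimensions); `encodeTheta` inverts it, so
#' `decodeTheta(space, encodeTheta(space, theta))` reproduces `theta` for
#' grid-valued dimensions.
#'
#' @param space a search space from [defaultSearchSpace()].
#' @param raw numeric vector inside the box.
#' @param theta named list of hyperparameter values.
#' @return `decodeTheta`: a named list; `encodeTheta`: a numeric vector.
#' @export
decodeTheta <- function(space, raw) {
  grids <- attr(space, "gridValues")
  out <- vector("list", nrow(space))
  names(out) <- space$name
  for (i in seq_len(nrow(space))) {
    v <- min(max(raw[i], space$low[i]), space$high[i])
    out[[i]] <- switch(space$transform[i],
      log10 = 10^v,
      linear = v,
      grid = {
        g <- grids[[space$name[i]]]
        g[min(max(round(v), 0L), length(g) - 1L) + 1L]
      })
  }
  out
}

#' @rdname decodeTheta
#' @export
encodeTheta <- function(space, theta) {
  grids <- attr(space, "gridValues")
  raw <- numeric(nrow(space))
  for (i in seq_len(nrow(space))) {
    v <- theta[[space$name[i]]]
    raw[i] <- switch(space$transform[i],
      log10 = log10(v),
      linear = v,
      grid = match(v, grids[[space$name[i]]]) - 1L)
  }
  raw
}

#' Construct a pipeline configuration
#'
#' Plain nested list (YAML round-trippable). Training defaults follow the
#' Adam / batch-32 / learning-rate-0.001 regime, scaled to a desk-size 30
#' epochs; the tuning and PCFAN stages are disabled by default.
#'
#' @param seed master seed; every stage derives its own seed from it.
#' @param nPerClass phantoms per class (default 100).
#' @param imageSize phantom side in pixels (default 128).
#' @param splitFraction training fraction (default 0.8).
#' @param preprocess enable the fusion preprocessing stage (default TRUE).
#' @param pcfan list: `enable` (default FALSE), `epochs`, `lr`, `batchSize`.
#' @param model list: `widthMultiplier` (default 0.5), `dropout` (0.2).
#' @param training list: `optimizer` ("adam"), `lr` (0.001), `epochs` (30),
#'   `batchSize` (32), `momentum` (0.9), `weightDecay` (0).
#' @param tuning list: `enable` (default FALSE), `n`, `maxIter`,
#'   `proxyEpochs`.
#' @param outDir optional output directory for report.json, history.csv and
#'   timings.csv.
#' @param deterministic reserved flag recorded in the report (all stages are
#'   seeded regardless).
#' @return A validated list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(seed = 1L, nPerClass = 100L, imageSize = 128L,
                           splitFraction = 0.8, preprocess = TRUE,
                           pcfan = list(), model = list(), training = list(),
                           tuning = list(), outDir = NULL,
                           deterministic = TRUE) {
  cfg <- list(
    seed = as.integer(seed),
    deterministic = isTRUE(deterministic),
    data = list(nPerClass = as.integer(nPerClass),
                imageSize = as.integer(imageSize),
                splitFraction = splitFraction),
    preprocess = isTRUE(preprocess),
    pcfan = utils::modifyList(
      list(enable = FALSE, epochs = 30L, lr = 1e-3, batchSize = 8L), pcfan),
    model = utils::modifyList(
      list(widthMultiplier = 0.5, dropout = 0.2), model),
    training = utils::modifyList(
      list(optimizer = "adam", lr = 0.001, epochs = 30L, batchSize = 32L,
           momentum = 0.9, weightDecay = 0), training),
    tuning = utils::modifyList(
      list(enable = FALSE, n = 6L, maxIter = 8L, proxyEpochs = 5L), tuning),
    outDir = outDir)
  if (cfg$data$splitFraction <= 0 || cfg$data$splitFraction >= 1) {
    stop("pdfusenet: splitFraction must be in (0, 1)", call. = FALSE)
  }
  structure(cfg, class = "pipelineConfig")
}

#' Write / read a pipeline configuration as YAML
#'
#' The round trip write -> read -> write is byte-identical.
#'
#' @param config a [pipelineConfig()].
#' @param path YAML file path.
#' @return `writePipelineConfig` returns the path invisibly;
#'   `readPipelineConfig` returns the configuration.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  structure(yaml::read_yaml(path), class = "pipelineConfig")
}

#' Tune classifier hyperparameters with IDMO
#'
#' Minimizes the validation error of a short proxy training run (fixed
#' reduced epochs, fixed seed per evaluation) over the search space. A
#' deterministic stub objective may be supplied instead of the proxy run,
#' in which case it receives the raw (continuous) coordinates.
#'
#' @param trainImages,trainLabels,valImages,valLabels the split (ignored
#'   when `objective` is supplied).
#' @param space search space, default [defaultSearchSpace()].
#' @param nPop,maxIter IDMO population size and iteration budget; the
#'   budget must cover at least one population sweep.
#' @param proxyEpochs epochs of each proxy training run.
#' @param imageSizeHint image side used to build proxy models (taken from
#'   the data).
#' @param objective optional deterministic stub `function(raw) scalar`.
#' @param seed seed for the optimizer and the proxy runs.
#' @return List with `best` (decoded hyperparameters), `bestRaw`,
#'   `bestError`, `trace` (per-iteration optimizer trace), `evaluated`
#'   (data frame of every evaluated raw point and its error) and
#'   `evaluations`.
#' @export
tuneHyperparameters <- function(trainImages = NULL, trainLabels = NULL,
                                valImages = NULL, valLabels = NULL,
                                space = defaultSearchSpace(), nPop = 6L,
                                maxIter = 8L, proxyEpochs = 5L,
                                objective = NULL, seed = 1L) {
  if (maxIter < 1L) {
    stop("pdfusenet: tuning budget smaller than one population sweep",
         call. = FALSE)
  }
  log <- new.env(parent = emptyenv())
  log$rows <- list()
  proxy <- if (!is.null(objective)) {
    function(raw) {
      v <- objective(raw)
      log$rows[[length(log$rows) + 1L]] <- c(raw, error = v)
      v
    }
  } else {
    function(raw) {
      th <- decodeTheta(space, raw)
      m <- buildMobileNetV3(
        modelConfig(widthMultiplier = th$widthMultiplier, dropout = th$dropout),
        seed = deriveSeed(seed, 911L))
      tr <- trainClassifier(
        m, trainImages, trainLabels, valImages, valLabels,
        hyper = list(lr = th$lr, epochs = proxyEpochs,
                     batchSize = th$batchSize, weightDecay = th$weightDecay),
        seed = deriveSeed(seed, 913L))
      err <- 1 - tr$history$valAcc[nrow(tr$history)]
      log$rows[[length(log$rows) + 1L]] <- c(raw, error = err)
      err
    }
  }
  cfg <- idmoConfig(n = nPop, maxIter = maxIter,
                    seed = deriveSeed(seed, 907L))
  frozen <- space$low == space$high
  if (all(frozen)) {
    # fully collapsed space: evaluate the single point once per individual
    pt <- space$low
    errs <- vapply(seq_len(nPop), function(i) proxy(pt), numeric(1))
    res <- list(bestX = pt, bestFitness = min(errs),
                trace = data.frame(iteration = 0L, bestFitness = min(errs),
                                   meanFitness = mean(errs),
                                   evaluations = nPop),
                evaluations = nPop)
  } else if (any(frozen)) {
    # optimize the free dimensions, holding frozen ones at their value
    full <- function(free) {
      x <- space$low
      x[!frozen] <- free
      x
    }
    sub <- function(raw) proxy(full(raw))
    res <- idmoOptimize(sub, space$low[!frozen], space$high[!frozen], cfg)
    res$bestX <- full(res$bestX)
  } else {
    res <- idmoOptimize(proxy, space$low, space$high, cfg)
  }
  evaluated <- as.data.frame(do.call(rbind, log$rows))
  names(evaluated) <- c(space$name, "error")
  list(best = decodeTheta(space, res$bestX), bestRaw = res$bestX,
       bestError = res$bestFitness, trace = res$trace, evaluated = evaluated,
       evaluations = res$evaluations)
}

preprocessSet <- function(images, fusion) {
  lapply(images, function(im) preprocessImage(im, fusion)$fused)
}

#' Run the full pipeline
#'
#' Generate (or reuse) phantoms, preprocess, optionally pretrain PCFAN and
#' pass images through it, optionally tune hyperparameters, train the
#' classifier, and evaluate on the held-out split. The returned `report`
#' contains only deterministic quantities (metrics, seeds, configuration,
#' history), so a same-seed rerun reproduces it bit-for-bit; wall-clock
#' `timings` are returned (and written) separately.
#'
#' @param config a [pipelineConfig()].
#' @param dataset optional pre-generated dataset (the [generateDataset()]
#'   return shape) to skip the generation stage.
#' @return List with `report`, `timings` (named seconds), `history`,
#'   `model`, and `tuning` (when enabled).
#' @export
runPipeline <- function(config = pipelineConfig(), dataset = NULL) {
  stopifnot(inherits(config, "pipelineConfig"))
  timings <- c()
  tic <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    list(value = v, sec = proc.time()[["elapsed"]] - t0)
  }

  seeds <- list(data = deriveSeed(config$seed, 1L),
                pcfan = deriveSeed(config$seed, 2L),
                tuning = deriveSeed(config$seed, 3L),
                model = deriveSeed(config$seed, 4L),
                training = deriveSeed(config$seed, 5L))

  if (is.null(dataset)) {
    g <- tic(generateDataset(
      config$data$nPerClass,
      phantomSpec(0L, imageSize = config$data$imageSize),
      splitFraction = config$data$splitFraction, seed = seeds$data))
    dataset <- g$value
    timings["generate"] <- g$sec
  }
  trainImgs <- dataset$train$images
  testImgs <- dataset$test$images
  trainLab <- dataset$train$labels
  testLab <- dataset$test$labels

  fusionStats <- NULL
  if (config$preprocess) {
    fusion <- fusionConfig()
    p <- tic({
      tr <- preprocessSet(trainImgs, fusion)
      te <- preprocessSet(testImgs, fusion)
      list(tr = tr, te = te)
    })
    trainImgs <- p$value$tr
    testImgs <- p$value$te
    timings["preprocess"] <- p$sec
  }

  pcfanLoss <- NULL
  if (isTRUE(config$pcfan$enable)) {
    p <- tic(pretrainPCFAN(trainImgs, pcfanConfig(),
                           epochs = config$pcfan$epochs, lr = config$pcfan$lr,
                           batchSize = config$pcfan$batchSize,
                           seed = seeds$pcfan))
    pre <- p$value
    timings["pcfan"] <- p$sec
    pcfanLoss <- list(initial = pre$initialLoss,
                      final = pre$history$loss[nrow(pre$history)])
    toImgs <- function(imgs) {
      out <- pcfanForward(pre$model, imgs)
      lapply(seq_len(dim(out)[4L]), function(i) out[, , 1L, i])
    }
    p2 <- tic(list(tr = toImgs(trainImgs), te = toImgs(testImgs)))
    trainImgs <- p2$value$tr
    testImgs <- p2$value$te
    timings["pcfanTransform"] <- p2$sec
  }

  hp <- config$training
  mcfg <- config$model
  tuning <- NULL
  if (isTRUE(config$tuning$enable)) {
    p <- tic(tuneHyperparameters(
      trainImgs, trainLab, testImgs, testLab,
      nPop = config$tuning$n, maxIter = config$tuning$maxIter,
      proxyEpochs = config$tuning$proxyEpochs, seed = seeds$tuning))
    tuning <- p$value
    timings["tuning"] <- p$sec
    hp$lr <- tuning$best$lr
    hp$batchSize <- tuning$best$batchSize
    hp$weightDecay <- tuning$best$weightDecay
    mcfg$dropout <- tuning$best$dropout
    mcfg$widthMultiplier <- tuning$best$widthMultiplier
  }

  model <- buildMobileNetV3(
    modelConfig(widthMultiplier = mcfg$widthMultiplier, dropout = mcfg$dropout),
    seed = seeds$model)
  p <- tic(trainClassifier(
    model, trainImgs, trainLab, testImgs, testLab,
    hyper = list(lr = hp$lr, epochs = hp$epochs, batchSize = hp$batchSize,
                 weightDecay = hp$weightDecay, optimizer = hp$optimizer,
                 momentum = hp$momentum),
    seed = seeds$training))
  trained <- p$value
  timings["train"] <- p$sec

  p <- tic({
    pred <- predictClasses(trained$model, testImgs)
    classificationReport(testLab, pred$labels, pred$probs)
  })
  rep <- p$value
  timings["evaluate"] <- p$sec

  report <- list(
    config = unclass(config),
    seeds = seeds,
    nParams = nParams(trained$model),
    pcfanLoss = pcfanLoss,
    bestHyperparameters = if (!is.null(tuning)) tuning$best,
    finalEpoch = as.list(trained$history[nrow(trained$history), ]),
    metrics = list(
      overallAccuracy = rep$overallAccuracy,
      perClass = rep$perClass,
      macro = as.list(rep$macro),
      weighted = as.list(rep$weighted),
      macroAuc = rep$auc$macroAuc,
      perClassAuc = rep$auc$perClass,
      confusion = rep$counts))

  if (!is.null(config$outDir)) {
    if (!dir.exists(config$outDir)) dir.create(config$outDir, recursive = TRUE)
    jsonlite::write_json(report, file.path(config$outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    utils::write.csv(trained$history,
                     file.path(config$outDir, "history.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(stage = names(timings), seconds = timings),
                     file.path(config$outDir, "timings.csv"),
                     row.names = FALSE)
  }

  list(report = report, timings = timings, history = trained$history,
       model = trained$model, tuning = tuning)
}
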
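# Compact, width-configurable MobileNetV3-style classifier: stem conv,
# a reduced stack of bneck blocks (inverted residual: 1x1 expand -> depthwise
# -> optional squeeze-excite -> linear 1x1 project, skip when stride 1 and
# widths match), 1x1 head conv, global average pooling, dropout and a linear
# softmax head over the three severity classes.

#' Specify one bneck (inverted residual) block
#'
#' @param inCh,expandCh,outCh input, expanded and output channel counts.
#' @param kernel depthwise kernel size, 3 or 5.
#' @param stride 1 or 2.
#' @param useSE include the squeeze-excitation module (hard-sigmoid gate,
#'   reduction 4 on the expanded width).
#' @param activation `"relu"` or `"hswish"` for the expand and depthwise
#'   stages; the projection is always linear.
#' @return A validated list of class `bneckSpec`. The residual skip is
#'   active iff `stride == 1` and `inCh == outCh`.
#' @export
bneckSpec <- function(inCh, expandCh, outCh, kernel = 3L, stride = 1L,
                      useSE = FALSE, activation = c("relu", "hswish")) {
  if (!kernel %in% c(3L, 5L)) stop("pdfusenet: kernel must be 3 or 5", call. = FALSE)
  if (!stride %in% c(1L, 2L)) stop("pdfusenet: stride must be 1 or 2", call. = FALSE)
  structure(list(inCh = as.integer(inCh), expandCh = as.integer(expandCh),
                 outCh = as.integer(outCh), kernel = as.integer(kernel),
                 stride = as.integer(stride), useSE = isTRUE(useSE),
                 activation = match.arg(activation)),
            class = "bneckSpec")
}

# reduced 6-block schedule (base widths, before the width multiplier)
defaultBneckSpecs <- function() list(
  bneckSpec(16L, 16L, 16L, 3L, 2L, TRUE, "relu"),
  bneckSpec(16L, 72L, 24L, 3L, 2L, FALSE, "relu"),
  bneckSpec(24L, 88L, 24L, 3L, 1L, FALSE, "relu"),
  bneckSpec(24L, 96L, 40L, 5L, 2L, TRUE, "hswish"),
  bneckSpec(40L, 240L, 40L, 5L, 1L, TRUE, "hswish"),
  bneckSpec(40L, 120L, 48L, 5L, 1L, TRUE, "hswish"))

#' Classifier model configuration
#'
#' @param widthMultiplier channel scaling in `[0.25, 1]` (default 0.5);
#'   scaled widths are rounded to multiples of 8 with a floor of 8.
#' @param nClasses number of severity classes (default 3).
#' @param inputChannels input image channels (default 1, grayscale).
#' @param dropout dropout fraction before the linear head (default 0.2).
#' @param bneckSpecs ordered list of [bneckSpec()]s (base widths).
#' @param stemChannels,headChannels base widths of the stem and head convs.
#' @return A validated list of class `modelConfig`.
#' @export
modelConfig <- function(widthMultiplier = 0.5, nClasses = 3L,
                        inputChannels = 1L, dropout = 0.2,
                        bneckSpecs = defaultBneckSpecs(),
                        stemChannels = 16L, headChannels = 96L) {
  if (widthMultiplier < 0.25 || widthMultiplier > 1) {
    stop("pdfusenet: widthMultiplier must be in [0.25, 1]", call. = FALSE)
  }
  if (nClasses < 2L) stop("pdfusenet: nClasses must be >= 2", call. = FALSE)
  if (dropout < 0 || dropout >= 1) stop("pdfusenet: dropout must be in [0, 1)",
                                        call. = FALSE)
  structure(list(widthMultiplier = widthMultiplier,
                 nClasses = as.integer(nClasses),
                 inputChannels = as.integer(inputChannels), dropout = dropout,
                 bneckSpecs = bneckSpecs,
                 stemChannels = as.integer(stemChannels),
                 headChannels = as.integer(headChannels)),
            class = "modelConfig")
}

# scale a channel count by the width multiplier, multiple of 8, floor 8
roundChannels <- function(c, mult) max(8L, as.integer(round(c * mult / 8) * 8))

scaleSpecs <- function(config) {
  wm <- config$widthMultiplier
  stem <- roundChannels(config$stemChannels, wm)
  prev <- stem
  specs <- lapply(config$bneckSpecs, function(s) {
    s$inCh <- prev
    s$expandCh <- roundChannels(s$expandCh, wm)
    s$outCh <- roundChannels(s$outCh, wm)
    prev <<- s$outCh
    s
  })
  list(stem = stem, specs = specs,
       head = roundChannels(config$headChannels, wm))
}

bneckInit <- function(spec) {
  p <- list(expand = convInit(1L, spec$inCh, spec$expandCh),
            bn1 = bnInit(spec$expandCh),
            dw = dwInit(spec$kernel, spec$expandCh),
            bn2 = bnInit(spec$expandCh),
            project = convInit(1L, spec$expandCh, spec$outCh),
            bn3 = bnInit(spec$outCh))
  if (spec$useSE) p$se <- seInit(spec$expandCh, max(1L, spec$expandCh %/% 4L))
  p
}

#' Build the classifier
#'
#' Stem 3x3 stride-2 convolution (batch norm, hard-swish), the bneck stack,
#' a 1x1 head convolution, global average pooling, dropout, and a linear
#' layer producing softmax class probabilities.
#'
#' @param config a [modelConfig()].
#' @param seed seed for the He-initialized weight draw.
#' @return A model list (`config`, scaled `arch`, `params`).
#' @export
buildMobileNetV3 <- function(config = modelConfig(), seed = 1L) {
  arch <- scaleSpecs(config)
  params <- withSeed(seed, {
    blocks <- lapply(arch$specs, bneckInit)
    list(stem = list(conv = convInit(3L, config$inputChannels, arch$stem),
                     bn = bnInit(arch$stem)),
         blocks = blocks,
         head = list(conv = convInit(1L, arch$specs[[length(arch$specs)]]$outCh,
                                     arch$head),
                     bn = bnInit(arch$head),
                     fc = denseInit(arch$head, config$nClasses)))
  })
  list(config = config, arch = arch, params = params)
}

#' Number of trainable parameters
#'
#' Counts weights, biases and batch-norm scale/shift; running batch-norm
#' statistics are excluded.
#'
#' @param model a model from [buildMobileNetV3()] or [pcfanInit()].
#' @return Integer parameter count.
#' @export
nParams <- function(model) as.integer(countParams(model$params))

# ------------------------------------------------------------- bneck fwd/bwd

bneckFwd <- function(par, spec, x, training) {
  e <- convFwd(par$expand, x, 1L)
  b1 <- bnFwd(par$bn1, e$out, training)
  a1 <- actFwd(spec$activation, b1$out)
  dwv <- dwFwd(par$dw, a1$out, spec$kernel, stride = spec$stride)
  b2 <- bnFwd(par$bn2, dwv$out, training)
  a2 <- actFwd(spec$activation, b2$out)
  h <- a2$out
  seCache <- NULL
  if (spec$useSE) {
    sev <- seFwd(par$se, h, "hsigmoid")
    h <- sev$out
    seCache <- sev$cache
  }
  pr <- convFwd(par$project, h, 1L)
  b3 <- bnFwd(par$bn3, pr$out, training)
  skip <- spec$stride == 1L && spec$inCh == spec$outCh
  out <- if (skip) b3$out + x else b3$out
  list(out = out,
       cache = list(e = e$cache, b1 = b1$cache, a1 = a1$cache, dw = dwv$cache,
                    b2 = b2$cache, a2 = a2$cache, se = seCache, pr = pr$cache,
                    b3 = b3$cache, skip = skip),
       states = list(bn1 = b1$state, bn2 = b2$state, bn3 = b3$state))
}

bneckBwd <- function(par, spec, cache, dy) {
  g <- list()
  d3 <- bnBwd(par$bn3, cache$b3, dy)
  g$bn3 <- d3$grads
  bp <- convBwd(par$project, cache$pr, d3$dx)
  g$project <- bp$grads
  dh <- bp$dx
  if (spec$useSE) {
    bs <- seBwd(par$se, cache$se, dh)
    g$se <- bs$grads
    dh <- bs$dx
  }
  da2 <- actBwd(spec$activation, cache$a2, dh)
  d2 <- bnBwd(par$bn2, cache$b2, da2)
  g$bn2 <- d2$grads
  bdw <- dwBwd(par$dw, cache$dw, d2$dx)
  g$dw <- bdw$grads
  da1 <- actBwd(spec$activation, cache$a1, bdw$dx)
  d1 <- bnBwd(par$bn1, cache$b1, da1)
  g$bn1 <- d1$grads
  be <- convBwd(par$expand, cache$e, d1$dx)
  g$expand <- be$grads
  dx <- be$dx
  if (cache$skip) dx <- dx + dy
  list(dx = dx, grads = g)
}

# ------------------------------------------------------------- model fwd/bwd

mnv3Forward <- function(model, x, training = FALSE) {
  p <- model$params
  st <- convFwd(p$stem$conv, x, 3L, stride = 2L)
  sb <- bnFwd(p$stem$bn, st$out, training)
  sa <- actFwd("hswish", sb$out)
  h <- sa$out
  bcaches <- vector("list", length(p$blocks))
  bstates <- vector("list", length(p$blocks))
  for (i in seq_along(p$blocks)) {
    r <- bneckFwd(p$blocks[[i]], model$arch$specs[[i]], h, training)
    h <- r$out
    bcaches[[i]] <- r$cache
    bstates[[i]] <- r$states
  }
  hc <- convFwd(p$head$conv, h, 1L)
  hb <- bnFwd(p$head$bn, hc$out, training)
  ha <- actFwd("hswish", hb$out)
  gp <- gapFwd(ha$out)
  dp <- dropoutFwd(gp$out, model$config$dropout, training)
  fc <- denseFwd(p$head$fc, dp$out)
  list(logits = fc$out, probs = softmaxProbs(fc$out),
       cache = list(st = st$cache, sb = sb$cache, sa = sa$cache,
                    blocks = bcaches, hc = hc$cache, hb = hb$cache,
                    ha = ha$cache, gp = gp$cache, dp = dp$cache,
                    fcIn = dp$out),
       states = list(stem = sb$state, blocks = bstates, head = hb$state))
}

mnv3Backward <- function(model, cache, dlogits) {
  p <- model$params
  g <- list(stem = list(), blocks = vector("list", length(p$blocks)),
            head = list())
  bfc <- denseBwd(p$head$fc, cache$fcIn, dlogits)
  g$head$fc <- bfc$grads
  ddp <- dropoutBwd(cache$dp, bfc$dx)
  dga <- gapBwd(cache$gp, ddp)
  dha <- actBwd("hswish", cache$ha, dga)
  dhb <- bnBwd(p$head$bn, cache$hb, dha)
  g$head$bn <- dhb$grads
  bhc <- convBwd(p$head$conv, cache$hc, dhb$dx)
  g$head$conv <- bhc$grads
  dy <- bhc$dx
  for (i in rev(seq_along(p$blocks))) {
    r <- bneckBwd(p$blocks[[i]], model$arch$specs[[i]], cache$blocks[[i]], dy)
    dy <- r$dx
    g$blocks[[i]] <- r$grads
  }
  dsa <- actBwd("hswish", cache$sa, dy)
  dsb <- bnBwd(p$stem$bn, cache$sb, dsa)
  g$stem$bn <- dsb$grads
  bst <- convBwd(p$stem$conv, cache$st, dsb$dx)
  g$stem$conv <- bst$grads
  list(dx = bst$dx, grads = g)
}

# merge freshly computed BN running stats back into the parameter tree
applyBnStates <- function(params, states) {
  if (!is.null(states$stem)) {
    params$stem$bn[c("runMean", "runVar")] <- states$stem
  }
  for (i in seq_along(states$blocks)) {
    for (nm in c("bn1", "bn2", "bn3")) {
      s <- states$blocks[[i]][[nm]]
      if (!is.null(s)) params$blocks[[i]][[nm]][c("runMean", "runVar")] <- s
    }
  }
  if (!is.null(states$head)) {
    params$head$bn[c("runMean", "runVar")] <- states$head
  }
  params
}

#' Predict class probabilities and labels
#'
#' @param model a trained or freshly built model.
#' @param images matrix, list of matrices, or `(H, W, C, N)` tensor.
#' @param batchSize evaluation batch size.
#' @return List with `probs` (row-stochastic N x K matrix) and `labels`
#'   (0-based class integers, the row-wise argmax).
#' @export
predictClasses <- function(model, images, batchSize = 32L) {
  x <- imagesToTensor(images)
  if (dim(x)[3L] != model$config$inputChannels) {
    stop("pdfusenet: input channel mismatch", call. = FALSE)
  }
  n <- dim(x)[4L]
  probs <- NULL
  for (start in seq(1L, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, n)
    fw <- mnv3Forward(model, x[, , , idx, drop = FALSE], training = FALSE)
    probs <- rbind(probs, fw$probs)
  }
  list(probs = probs, labels = max.col(probs, ties.method = "first") - 1L)
}

evalSplit <- function(model, x, labels, batchSize) {
  n <- dim(x)[4L]
  loss <- 0
  correct <- 0L
  for (start in seq(1L, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, n)
    fw <- mnv3Forward(model, x[, , , idx, drop = FALSE], training = FALSE)
    ce <- softmaxCE(fw$logits, labels[idx])
    loss <- loss + ce$loss * length(idx)
    correct <- correct +
      sum(max.col(fw$probs, ties.method = "first") - 1L == labels[idx])
  }
  c(acc = correct / n, loss = loss / n)
}

#' Train the classifier
#'
#' Cross-entropy training with Adam (default) or SGD-with-momentum, optional
#' L2 weight decay and dropout. Training accuracy/loss accumulate over the
#' training-mode minibatch outputs; validation metrics come from an
#' evaluation-mode pass at each epoch end. With `lr = 0` no parameter or
#' batch-norm state is updated, so (for a fixed batch composition, i.e.
#' `batchSize >= n`, and no dropout) the history is exactly constant.
#' Fixed seeds give reproducible histories.
#'
#' @param model a model from [buildMobileNetV3()].
#' @param images,labels training images (list of matrices or tensor) and
#'   0-based integer labels.
#' @param valImages,valLabels optional validation split.
#' @param hyper list of hyperparameters: `lr` (default 0.001), `epochs`
#'   (default 30), `batchSize` (default 32), `weightDecay` (default 0),
#'   `optimizer` (`"adam"` default or `"sgd"`), `momentum` (default 0.9,
#'   used by SGD only).
#' @param seed RNG seed for shuffling and dropout.
#' @return List with `model` (trained) and `history` (data frame
#'   `epoch, trainAcc, valAcc, trainLoss, valLoss`).
#' @export
trainClassifier <- function(model, images, labels, valImages = NULL,
                            valLabels = NULL, hyper = list(), seed = 1L) {
  h <- utils::modifyList(list(lr = 0.001, epochs = 30L, batchSize = 32L,
                              weightDecay = 0, optimizer = "adam",
                              momentum = 0.9), hyper)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("pdfusenet: training set contains a single class", call. = FALSE)
  }
  x <- imagesToTensor(images)
  n <- dim(x)[4L]
  if (length(labels) != n) stop("pdfusenet: labels/images length mismatch",
                                call. = FALSE)
  xv <- if (!is.null(valImages)) imagesToTensor(valImages)
  state <- adamInitState(model$params)
  history <- NULL
  set.seed(deriveSeed(seed, 29L))
  t <- 0L
  for (ep in seq_len(h$epochs)) {
    perm <- sample.int(n)
    lossSum <- 0
    correct <- 0L
    for (start in seq(1L, n, by = h$batchSize)) {
      idx <- perm[start:min(start + h$batchSize - 1L, n)]
      fw <- mnv3Forward(model, x[, , , idx, drop = FALSE], training = TRUE)
      ce <- softmaxCE(fw$logits, labels[idx])
      lossSum <- lossSum + ce$loss * length(idx)
      correct <- correct +
        sum(max.col(fw$probs, ties.method = "first") - 1L == labels[idx])
      if (h$lr > 0) {
        grads <- mnv3Backward(model, fw$cache, ce$dlogits)$grads
        t <- t + 1L
        st <- if (identical(h$optimizer, "sgd")) {
          sgdStep(model$params, grads, state, h$lr, h$momentum, h$weightDecay)
        } else {
          adamStep(model$params, grads, state, h$lr, t, h$weightDecay)
        }
        model$params <- applyBnStates(st$params, fw$states)
        state <- st$state
      }
    }
    va <- if (!is.null(xv)) evalSplit(model, xv, valLabels, h$batchSize) else
      c(acc = NA_real_, loss = NA_real_)
    history <- rbind(history, data.frame(
      epoch = ep, trainAcc = correct / n, valAcc = va[["acc"]],
      trainLoss = lossSum / n, valLoss = va[["loss"]]))
  }
  list(model = model, history = history)
}
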
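# Pyramid channel-based feature attention network (PCFAN): a three-scale
# encoder (32/64/128 channels at full/half/quarter resolution), four
# channel-attention blocks wired into a top-down pyramid fusion (PCFA), and
# a single-convolution reconstruction head. Trained self-supervised with an
# MSE reconstruction loss.

#' Construct a PCFAN configuration
#'
#' @param stageChannels strictly increasing channel triple for the three
#'   encoder stages (default 32, 64, 128).
#' @param resblocksPerStage residual blocks per stage (default 2).
#' @param attentionReduction channel-reduction divisor r of the attention
#'   blocks (default 8); must divide every attended channel count.
#' @param upsampleMode `"bilinear"` (default) or `"nearest"`.
#' @param outputChannels channels of the reconstructed image (default 1).
#' @return A validated list of class `pcfanConfig`.
#' @export
pcfanConfig <- function(stageChannels = c(32L, 64L, 128L),
                        resblocksPerStage = 2L, attentionReduction = 8L,
                        upsampleMode = c("bilinear", "nearest"),
                        outputChannels = 1L) {
  stageChannels <- as.integer(stageChannels)
  if (length(stageChannels) != 3L || any(diff(stageChannels) <= 0L)) {
    stop("pdfusenet: stageChannels must be a strictly increasing triple",
         call. = FALSE)
  }
  r <- as.integer(attentionReduction)
  attended <- c(stageChannels, stageChannels[2L] + stageChannels[3L])
  if (any(attended %% r != 0L)) {
    stop("pdfusenet: attentionReduction must divide every attended channel ",
         "count (", paste(attended, collapse = ", "), ")", call. = FALSE)
  }
  structure(list(stageChannels = stageChannels,
                 resblocksPerStage = as.integer(resblocksPerStage),
                 attentionReduction = r,
                 upsampleMode = match.arg(upsampleMode),
                 outputChannels = as.integer(outputChannels)),
            class = "pcfanConfig")
}

resInit <- function(c) list(conv1 = convInit(3L, c, c), conv2 = convInit(3L, c, c))

#' Initialize a PCFAN model
#'
#' He-initialized weights, deterministic for a fixed seed.
#'
#' @param config a [pcfanConfig()].
#' @param inputChannels channels of the input image (default 1).
#' @param seed integer seed for the weight draw.
#' @return A model list with elements `config` and `params`.
#' @export
pcfanInit <- function(config = pcfanConfig(), inputChannels = 1L, seed = 1L) {
  ch <- config$stageChannels
  r <- config$attentionReduction
  nres <- config$resblocksPerStage
  params <- withSeed(seed, list(
    stage1 = list(conv = convInit(3L, inputChannels, ch[1L]),
                  res = lapply(seq_len(nres), function(i) resInit(ch[1L]))),
    stage2 = list(conv = convInit(3L, ch[1L], ch[2L]),
                  res = lapply(seq_len(nres), function(i) resInit(ch[2L]))),
    stage3 = list(conv = convInit(3L, ch[2L], ch[3L]),
                  res = lapply(seq_len(nres), function(i) resInit(ch[3L]))),
    pcfa = list(ca3 = seInit(ch[3L], ch[3L] %/% r),
                ca2 = seInit(ch[2L], ch[2L] %/% r),
                ca23 = seInit(ch[2L] + ch[3L], (ch[2L] + ch[3L]) %/% r),
                ca1 = seInit(ch[1L], ch[1L] %/% r),
                fuse = convInit(1L, ch[1L] + ch[2L] + ch[3L], ch[1L])),
    recon = list(conv = convInit(3L, ch[1L], config$outputChannels))))
  list(config = config, params = params, inputChannels = as.integer(inputChannels))
}

#' Number of channel-attention blocks in the PCFA graph
#'
#' @param model a PCFAN model from [pcfanInit()].
#' @return Integer count (4 for the standard wiring).
#' @export
pcfaAttentionBlockCount <- function(model) {
  sum(grepl("^ca", names(model$params$pcfa)))
}

# list of H x W matrices (or one matrix / 4-d array) -> (H, W, C, N) tensor
imagesToTensor <- function(images) {
  if (is.matrix(images)) images <- list(images)
  if (is.array(images) && length(dim(images)) == 4L) return(images)
  d <- dim(images[[1L]])
  array(unlist(images, use.names = FALSE), c(d[1L], d[2L], 1L, length(images)))
}

padToMultiple <- function(x, m) {
  d <- dim(x)
  H2 <- ceiling(d[1L] / m) * m
  W2 <- ceiling(d[2L] / m) * m
  if (H2 == d[1L] && W2 == d[2L]) return(x)
  out <- array(0, c(H2, W2, d[3L], d[4L]))
  out[seq_len(d[1L]), seq_len(d[2L]), , ] <- x
  out
}

# -------------------------------------------------------- forward / backward

resFwd <- function(par, x) {
  c1 <- convFwd(par$conv1, x, 3L)
  a <- actFwd("relu", c1$out)
  c2 <- convFwd(par$conv2, a$out, 3L)
  list(out = x + c2$out, cache = list(c1 = c1$cache, a = a$cache, c2 = c2$cache))
}

resBwd <- function(par, cache, dy) {
  b2 <- convBwd(par$conv2, cache$c2, dy)
  da <- actBwd("relu", cache$a, b2$dx)
  b1 <- convBwd(par$conv1, cache$c1, da)
  list(dx = dy + b1$dx, grads = list(conv1 = b1$grads, conv2 = b2$grads))
}

stageFwd <- function(par, x, stride) {
  cv <- convFwd(par$conv, x, 3L, stride = stride)
  a <- actFwd("relu", cv$out)
  h <- a$out
  rcaches <- vector("list", length(par$res))
  for (i in seq_along(par$res)) {
    r <- resFwd(par$res[[i]], h)
    h <- r$out
    rcaches[[i]] <- r$cache
  }
  list(out = h, cache = list(cv = cv$cache, a = a$cache, res = rcaches))
}

stageBwd <- function(par, cache, dy) {
  gres <- vector("list", length(par$res))
  for (i in rev(seq_along(par$res))) {
    r <- resBwd(par$res[[i]], cache$res[[i]], dy)
    dy <- r$dx
    gres[[i]] <- r$grads
  }
  da <- actBwd("relu", cache$a, dy)
  bcv <- convBwd(par$conv, cache$cv, da)
  list(dx = bcv$dx, grads = list(conv = bcv$grads, res = gres))
}

encodeFwdInternal <- function(params, x) {
  s1 <- stageFwd(params$stage1, x, 1L)
  s2 <- stageFwd(params$stage2, s1$out, 2L)
  s3 <- stageFwd(params$stage3, s2$out, 2L)
  list(f1 = s1$out, f2 = s2$out, f3 = s3$out,
       cache = list(s1 = s1$cache, s2 = s2$cache, s3 = s3$cache))
}

pcfaFwdInternal <- function(params, pyr, mode) {
  a3 <- seFwd(params$ca3, pyr$f3)
  u3 <- upFwd(a3$out, mode)
  a2 <- seFwd(params$ca2, pyr$f2)
  cat32 <- concatC(u3$out, a2$out)
  a23 <- seFwd(params$ca23, cat32)
  u23 <- upFwd(a23$out, mode)
  a1 <- seFwd(params$ca1, pyr$f1)
  cat321 <- concatC(u23$out, a1$out)
  fz <- convFwd(params$fuse, cat321, 1L)
  list(out = fz$out,
       cache = list(a3 = a3$cache, u3 = u3$cache, a2 = a2$cache,
                    a23 = a23$cache, u23 = u23$cache, a1 = a1$cache,
                    fz = fz$cache, c3 = dim(pyr$f3)[3L],
                    cTop = dim(u23$out)[3L]))
}

pcfaBwdInternal <- function(params, cache, dy) {
  bfz <- convBwd(params$fuse, cache$fz, dy)
  sp <- splitC(bfz$dx, cache$cTop)
  du23 <- sp[[1L]]
  ba1 <- seBwd(params$ca1, cache$a1, sp[[2L]])
  da23 <- upBwd(cache$u23, du23)
  b23 <- seBwd(params$ca23, cache$a23, da23)
  sp2 <- splitC(b23$dx, cache$c3)
  du3 <- sp2[[1L]]
  ba2 <- seBwd(params$ca2, cache$a2, sp2[[2L]])
  da3 <- upBwd(cache$u3, du3)
  ba3 <- seBwd(params$ca3, cache$a3, da3)
  list(df1 = ba1$dx, df2 = ba2$dx, df3 = ba3$dx,
       grads = list(ca3 = ba3$grads, ca2 = ba2$grads, ca23 = b23$grads,
                    ca1 = ba1$grads, fuse = bfz$grads))
}

pcfanForwardInternal <- function(model, x) {
  enc <- encodeFwdInternal(model$params, x)
  pf <- pcfaFwdInternal(model$params$pcfa, enc, model$config$upsampleMode)
  rc <- convFwd(model$params$recon$conv, pf$out, 3L)
  sg <- actFwd("sigmoid", rc$out)
  list(out = sg$out,
       cache = list(enc = enc$cache, pf = pf$cache, rc = rc$cache,
                    sg = sg$cache))
}

pcfanBackwardInternal <- function(model, cache, dout) {
  dsg <- actBwd("sigmoid", cache$sg, dout)
  brc <- convBwd(model$params$recon$conv, cache$rc, dsg)
  bpf <- pcfaBwdInternal(model$params$pcfa, cache$pf, brc$dx)
  b3 <- stageBwd(model$params$stage3, cache$enc$s3, bpf$df3)
  b2 <- stageBwd(model$params$stage2, cache$enc$s2, bpf$df2 + b3$dx)
  b1 <- stageBwd(model$params$stage1, cache$enc$s1, bpf$df1 + b2$dx)
  list(dx = b1$dx,
       grads = list(stage1 = b1$grads, stage2 = b2$grads, stage3 = b3$grads,
                    pcfa = bpf$grads, recon = list(conv = brc$grads)))
}

# ------------------------------------------------------------- exported ops

#' Channel-attention gating of a feature map
#'
#' SE-style gating: the per-channel global-average descriptor is reduced
#' (`C -> C/r`), passed through ReLU, expanded back (`C/r -> C`) and squashed
#' by a sigmoid into an attention vector in `(0, 1)^C` that multiplies the
#' feature map elementwise. Output magnitudes therefore never exceed the
#' input's.
#'
#' @param f feature map: `(H, W, C)` or `(H, W, C, N)` array.
#' @param params optional parameter list (`W1, b1, W2, b2`); freshly
#'   initialized from `seed` when omitted.
#' @param reduction channel-reduction divisor r; must divide C.
#' @param seed seed for the default initialization.
#' @return The gated feature map, same shape as `f`.
#' @export
channelAttention <- function(f, params = NULL, reduction = 8L, seed = 1L) {
  squeeze <- FALSE
  if (length(dim(f)) == 3L) {
    dim(f) <- c(dim(f), 1L)
    squeeze <- TRUE
  }
  C <- dim(f)[3L]
  if (C %% reduction != 0L) {
    stop("pdfusenet: channel count ", C, " not divisible by reduction ",
         reduction, call. = FALSE)
  }
  if (is.null(params)) params <- withSeed(seed, seInit(C, C %/% reduction))
  out <- seFwd(params, f, "sigmoid")$out
  if (squeeze) dim(out) <- dim(out)[1:3]
  out
}

#' Encode an image into the three-scale feature pyramid
#'
#' Stage 1 is a 3x3 convolution to the first channel width plus residual
#' blocks at full resolution; stages 2 and 3 halve the resolution with a
#' stride-2 convolution while doubling the channels. Inputs are zero-padded
#' to multiples of 4 so the spatial dimensions halve exactly.
#'
#' @param model a PCFAN model from [pcfanInit()].
#' @param images a matrix, list of matrices, or `(H, W, C, N)` array.
#' @return A list `f1`, `f2`, `f3` of feature tensors (`(H, W, C, N)`).
#' @export
pcfanEncode <- function(model, images) {
  x <- padToMultiple(imagesToTensor(images), 4L)
  if (any(dim(x)[1:2] < 8L)) {
    stop("pdfusenet: input spatial dimensions must be >= 8", call. = FALSE)
  }
  enc <- encodeFwdInternal(model$params, x)
  list(f1 = enc$f1, f2 = enc$f2, f3 = enc$f3)
}

#' Pyramid channel-attention fusion (PCFA)
#'
#' Fixed wiring: the attended third-stage features are upsampled and
#' concatenated with the attended second stage; that concatenation passes a
#' third attention block, is upsampled and concatenated with the attended
#' first stage; a 1x1 convolution maps the result back to the stage-1
#' width. Exactly four channel-attention blocks, two upsamplings and two
#' concatenations are instantiated.
#'
#' @param model a PCFAN model.
#' @param pyramid a feature pyramid from [pcfanEncode()].
#' @return The fused feature map at full resolution, stage-1 channel width.
#' @export
pcfanFuse <- function(model, pyramid) {
  ch <- model$config$stageChannels
  ok <- identical(dim(pyramid$f1)[3L], ch[1L]) &&
    identical(dim(pyramid$f2)[3L], ch[2L]) &&
    identical(dim(pyramid$f3)[3L], ch[3L]) &&
    all(dim(pyramid$f2)[1:2] * 2L == dim(pyramid$f1)[1:2]) &&
    all(dim(pyramid$f3)[1:2] * 2L == dim(pyramid$f2)[1:2])
  if (!ok) stop("pdfusenet: pyramid shapes inconsistent with the model config",
                call. = FALSE)
  pcfaFwdInternal(model$params$pcfa, pyramid, model$config$upsampleMode)$out
}

#' Reconstruct an image from the fused feature map
#'
#' A single 3x3 convolution to the output channel count followed by a
#' sigmoid into `[0, 1]`.
#'
#' @param model a PCFAN model.
#' @param fused fused feature map from [pcfanFuse()].
#' @return Image tensor `(H, W, outputChannels, N)` in `[0, 1]`.
#' @export
pcfanReconstruct <- function(model, fused) {
  if (dim(fused)[3L] != model$config$stageChannels[1L]) {
    stop("pdfusenet: fused map must have the stage-1 channel width",
         call. = FALSE)
  }
  rc <- convFwd(model$params$recon$conv, fused, 3L)
  actFwd("sigmoid", rc$out)$out
}

#' Full PCFAN forward pass
#'
#' Encode, fuse, reconstruct. Deterministic for fixed weights and input.
#'
#' @inheritParams pcfanEncode
#' @return Reconstructed image tensor in `[0, 1]`.
#' @export
pcfanForward <- function(model, images) {
  x <- padToMultiple(imagesToTensor(images), 4L)
  pcfanForwardInternal(model, x)$out
}

#' Mean squared error between two images or tensors
#'
#' `L = mean((clear - extracted)^2)` over all channels and pixels.
#'
#' @param clear,extracted arrays of one shape.
#' @return Non-negative scalar; symmetric in its arguments.
#' @export
mseLoss <- function(clear, extracted) {
  if (!identical(dim(clear), dim(extracted))) {
    stop("pdfusenet: mseLoss shapes differ", call. = FALSE)
  }
  mean((clear - extracted)^2)
}

#' Self-supervised PCFAN pretraining
#'
#' Trains the network to reconstruct its own input (optionally from a
#' noise-corrupted copy) under the MSE loss with Adam. The per-epoch loss is
#' the evaluation-weighted mean over batches, so it is invariant to the
#' shuffling order.
#'
#' @param images list of grayscale matrices (>= 8).
#' @param config a [pcfanConfig()].
#' @param epochs training epochs (default 30).
#' @param lr Adam learning rate (default 1e-3); `lr = 0` leaves the model
#'   untouched.
#' @param batchSize minibatch size (default 8).
#' @param corruptSigma sd of Gaussian noise added to the inputs (target
#'   stays clean); 0 disables.
#' @param seed RNG seed (weights, shuffling, corruption).
#' @return List with `model` (trained), `history` (data frame
#'   `epoch, loss`), and `initialLoss` (full-data MSE at initialization).
#' @export
pretrainPCFAN <- function(images, config = pcfanConfig(), epochs = 30L,
                          lr = 1e-3, batchSize = 8L, corruptSigma = 0,
                          seed = 1L) {
  if (length(images) == 0L) stop("pdfusenet: empty training set", call. = FALSE)
  if (length(images) < 8L) {
    stop("pdfusenet: PCFAN pretraining needs >= 8 images", call. = FALSE)
  }
  model <- pcfanInit(config, inputChannels = 1L, seed = seed)
  x <- padToMultiple(imagesToTensor(images), 4L)
  n <- dim(x)[4L]
  state <- adamInitState(model$params)
  initialLoss <- mseLoss(pcfanForwardInternal(model, x)$out, x)
  history <- data.frame(epoch = integer(), loss = numeric())
  set.seed(deriveSeed(seed, 17L))
  t <- 0L
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    lossSum <- 0
    for (start in seq(1L, n, by = batchSize)) {
      idx <- perm[start:min(start + batchSize - 1L, n)]
      xb <- x[, , , idx, drop = FALSE]
      inb <- if (corruptSigma > 0) {
        clip01(xb + array(stats::rnorm(length(xb), sd = corruptSigma), dim(xb)))
      } else xb
      fw <- pcfanForwardInternal(model, inb)
      loss <- mseLoss(fw$out, xb)
      lossSum <- lossSum + loss * length(idx)
      if (lr > 0) {
        dout <- 2 * (fw$out - xb) / length(xb)
        grads <- pcfanBackwardInternal(model, fw$cache, dout)$grads
        t <- t + 1L
        st <- adamStep(model$params, grads, state, lr, t)
        model$params <- st$params
        state <- st$state
      }
    }
    history <- rbind(history, data.frame(epoch = ep, loss = lossSum / n))
  }
  list(model = model, history = history, initialLoss = initialLoss)
}
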
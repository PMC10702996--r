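# Minimal reverse-mode CNN primitives on dense double arrays.
#
# Tensor layout is (H, W, C, N) throughout (column-major; H fastest).
# Standard convolutions go through compiled im2col/col2im (src/kernels.cpp)
# plus one BLAS GEMM; depthwise convolutions run in compiled loops; pooling,
# normalization, attention and upsampling are vectorized R. Every primitive
# returns its forward value plus the cache its backward needs, and every
# backward is covered by central finite-difference tests.

#' @useDynLib PDFuseNet, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ------------------------------------------------------------ shape helpers

as4d <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  stopifnot(length(dim(x)) == 4L)
  x
}

pad4d <- function(x, p) {
  d <- dim(x)
  out <- array(0, c(d[1L] + 2L * p, d[2L] + 2L * p, d[3L], d[4L]))
  out[(p + 1L):(p + d[1L]), (p + 1L):(p + d[2L]), , ] <- x
  out
}

# (H,W,C,N) -> (H*W*N, C) matrix, channels as columns
toCN <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1L, 2L, 4L, 3L)), d[1L] * d[2L] * d[4L], d[3L])
}

fromCN <- function(m, d) {
  aperm(array(m, c(d[1L], d[2L], d[4L], d[3L])), c(1L, 2L, 4L, 3L))
}

# multiply x (H,W,C,N) by a per-(channel, sample) factor g (N, C)
scaleByChannel <- function(x, g) {
  d <- dim(x)
  x * rep(as.vector(t(g)), each = d[1L] * d[2L])
}

# sum of x over H, W -> (N, C)
sumHW <- function(x) {
  d <- dim(x)
  t(matrix(.colSums(x, d[1L] * d[2L], d[3L] * d[4L]), d[3L], d[4L]))
}

# sum of x over H, W, N -> length-C vector
sumHWN <- function(x) {
  d <- dim(x)
  .rowSums(matrix(.colSums(x, d[1L] * d[2L], d[3L] * d[4L]), d[3L], d[4L]),
           d[3L], d[4L])
}

# -------------------------------------------------------------- activations

#' Hard-swish activation
#'
#' `hswish(x) = x * relu6(x + 3) / 6` with `relu6(z) = min(max(z, 0), 6)`:
#' the cheap piecewise approximation of swish used throughout the
#' MobileNetV3 family. Continuous, monotone non-decreasing on `[-3, Inf)`,
#' asymptotically the identity.
#'
#' @param x numeric scalar, vector or array.
#' @return Same shape as `x`.
#' @examples
#' hSwish(c(-5, -3, 0, 3))
#' @export
hSwish <- function(x) x * pmin(pmax(x + 3, 0), 6) / 6

actFwd <- function(type, x) {
  out <- switch(type,
    linear = x,
    relu = { y <- x; y[y < 0] <- 0; y },
    relu6 = pmin(pmax(x, 0), 6),
    hswish = hSwish(x),
    sigmoid = 1 / (1 + exp(-x)),
    hsigmoid = pmin(pmax(x + 3, 0), 6) / 6,
    stop("unknown activation ", type))
  list(out = out, cache = if (type == "sigmoid") out else x)
}

actDeriv <- function(type, cache) {
  switch(type,
    linear = 1,
    relu = (cache > 0) * 1,
    relu6 = (cache > 0 & cache < 6) * 1,
    hswish = {
      d <- (2 * cache + 3) / 6
      d[cache <= -3] <- 0
      d[cache >= 3] <- 1
      d
    },
    sigmoid = cache * (1 - cache), # cache holds the output
    hsigmoid = (cache > -3 & cache < 3) / 6)
}

actBwd <- function(type, cache, dy) dy * actDeriv(type, cache)

# ------------------------------------------------------ standard convolution

convInit <- function(k, cin, cout) {
  sdw <- sqrt(2 / (k * k * cin))
  list(W = matrix(stats::rnorm(k * k * cin * cout, sd = sdw), k * k * cin, cout),
       b = numeric(cout))
}

convFwd <- function(par, x, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  d <- dim(x)
  Ho <- (d[1L] + 2L * pad - k) %/% stride + 1L
  Wo <- (d[2L] + 2L * pad - k) %/% stride + 1L
  P <- im2colCpp(x, d, k, stride, pad)
  Y <- P %*% par$W
  Y <- Y + rep(par$b, each = nrow(Y))
  out <- permute34Cpp(Y, c(Ho, Wo, d[4L], ncol(par$W)))
  list(out = out, cache = list(P = P, inDim = d, Ho = Ho, Wo = Wo,
                               k = k, stride = stride, pad = pad))
}

convBwd <- function(par, cache, dy) {
  d <- cache$inDim
  Ho <- cache$Ho; Wo <- cache$Wo
  dY <- permute34Cpp(dy, dim(dy))   # (Ho, Wo, N, F)
  dim(dY) <- c(Ho * Wo * d[4L], ncol(par$W))
  dW <- crossprod(cache$P, dY)
  db <- .colSums(dY, nrow(dY), ncol(dY))
  dP <- tcrossprod(dY, par$W)
  dx <- col2imCpp(dP, d, cache$k, cache$stride, cache$pad)
  list(dx = dx, grads = list(W = dW, b = db))
}

# ----------------------------------------------------- depthwise convolution

dwInit <- function(k, c) {
  list(W = matrix(stats::rnorm(k * k * c, sd = sqrt(2 / (k * k))), k * k, c),
       b = numeric(c))
}

dwFwd <- function(par, x, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  list(out = dwConvFwdCpp(x, dim(x), par$W, par$b, k, stride, pad),
       cache = list(x = x, inDim = dim(x), k = k, stride = stride, pad = pad))
}

dwBwd <- function(par, cache, dy) {
  r <- dwConvBwdCpp(cache$x, cache$inDim, dy, par$W, cache$k, cache$stride,
                    cache$pad)
  list(dx = r$dx, grads = list(W = r$dW, b = r$db))
}

# ------------------------------------------------------------ batch norm

bnInit <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c),
       runMean = numeric(c), runVar = rep(1, c))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# Per-channel statistics are reduced with .colSums over the natural
# (H*W, C*N) view, so no aperm/copy of the activation tensor is needed.
bnFwd <- function(par, x, training) {
  d <- dim(x)
  HW <- d[1L] * d[2L]
  n <- HW * d[4L]
  if (training) {
    mu <- sumHWN(x) / n
    v <- sumHWN(x * x) / n - mu * mu
    v[v < 0] <- 0
    newState <- list(
      runMean = (1 - BN_MOMENTUM) * par$runMean + BN_MOMENTUM * mu,
      runVar = (1 - BN_MOMENTUM) * par$runVar + BN_MOMENTUM * v)
  } else {
    mu <- par$runMean
    v <- par$runVar
    newState <- NULL
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  scl <- par$gamma * invstd
  y <- x * rep(scl, each = HW) + rep(par$beta - mu * scl, each = HW)
  list(out = y,
       cache = list(x = x, mu = mu, invstd = invstd, n = n, HW = HW,
                    training = training),
       state = newState)
}

bnBwd <- function(par, cache, dy) {
  HW <- cache$HW
  n <- cache$n
  xhat <- (cache$x - rep(cache$mu, each = HW)) * rep(cache$invstd, each = HW)
  dgamma <- sumHWN(dy * xhat)
  dbeta <- sumHWN(dy)
  scl <- par$gamma * cache$invstd
  dx <- if (cache$training) {
    rep(scl, each = HW) *
      (dy - rep(dbeta / n, each = HW) - xhat * rep(dgamma / n, each = HW))
  } else {
    dy * rep(scl, each = HW)
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

# ------------------------------------------------------------ dense / pooling

denseInit <- function(din, dout) {
  list(W = matrix(stats::rnorm(din * dout, sd = sqrt(2 / din)), din, dout),
       b = numeric(dout))
}

denseFwd <- function(par, x) {
  y <- x %*% par$W
  y <- y + rep(par$b, each = nrow(y))
  list(out = y, cache = x)
}

denseBwd <- function(par, cache, dy) {
  list(dx = tcrossprod(dy, par$W),
       grads = list(W = crossprod(cache, dy), b = colSums(dy)))
}

gapFwd <- function(x) {
  d <- dim(x)
  list(out = sumHW(x) / (d[1L] * d[2L]), cache = d)
}

gapBwd <- function(cache, dy) {
  d <- cache
  array(rep(as.vector(t(dy)), each = d[1L] * d[2L]) / (d[1L] * d[2L]), d)
}

# --------------------------------------------------- squeeze-excite attention

seInit <- function(c, hidden) {
  list(W1 = matrix(stats::rnorm(c * hidden, sd = sqrt(2 / c)), c, hidden),
       b1 = numeric(hidden),
       W2 = matrix(stats::rnorm(hidden * c, sd = sqrt(2 / hidden)), hidden, c),
       b2 = numeric(c))
}

# SE-style channel gating: pooled descriptor -> reduce -> ReLU -> expand ->
# gate in (0,1) -> broadcast elementwise product. gate is "sigmoid" for the
# attention blocks of the feature pyramid and "hsigmoid" inside bneck blocks.
seFwd <- function(par, x, gate = "sigmoid") {
  g0 <- gapFwd(x)
  s <- g0$out                               # (N, C)
  h <- s %*% par$W1 + rep(par$b1, each = nrow(s))
  hr <- actFwd("relu", h)$out
  z <- hr %*% par$W2 + rep(par$b2, each = nrow(s))
  gv <- actFwd(gate, z)$out                 # (N, C) in (0, 1)
  list(out = scaleByChannel(x, gv),
       cache = list(x = x, s = s, h = h, hr = hr, z = z, gv = gv,
                    gapDim = g0$cache, gate = gate))
}

seBwd <- function(par, cache, dy) {
  gate <- cache$gate
  dgv <- sumHW(dy * cache$x)
  dx <- scaleByChannel(dy, cache$gv)
  gcache <- if (gate == "sigmoid") cache$gv else cache$z
  dz <- dgv * actDeriv(gate, gcache)
  dW2 <- crossprod(cache$hr, dz)
  db2 <- colSums(dz)
  dhr <- tcrossprod(dz, par$W2)
  dh <- dhr * (cache$h > 0)
  dW1 <- crossprod(cache$s, dh)
  db1 <- colSums(dh)
  ds <- tcrossprod(dh, par$W1)
  dx <- dx + gapBwd(cache$gapDim, ds)
  list(dx = dx, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

# --------------------------------------------------------------- upsampling

# 1-D linear interpolation matrix, scale factor 2, half-pixel centers
interpMatrix <- function(nin) {
  nout <- 2L * nin
  A <- matrix(0, nout, nin)
  for (i in seq_len(nout)) {
    src <- (i - 0.5) / 2 - 0.5
    i0 <- floor(src)
    w <- src - i0
    i0c <- min(max(i0, 0), nin - 1L)
    i1c <- min(max(i0 + 1L, 0), nin - 1L)
    A[i, i0c + 1L] <- A[i, i0c + 1L] + (1 - w)
    A[i, i1c + 1L] <- A[i, i1c + 1L] + w
  }
  A
}

applyRows <- function(A, x) {
  d <- dim(x)
  y <- A %*% matrix(x, d[1L], prod(d[-1L]))
  array(y, c(nrow(A), d[-1L]))
}

upFwd <- function(x, mode = c("bilinear", "nearest")) {
  mode <- match.arg(mode)
  d <- dim(x)
  if (mode == "nearest") {
    out <- x[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), , ,
             drop = FALSE]
    return(list(out = out, cache = list(mode = mode, d = d)))
  }
  Ah <- interpMatrix(d[1L])
  Aw <- interpMatrix(d[2L])
  y <- applyRows(Ah, x)
  y <- aperm(applyRows(Aw, aperm(y, c(2L, 1L, 3L, 4L))), c(2L, 1L, 3L, 4L))
  list(out = y, cache = list(mode = mode, d = d, Ah = Ah, Aw = Aw))
}

upBwd <- function(cache, dy) {
  d <- cache$d
  if (cache$mode == "nearest") {
    dx <- array(0, d)
    for (oy in 0:1) {
      for (ox in 0:1) {
        dx <- dx + dy[seq.int(1L + oy, by = 2L, length.out = d[1L]),
                      seq.int(1L + ox, by = 2L, length.out = d[2L]), , ,
                      drop = FALSE]
      }
    }
    return(dx)
  }
  g <- applyRows(t(cache$Ah), dy)
  aperm(applyRows(t(cache$Aw), aperm(g, c(2L, 1L, 3L, 4L))), c(2L, 1L, 3L, 4L))
}

# ------------------------------------------------------------ concat / misc

concatC <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1L], da[2L], da[3L] + db[3L], da[4L]))
  out[, , seq_len(da[3L]), ] <- a
  out[, , da[3L] + seq_len(db[3L]), ] <- b
  out
}

splitC <- function(dy, c1) {
  d <- dim(dy)
  list(dy[, , seq_len(c1), , drop = FALSE],
       dy[, , (c1 + 1L):d[3L], , drop = FALSE])
}

dropoutFwd <- function(x, p, training) {
  if (!training || p <= 0) return(list(out = x, cache = NULL))
  mask <- (stats::runif(length(x)) >= p) / (1 - p)
  list(out = x * mask, cache = mask)
}

dropoutBwd <- function(cache, dy) if (is.null(cache)) dy else dy * cache

# softmax cross-entropy over logits (N, K); labels are 0-based integers
softmaxProbs <- function(logits) {
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

softmaxCE <- function(logits, labels) {
  P <- softmaxProbs(logits)
  n <- nrow(P)
  idx <- cbind(seq_len(n), labels + 1L)
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  dlogits <- P
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n, probs = P)
}

# ------------------------------------------------------------- Adam optimizer

adamInitState <- function(params) {
  if (is.list(params)) return(lapply(params, adamInitState))
  list(m = params * 0, v = params * 0)
}

BN_STATE_NAMES <- c("runMean", "runVar")

adamStep <- function(params, grads, state, lr, t, weightDecay = 0,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.list(params) && is.null(params$m)) {
    for (nm in names(params)) {
      if (nm %in% BN_STATE_NAMES || is.null(grads[[nm]])) next
      r <- adamStep(params[[nm]], grads[[nm]], state[[nm]], lr, t,
                    weightDecay, beta1, beta2, eps)
      params[[nm]] <- r$params
      state[[nm]] <- r$state
    }
    return(list(params = params, state = state))
  }
  if (is.list(params)) stop("adamStep: malformed parameter tree")
  m <- beta1 * state$m + (1 - beta1) * grads
  v <- beta2 * state$v + (1 - beta2) * grads * grads
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  params <- params - lr * (mhat / (sqrt(vhat) + eps) + weightDecay * params)
  list(params = params, state = list(m = m, v = v))
}

# SGD with momentum (alternative optimizer)
sgdStep <- function(params, grads, state, lr, momentum = 0.9, weightDecay = 0) {
  if (is.list(params) && is.null(params$m)) {
    for (nm in names(params)) {
      if (nm %in% BN_STATE_NAMES || is.null(grads[[nm]])) next
      r <- sgdStep(params[[nm]], grads[[nm]], state[[nm]], lr, momentum,
                   weightDecay)
      params[[nm]] <- r$params
      state[[nm]] <- r$state
    }
    return(list(params = params, state = state))
  }
  m <- momentum * state$m + grads + weightDecay * params
  params <- params - lr * m
  list(params = params, state = list(m = m, v = state$v))
}

# recursively add L2 gradient contribution (decay handled inside steps instead)
countParams <- function(params) {
  if (is.list(params)) {
    nm <- names(params)
    keep <- if (is.null(nm)) seq_along(params) else which(!nm %in% BN_STATE_NAMES)
    return(sum(vapply(params[keep], countParams, numeric(1))))
  }
  length(params)
}
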
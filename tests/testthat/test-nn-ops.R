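# Finite-difference verification of every reverse-mode primitive, plus the
# shape/identity contracts the layer library guarantees.

test_that("convolution forward/backward match finite differences", {
  set.seed(1)
  x <- array(rnorm(5 * 6 * 3 * 2), c(5, 6, 3, 2))
  for (cfg in list(list(k = 3L, s = 1L), list(k = 3L, s = 2L),
                   list(k = 1L, s = 1L))) {
    par <- PDFuseNet:::convInit(cfg$k, 3L, 4L)
    fw <- PDFuseNet:::convFwd(par, x, cfg$k, stride = cfg$s)
    dy <- cos(fw$out)
    bw <- PDFuseNet:::convBwd(par, fw$cache, dy)
    f <- function(xx) sum(sin(PDFuseNet:::convFwd(par, xx, cfg$k,
                                                  stride = cfg$s)$out))
    expect_lt(relErr(bw$dx, numGrad(f, x)), 1e-6)
    fW <- function(w) {
      p <- par; p$W <- w
      sum(sin(PDFuseNet:::convFwd(p, x, cfg$k, stride = cfg$s)$out))
    }
    expect_lt(relErr(bw$grads$W, numGrad(fW, par$W)), 1e-6)
    fb <- function(b) {
      p <- par; p$b <- b
      sum(sin(PDFuseNet:::convFwd(p, x, cfg$k, stride = cfg$s)$out))
    }
    expect_lt(relErr(bw$grads$b, numGrad(fb, par$b)), 1e-6)
  }
})

test_that("depthwise convolution matches finite differences for k = 3 and 5", {
  set.seed(2)
  x <- array(rnorm(6 * 7 * 3 * 2), c(6, 7, 3, 2))
  for (cfg in list(list(k = 3L, s = 1L), list(k = 3L, s = 2L),
                   list(k = 5L, s = 1L))) {
    par <- PDFuseNet:::dwInit(cfg$k, 3L)
    fw <- PDFuseNet:::dwFwd(par, x, cfg$k, stride = cfg$s)
    dy <- cos(fw$out)
    bw <- PDFuseNet:::dwBwd(par, fw$cache, dy)
    f <- function(xx) sum(sin(PDFuseNet:::dwFwd(par, xx, cfg$k,
                                                stride = cfg$s)$out))
    expect_lt(relErr(bw$dx, numGrad(f, x)), 1e-6)
    fW <- function(w) {
      p <- par; p$W <- w
      sum(sin(PDFuseNet:::dwFwd(p, x, cfg$k, stride = cfg$s)$out))
    }
    expect_lt(relErr(bw$grads$W, numGrad(fW, par$W)), 1e-6)
  }
})

test_that("batch norm, squeeze-excite, dense and upsampling backprop", {
  set.seed(3)
  x <- array(rnorm(5 * 6 * 4 * 3), c(5, 6, 4, 3))
  pbn <- PDFuseNet:::bnInit(4L)
  pbn$gamma <- runif(4, 0.5, 1.5); pbn$beta <- rnorm(4)
  fw <- PDFuseNet:::bnFwd(pbn, x, TRUE)
  bw <- PDFuseNet:::bnBwd(pbn, fw$cache, cos(fw$out))
  expect_lt(relErr(bw$dx, numGrad(function(xx)
    sum(sin(PDFuseNet:::bnFwd(pbn, xx, TRUE)$out)), x)), 1e-5)
  expect_lt(relErr(bw$grads$gamma, numGrad(function(g) {
    p <- pbn; p$gamma <- g
    sum(sin(PDFuseNet:::bnFwd(p, x, TRUE)$out))
  }, pbn$gamma)), 1e-6)

  for (gate in c("sigmoid", "hsigmoid")) {
    pse <- PDFuseNet:::seInit(4L, 2L)
    fw <- PDFuseNet:::seFwd(pse, x, gate)
    bw <- PDFuseNet:::seBwd(pse, fw$cache, cos(fw$out))
    expect_lt(relErr(bw$dx, numGrad(function(xx)
      sum(sin(PDFuseNet:::seFwd(pse, xx, gate)$out)), x)), 1e-5)
    for (nm in c("W1", "W2", "b1", "b2")) {
      expect_lt(relErr(bw$grads[[nm]], numGrad(function(w) {
        p <- pse; p[[nm]] <- w
        sum(sin(PDFuseNet:::seFwd(p, x, gate)$out))
      }, pse[[nm]])), 1e-5)
    }
  }

  pd <- PDFuseNet:::denseInit(4L, 3L)
  xm <- matrix(rnorm(8), 2, 4)
  fw <- PDFuseNet:::denseFwd(pd, xm)
  bw <- PDFuseNet:::denseBwd(pd, fw$cache, cos(fw$out))
  expect_lt(relErr(bw$grads$W, numGrad(function(w) {
    p <- pd; p$W <- w
    sum(sin(PDFuseNet:::denseFwd(p, xm)$out))
  }, pd$W)), 1e-6)

  for (mode in c("nearest", "bilinear")) {
    x3 <- array(rnorm(4 * 6 * 2 * 2), c(4, 6, 2, 2))
    fw <- PDFuseNet:::upFwd(x3, mode)
    expect_identical(dim(fw$out), c(8L, 12L, 2L, 2L))
    dx <- PDFuseNet:::upBwd(fw$cache, cos(fw$out))
    expect_lt(relErr(dx, numGrad(function(xx)
      sum(sin(PDFuseNet:::upFwd(xx, mode)$out)), x3)), 1e-6)
  }
})

test_that("softmax cross-entropy gradients and probabilities are exact", {
  set.seed(4)
  logits <- matrix(rnorm(12), 4, 3)
  labs <- c(0L, 2L, 1L, 0L)
  ce <- PDFuseNet:::softmaxCE(logits, labs)
  expect_equal(rowSums(ce$probs), rep(1, 4), tolerance = 1e-12)
  g <- numGrad(function(l) PDFuseNet:::softmaxCE(l, labs)$loss, logits)
  expect_lt(relErr(ce$dlogits, g), 1e-6)
})

test_that("Adam and SGD walk the parameter tree and skip BN running stats", {
  params <- list(a = list(W = matrix(1, 2, 2), b = c(0, 0)),
                 bn = list(gamma = c(1, 1), beta = c(0, 0),
                           runMean = c(5, 5), runVar = c(2, 2)))
  grads <- list(a = list(W = matrix(1, 2, 2), b = c(1, 1)),
                bn = list(gamma = c(1, 1), beta = c(1, 1)))
  st <- PDFuseNet:::adamInitState(params)
  r <- PDFuseNet:::adamStep(params, grads, st, lr = 0.1, t = 1L)
  expect_lt(r$params$a$W[1, 1], 1)
  expect_identical(r$params$bn$runMean, c(5, 5))
  expect_identical(r$params$bn$runVar, c(2, 2))
  r2 <- PDFuseNet:::sgdStep(params, grads, st, lr = 0.1)
  expect_equal(r2$params$a$W[1, 1], 0.9)
  expect_identical(r2$params$bn$runMean, c(5, 5))
})
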
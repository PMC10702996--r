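# The reduced-width configuration keeps these tests desk-fast while
# exercising exactly the same code paths as the full 32/64/128 network.
smallCfg <- pcfanConfig(stageChannels = c(8L, 16L, 32L),
                        resblocksPerStage = 1L, attentionReduction = 4L)

test_that("channel attention gates without amplifying", {
  set.seed(1)
  f <- array(rnorm(8 * 8 * 8 * 2), c(8, 8, 8, 2))
  out <- channelAttention(f, reduction = 4L, seed = 2L)
  expect_identical(dim(out), dim(f))
  expect_true(all(abs(out) <= abs(f) + 1e-12))
  expect_equal(channelAttention(f * 0, reduction = 4L, seed = 2L), f * 0)
  # zeroed weights force the gate to sigmoid(0) = 0.5 exactly
  pz <- list(W1 = matrix(0, 8, 2), b1 = numeric(2),
             W2 = matrix(0, 2, 8), b2 = numeric(8))
  expect_equal(channelAttention(f, params = pz), 0.5 * f, tolerance = 1e-14)
  expect_error(channelAttention(f, reduction = 3L), "divisible")
})

test_that("encoder produces the contracted pyramid shapes", {
  model <- pcfanInit(pcfanConfig(), seed = 1L)
  for (side in c(128L, 96L)) {
    pyr <- pcfanEncode(model, matrix(runif(side * side), side, side))
    expect_identical(dim(pyr$f1), c(side, side, 32L, 1L))
    expect_identical(dim(pyr$f2), c(side %/% 2L, side %/% 2L, 64L, 1L))
    expect_identical(dim(pyr$f3), c(side %/% 4L, side %/% 4L, 128L, 1L))
  }
  expect_error(pcfanEncode(model, matrix(0.5, 4, 4)), ">= 8")
  # deterministic for fixed weights and input
  m2 <- pcfanInit(pcfanConfig(), seed = 1L)
  x <- matrix(runif(32 * 32), 32, 32)
  expect_identical(pcfanEncode(model, x), pcfanEncode(m2, x))
})

test_that("pyramid fusion wiring has 4 attention blocks, 2 upsamples, 2 concats", {
  model <- pcfanInit(smallCfg, seed = 3L)
  expect_identical(pcfaAttentionBlockCount(model), 4L)
  x <- matrix(runif(16 * 16), 16, 16)
  pyr <- pcfanEncode(model, x)
  fused <- pcfanFuse(model, pyr)
  expect_identical(dim(fused), c(16L, 16L, 8L, 1L))
  # the forward cache records exactly two upsample and two concat nodes
  fw <- PDFuseNet:::pcfaFwdInternal(model$params$pcfa, pyr,
                                    model$config$upsampleMode)
  expect_identical(sum(grepl("^u", names(fw$cache))), 2L)
  expect_identical(sum(grepl("^a", names(fw$cache))), 3L + 1L) # a1,a2,a3,a23
  bad <- pyr; bad$f2 <- bad$f2[, , 1:4, , drop = FALSE]
  expect_error(pcfanFuse(model, bad), "pyramid")
})

test_that("reconstruction is a single sigmoid-bounded convolution", {
  model <- pcfanInit(smallCfg, seed = 4L)
  fused <- array(rnorm(16 * 16 * 8 * 2), c(16, 16, 8, 2))
  out <- pcfanReconstruct(model, fused)
  expect_identical(dim(out), c(16L, 16L, 1L, 2L))
  expect_true(all(out > 0 & out < 1))
  # zero weights and bias give the constant sigmoid(0) = 0.5 image
  mz <- model
  mz$params$recon$conv$W[] <- 0
  mz$params$recon$conv$b[] <- 0
  expect_equal(pcfanReconstruct(mz, fused),
               array(0.5, c(16, 16, 1, 2)), tolerance = 1e-14)
  expect_error(pcfanReconstruct(model, fused[, , 1:4, , drop = FALSE]),
               "stage-1")
})

test_that("MSE loss matches the naive loop and is symmetric", {
  set.seed(5)
  a <- array(runif(4 * 5 * 2 * 2), c(4, 5, 2, 2))
  b <- array(runif(4 * 5 * 2 * 2), c(4, 5, 2, 2))
  naive <- 0
  for (i in seq_along(a)) naive <- naive + (a[i] - b[i])^2
  expect_lt(abs(mseLoss(a, b) - naive / length(a)), 1e-12)
  expect_identical(mseLoss(a, b), mseLoss(b, a))
  expect_identical(mseLoss(a, a), 0)
  expect_equal(mseLoss(a, a + 0.1), 0.01, tolerance = 1e-12)
  expect_error(mseLoss(a, b[, 1:4, , , drop = FALSE]), "shapes")
})

test_that("full PCFAN loss gradients match finite differences", {
  set.seed(6)
  cfg <- pcfanConfig(stageChannels = c(4L, 8L, 16L), resblocksPerStage = 1L,
                     attentionReduction = 2L)
  model <- pcfanInit(cfg, seed = 7L)
  x <- array(runif(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  tgt <- array(runif(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  fw <- PDFuseNet:::pcfanForwardInternal(model, x)
  dout <- 2 * (fw$out - tgt) / length(tgt)
  grads <- PDFuseNet:::pcfanBackwardInternal(model, fw$cache, dout)$grads
  lossFor <- function(m) mseLoss(PDFuseNet:::pcfanForwardInternal(m, x)$out, tgt)
  checks <- list(
    list(g = grads$stage1$conv$W,
         get = function(m) m$params$stage1$conv$W,
         set = function(m, v) { m$params$stage1$conv$W <- v; m }),
    list(g = grads$stage2$res[[1]]$conv1$W,
         get = function(m) m$params$stage2$res[[1]]$conv1$W,
         set = function(m, v) { m$params$stage2$res[[1]]$conv1$W <- v; m }),
    list(g = grads$pcfa$ca1$W2,
         get = function(m) m$params$pcfa$ca1$W2,
         set = function(m, v) { m$params$pcfa$ca1$W2 <- v; m }),
    list(g = grads$pcfa$fuse$W,
         get = function(m) m$params$pcfa$fuse$W,
         set = function(m, v) { m$params$pcfa$fuse$W <- v; m }),
    list(g = grads$recon$conv$W,
         get = function(m) m$params$recon$conv$W,
         set = function(m, v) { m$params$recon$conv$W <- v; m }))
  eps <- 1e-5
  for (ck in checks) {
    p <- ck$get(model)
    idx <- which.max(abs(ck$g))
    p[idx] <- p[idx] + eps
    lp <- lossFor(ck$set(model, p))
    p[idx] <- p[idx] - 2 * eps
    lm <- lossFor(ck$set(model, p))
    num <- (lp - lm) / (2 * eps)
    expect_lt(abs(ck$g[idx] - num), 1e-6 + 1e-3 * abs(num))
  }
})

test_that("self-supervised pretraining reduces reconstruction error", {
  imgs <- phantomStack(6L, imageSize = 32L, seed = 8L)$images
  pre <- pretrainPCFAN(imgs, smallCfg, epochs = 4L, lr = 2e-3,
                       batchSize = 6L, seed = 9L)
  final <- pre$history$loss[nrow(pre$history)]
  expect_lt(final, pre$initialLoss)
  # determinism
  pre2 <- pretrainPCFAN(imgs, smallCfg, epochs = 4L, lr = 2e-3,
                        batchSize = 6L, seed = 9L)
  expect_identical(pre$history, pre2$history)
  # zero learning rate leaves the loss curve flat
  pre0 <- pretrainPCFAN(imgs, smallCfg, epochs = 3L, lr = 0,
                        batchSize = 6L, seed = 9L)
  expect_identical(length(unique(pre0$history$loss)), 1L)
  expect_equal(pre0$history$loss[1], pre0$initialLoss, tolerance = 1e-12)
  expect_error(pretrainPCFAN(list(), smallCfg), "empty")
  expect_error(pretrainPCFAN(imgs[1:3], smallCfg), ">= 8")
})
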
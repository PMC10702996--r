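test_that("hard-swish matches its closed form and asymptotics", {
  expect_equal(hSwish(c(-5, -3, 0, 3)), c(0, 0, 0, 3))
  expect_equal(hSwish(10), 10)
  # continuity, and monotonicity from the stationary point x = -3/2 on
  # (x * (x + 3) / 6 dips to its minimum -0.375 at -1.5)
  xs <- seq(-3, 6, by = 0.01)
  ys <- hSwish(xs)
  expect_lt(max(abs(diff(ys))), 0.02) # no jumps
  xs2 <- seq(-1.5, 6, by = 0.01)
  expect_true(all(diff(hSwish(xs2)) >= -1e-12))
  expect_equal(min(ys), -0.375)
  expect_lt(abs(hSwish(100) / 100 - 1), 1e-2)
  # piecewise definition x * relu6(x + 3) / 6 checked against direct eval
  xs <- seq(-6, 6, by = 0.25)
  expect_equal(hSwish(xs), xs * pmin(pmax(xs + 3, 0), 6) / 6)
})

test_that("bneck respects the skip/identity and stride contracts", {
  spec <- bneckSpec(8L, 16L, 8L, 3L, 1L, TRUE, "relu")
  par <- PDFuseNet:::bneckInit(spec)
  # zero all weights/biases: projection emits 0, skip restores the input
  zeroTree <- function(p) rapply(p, function(v) v * 0, how = "replace")
  pz <- zeroTree(par)
  pz$bn1[c("gamma")] <- list(rep(1, 16))
  pz$bn2[c("gamma")] <- list(rep(1, 16))
  pz$bn3[c("gamma")] <- list(rep(1, 8))
  pz$bn1$runVar <- rep(1, 16); pz$bn2$runVar <- rep(1, 16)
  pz$bn3$runVar <- rep(1, 8)
  x <- array(runif(8 * 8 * 8 * 2), c(8, 8, 8, 2))
  out <- PDFuseNet:::bneckFwd(pz, spec, x, training = FALSE)$out
  expect_equal(out, x, tolerance = 1e-12)
  # stride-2 halves the spatial dims
  s2 <- bneckSpec(8L, 16L, 12L, 3L, 2L, FALSE, "hswish")
  p2 <- PDFuseNet:::bneckInit(s2)
  x2 <- array(runif(32 * 32 * 8 * 2), c(32, 32, 8, 2))
  expect_identical(dim(PDFuseNet:::bneckFwd(p2, s2, x2, TRUE)$out),
                   c(16L, 16L, 12L, 2L))
  expect_error(bneckSpec(8L, 16L, 8L, 4L), "kernel")
})

test_that("bneck parameter count matches the symbolic closed form", {
  spec <- bneckSpec(16L, 48L, 24L, 5L, 1L, TRUE, "hswish")
  par <- PDFuseNet:::bneckInit(spec)
  Cin <- 16; E <- 48; Cout <- 24; k <- 5
  expected <- (Cin * E + E) +          # expand conv + bias
    (k * k * E + E) +                  # depthwise + bias
    (E * (E / 4) + E / 4 + (E / 4) * E + E) + # SE reduce/expand + biases
    (E * Cout + Cout) +                # linear projection + bias
    2 * E + 2 * E + 2 * Cout           # BN gamma/beta per stage
  expect_identical(as.integer(PDFuseNet:::countParams(par)),
                   as.integer(expected))
})

test_that("width scaling, softmax head and prediction contracts hold", {
  m25 <- buildMobileNetV3(modelConfig(widthMultiplier = 0.25), seed = 1L)
  m50 <- buildMobileNetV3(modelConfig(widthMultiplier = 0.5), seed = 1L)
  m100 <- buildMobileNetV3(modelConfig(widthMultiplier = 1), seed = 1L)
  expect_lt(nParams(m25), nParams(m50))
  expect_lt(nParams(m50), nParams(m100))
  # all scaled channel widths are multiples of 8 with floor 8
  widths <- unlist(lapply(m50$arch$specs, function(s)
    c(s$inCh, s$expandCh, s$outCh)))
  expect_true(all(widths %% 8L == 0L & widths >= 8L))

  imgs <- lapply(1:4, function(i) matrix(runif(64 * 64), 64, 64))
  pr <- predictClasses(m25, imgs)
  expect_identical(dim(pr$probs), c(4L, 3L))
  expect_equal(rowSums(pr$probs), rep(1, 4), tolerance = 1e-6)
  expect_true(all(pr$labels %in% 0:2))
  expect_identical(pr$labels, max.col(pr$probs, ties.method = "first") - 1L)
  # zero-weight head gives exactly uniform class probabilities
  mz <- m25
  mz$params$head$fc$W[] <- 0
  mz$params$head$fc$b[] <- 0
  przz <- predictClasses(mz, imgs)
  expect_equal(przz$probs, matrix(1 / 3, 4, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  # forward pass on 128x128 yields (batch, 3)
  big <- lapply(1:2, function(i) matrix(runif(128 * 128), 128, 128))
  expect_identical(dim(predictClasses(m50, big)$probs), c(2L, 3L))
})

test_that("classifier training learns, reproduces, and freezes at lr 0", {
  st <- phantomStack(4L, imageSize = 32L, seed = 10L)
  m <- buildMobileNetV3(modelConfig(widthMultiplier = 0.25, dropout = 0),
                        seed = 2L)
  hyper <- list(lr = 2e-3, epochs = 6L, batchSize = 12L)
  tr <- trainClassifier(m, st$images, st$labels, hyper = hyper, seed = 3L)
  expect_gt(tr$history$trainAcc[6], tr$history$trainAcc[1] - 1e-12)
  expect_lt(tr$history$trainLoss[6], tr$history$trainLoss[1])
  tr2 <- trainClassifier(m, st$images, st$labels, hyper = hyper, seed = 3L)
  expect_identical(tr$history, tr2$history)
  # lr = 0 with full-batch, dropout-free setup: perfectly constant history
  tr0 <- trainClassifier(m, st$images, st$labels,
                         hyper = list(lr = 0, epochs = 4L, batchSize = 12L),
                         seed = 3L)
  expect_identical(length(unique(tr0$history$trainAcc)), 1L)
  expect_lt(diff(range(tr0$history$trainLoss)), 1e-12)
  expect_error(trainClassifier(m, st$images[1:4], rep(0L, 4)), "single class")
})

test_that("default model overfits a dozen phantoms to 100% train accuracy", {
  st <- phantomStack(4L, imageSize = 64L, seed = 20L)
  m <- buildMobileNetV3(modelConfig(dropout = 0), seed = 5L)
  # 150 full-batch steps (within the 200-step capacity budget)
  tr <- trainClassifier(m, st$images, st$labels,
                        hyper = list(lr = 2e-3, epochs = 150L,
                                     batchSize = 12L), seed = 6L)
  expect_identical(max(tr$history$trainAcc), 1)
})
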
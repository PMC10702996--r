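test_that("brightness transform matches its closed form and edge cases", {
  img <- matrix(runif(64, 0, 1), 8, 8)
  expect_equal(btf(img, 1), img, tolerance = 1e-14)
  z <- matrix(0, 4, 4)
  expect_equal(btf(z, 3), z)
  # scalar spot value from direct high-precision evaluation of the form
  a <- 0.3293; b <- 1.158
  g <- k <- NULL
  k <- 2
  gamma <- k^a; beta <- exp(b * (1 - gamma))
  expect_equal(btf(matrix(0.5, 1, 1), 2)[1, 1],
               min(1, beta * 0.5^gamma), tolerance = 1e-12)
  expect_error(btf(img, 0), "positive")
  expect_error(btf(img, -1), "positive")
  bad <- img; bad[1, 1] <- NaN
  expect_error(btf(bad, 2), "NA")
})

test_that("illumination weight is bounded and tracks exposure", {
  cfg <- fusionConfig()
  expect_equal(illuminationWeight(matrix(1, 16, 16), cfg),
               matrix(1, 16, 16), tolerance = 1e-12)
  expect_equal(illuminationWeight(matrix(0, 16, 16), cfg),
               matrix(0, 16, 16), tolerance = 1e-12)
  # half-dark / half-bright: weight low on the dark side, high on the
  # bright side, monotone non-decreasing across the smoothed boundary
  img <- cbind(matrix(0, 32, 16), matrix(1, 32, 16))
  W <- illuminationWeight(img, cfg)
  expect_true(all(W >= 0 & W <= 1))
  expect_lt(mean(W[, 1:8]), 0.25)
  expect_gt(mean(W[, 25:32]), 0.8)
  rowProfile <- W[16, ]
  expect_true(all(diff(rowProfile) >= -1e-12))
})

test_that("exposure-ratio search honors its fallback, tie-break and oracle", {
  cfg <- fusionConfig()
  bright <- matrix(0.9, 16, 16)
  expect_equal(findExposureRatio(bright, illuminationWeight(bright, cfg), cfg), 1)
  # constant dark image: entropy flat in k, tie broken to the lower bound
  dark <- matrix(0.05, 16, 16)
  expect_equal(findExposureRatio(dark, illuminationWeight(dark, cfg), cfg),
               cfg@kRange[1])
  # dark two-level image against an exhaustive fine-grid scan
  img <- matrix(rep(c(0.05, 0.15), each = 128), 16, 16)
  W <- illuminationWeight(img, cfg)
  k <- findExposureRatio(img, W, cfg)
  Q <- img[W < 0.5]
  entOf <- function(kk) {
    v <- btf(matrix(Q, ncol = 1), kk, cfg)
    cnt <- tabulate(pmin(floor(v * 256), 255) + 1L, 256L)
    p <- cnt[cnt > 0] / length(v)
    -sum(p * log2(p))
  }
  grid <- seq(1, 8, by = 1e-4)
  eg <- vapply(grid, entOf, numeric(1))
  kBrute <- grid[which.max(eg)]
  expect_lt(abs(k - kBrute), 2e-3)
  expect_error(findExposureRatio(matrix(numeric(0), 0, 0), matrix(numeric(0), 0, 0), cfg),
               "empty")
})

test_that("enhancement composes the weighted blend identity", {
  cfg <- fusionConfig()
  bright <- matrix(1, 16, 16)
  r <- enhance(bright, cfg)
  expect_equal(enhancedImage(r), bright, tolerance = 1e-12)
  # phantom case: the combination identity holds to 1e-10 (also enforced
  # by the class validity) and output stays in range
  img <- generatePhantom(phantomSpec(0L, imageSize = 64L, seed = 7L))
  r <- enhance(img, cfg)
  recon <- weightMap(r) * img + (1 - weightMap(r)) * syntheticExposure(r)
  expect_lt(max(abs(recon - enhancedImage(r))), 1e-10)
  expect_gte(min(enhancedImage(r)), 0)
  expect_lte(max(enhancedImage(r)), 1)
  # mean intensity does not decrease (k >= 1 regime)
  expect_gte(mean(enhancedImage(r)), mean(img) - 1e-12)
})

test_that("mean filter equals the naive reflect-padded box mean", {
  expect_equal(meanFilter(matrix(0.4, 10, 10), 3L), matrix(0.4, 10, 10),
               tolerance = 1e-14)
  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  mf <- meanFilter(imp, 3L)
  expect_equal(mf[4:6, 4:6], matrix(1 / 9, 3, 3), tolerance = 1e-14)
  expect_equal(sum(mf), 1, tolerance = 1e-12)
  set.seed(42)
  img <- matrix(runif(256), 16, 16)
  for (w in c(3L, 5L)) {
    expect_lt(max(abs(meanFilter(img, w) - naiveMeanFilter(img, w))), 1e-12)
  }
  expect_error(meanFilter(img, 4L), "odd")
})

test_that("MSMG matches the per-scale naive oracle and its weights", {
  expect_equal(msmgWeights(3L), c(1 / 3, 1 / 5, 1 / 7))
  cfg <- fusionConfig()
  expect_equal(gradientValues(msmg(matrix(0.7, 12, 12), cfg)),
               matrix(0, 12, 12))
  # single-step edge at one scale: support = within one SE radius of the
  # edge, magnitude = step height * w_1
  edge <- cbind(matrix(0, 8, 4), matrix(0.6, 8, 4))
  g1 <- gradientValues(msmg(edge, fusionConfig(msmgScales = 1L)))
  expect_equal(g1[, 4:5], matrix(0.6 / 3, 8, 2), tolerance = 1e-12)
  expect_equal(g1[, c(1:3, 6:8)], matrix(0, 8, 6), tolerance = 1e-12)
  set.seed(7)
  img <- matrix(runif(256), 16, 16)
  for (N in 1:3) {
    m <- gradientValues(msmg(img, fusionConfig(msmgScales = as.integer(N))))
    expect_lt(max(abs(m - naiveMSMG(img, N))), 1e-12)
    expect_gte(min(m), 0)
  }
})

test_that("fusion blend selects sharp content and respects symmetry", {
  cfg <- fusionConfig()
  img <- generatePhantom(phantomSpec(1L, imageSize = 64L, seed = 9L))
  expect_equal(fuseImages(img, img, cfg), img, tolerance = 1e-12,
               ignore_attr = TRUE)
  hard <- fusionConfig(blendMode = "hard")
  blur <- meanFilter(meanFilter(img, 5L), 5L)
  # the sharp image dominates the blurred one almost everywhere; ties go
  # to the first input, so fusing (img, blur) must return img wherever the
  # gradients differ
  f <- fuseImages(img, blur, hard)
  expect_true(all(f == img | f == blur))
  # soft blend is symmetric: swapping inputs flips rho to 1 - rho
  s1 <- fuseImages(img, blur, cfg)
  s2 <- fuseImages(blur, img, cfg)
  expect_equal(s1, s2, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(fuseImages(img, blur[1:32, 1:32], cfg), "shape")
})

test_that("split-focus fusion recovers the all-sharp composite", {
  # one copy sharp on the left/blurred right, the other the reverse;
  # hard-mode fusion must recover the all-sharp composite nearly
  # everywhere. The scene carries fine-grained speckle detail — the
  # multi-focus setting the MSMG focus measure is built for.
  set.seed(21)
  base <- generatePhantom(phantomSpec(2L, imageSize = 64L, seed = 21L,
                                      noiseSigma = 0, textureSigma = 0))
  sharp <- PDFuseNet:::clip01(0.7 * base + 0.3 * matrix(runif(64 * 64), 64, 64))
  blurred <- meanFilter(meanFilter(sharp, 5L), 5L)
  left <- cbind(sharp[, 1:32], blurred[, 33:64])
  right <- cbind(blurred[, 1:32], sharp[, 33:64])
  fused <- fuseImages(left, right, fusionConfig(blendMode = "hard"))
  interior <- 5:60
  agree <- mean(abs(fused[interior, interior] - sharp[interior, interior]) < 1e-9)
  expect_gte(agree, 0.95)
})

test_that("preprocessing pipeline keeps outputs in range", {
  img <- generatePhantom(phantomSpec(0L, imageSize = 64L, seed = 2L))
  out <- preprocessImage(img)
  expect_identical(dim(out$fused), dim(img))
  expect_gte(min(out$fused), 0)
  expect_lte(max(out$fused), 1)
  expect_gte(out$k, 1)
  alt <- preprocessImage(img, fusionConfig(fusePartner = "original"))
  expect_identical(dim(alt$fused), dim(img))
})
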
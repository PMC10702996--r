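# Shared brute-force oracles and numerical helpers. Each oracle is an
# independent, naive re-computation of the quantity it checks and is never
# shared with the implementation path.

relErr <- function(a, b) {
  max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))
}

# central finite differences of a scalar function at x (array or vector)
numGrad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# naive double-loop box mean with reflect padding
naiveMeanFilter <- function(img, window) {
  r <- (window - 1) %/% 2
  H <- nrow(img); W <- ncol(img)
  reflect <- function(i, n) {
    if (i < 1) 2 - i else if (i > n) 2 * n - i else i
  }
  out <- matrix(0, H, W)
  for (y in 1:H) {
    for (x in 1:W) {
      s <- 0
      for (dy in -r:r) {
        for (dx in -r:r) {
          s <- s + img[reflect(y + dy, H), reflect(x + dx, W)]
        }
      }
      out[y, x] <- s / (window * window)
    }
  }
  out
}

# naive grayscale morphology over in-bounds offsets of a logical SE matrix
naiveMorph <- function(img, se, type) {
  r <- (nrow(se) - 1) %/% 2
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (y in 1:H) {
    for (x in 1:W) {
      vals <- c()
      for (dy in -r:r) {
        for (dx in -r:r) {
          if (!se[dy + r + 1, dx + r + 1]) next
          yy <- y + dy; xx <- x + dx
          if (yy >= 1 && yy <= H && xx >= 1 && xx <= W) {
            vals <- c(vals, img[yy, xx])
          }
        }
      }
      out[y, x] <- if (type == "max") max(vals) else min(vals)
    }
  }
  out
}

# naive multi-scale morphological gradient with SE_t = base dilated (t-1)
# times; the SE masks themselves are taken from the implementation geometry
# (L1 balls), built here by direct distance test rather than dilation
naiveMSMG <- function(img, nScales) {
  M <- matrix(0, nrow(img), ncol(img))
  for (t in 1:nScales) {
    se <- outer(-t:t, -t:t, function(a, b) abs(a) + abs(b) <= t)
    G <- naiveMorph(img, se, "max") - naiveMorph(img, se, "min")
    M <- M + G / (2 * t + 1)
  }
  M
}

# Mann-Whitney pairwise AUC with half-credit ties
naiveAuc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# naive per-sample one-vs-rest confusion tally
naiveConfusion <- function(yt, yp, K) {
  out <- NULL
  for (k in 0:(K - 1)) {
    tp <- fp <- tn <- fn <- 0
    for (i in seq_along(yt)) {
      if (yt[i] == k && yp[i] == k) tp <- tp + 1
      if (yt[i] != k && yp[i] == k) fp <- fp + 1
      if (yt[i] != k && yp[i] != k) tn <- tn + 1
      if (yt[i] == k && yp[i] != k) fn <- fn + 1
    }
    out <- rbind(out, data.frame(class = k, tp = tp, fp = fp, tn = tn, fn = fn))
  }
  out
}

# small stack of phantom images for training-style tests
phantomStack <- function(nPerClass, imageSize = 32L, seed = 1L) {
  ds <- generateDataset(nPerClass, phantomSpec(0L, imageSize = imageSize),
                        splitFraction = 0.5, seed = seed)
  list(images = c(ds$train$images, ds$test$images),
       labels = c(ds$train$labels, ds$test$labels))
}
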
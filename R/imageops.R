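# Low-level grayscale image primitives shared by the phantom generator and
# the fusion stage: separable Gaussian smoothing with reflect padding, and
# flat grayscale morphology with explicit in-bounds border semantics (pixels
# outside the image never contribute to a max or min).

conv1dRows <- function(x, k) {
  H <- nrow(x); r <- (length(k) - 1L) %/% 2L
  xp <- padReflect(x, min(r, H - 1L, ncol(x) - 1L))
  # padReflect pads both dims; keep original columns
  off <- (nrow(xp) - H) %/% 2L
  coff <- (ncol(xp) - ncol(x)) %/% 2L
  xp <- xp[, (coff + 1L):(coff + ncol(x)), drop = FALSE]
  if (off < r) { # image smaller than kernel radius: renormalize the overlap
    k <- k[(r - off + 1L):(r + off + 1L)]
    k <- k / sum(k)
    r <- off
  }
  out <- matrix(0, H, ncol(x))
  for (o in seq_along(k)) {
    out <- out + k[o] * xp[o:(o + H - 1L), , drop = FALSE]
  }
  out
}

gaussianSmooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  t(conv1dRows(t(conv1dRows(x, k)), k))
}

# offsets of a flat structuring element given as a logical matrix with odd dims
seOffsets <- function(se) {
  r <- (nrow(se) - 1L) %/% 2L
  c0 <- (ncol(se) - 1L) %/% 2L
  idx <- which(se, arr.ind = TRUE)
  cbind(dy = idx[, 1L] - r - 1L, dx = idx[, 2L] - c0 - 1L)
}

# the 5-pixel discrete disk of radius 1 (city-block cross)
baseDisk <- function() {
  matrix(c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE), 3L, 3L)
}

# binary dilation of a structuring element by another (grows the SE support)
dilateSE <- function(se, by) {
  ra <- (nrow(se) - 1L) %/% 2L; rb <- (nrow(by) - 1L) %/% 2L
  r <- ra + rb
  out <- matrix(FALSE, 2L * r + 1L, 2L * r + 1L)
  offs <- seOffsets(by)
  for (i in seq_len(nrow(offs))) {
    rows <- (1L + rb + offs[i, 1L]):(2L * ra + 1L + rb + offs[i, 1L])
    cols <- (1L + rb + offs[i, 2L]):(2L * ra + 1L + rb + offs[i, 2L])
    out[rows, cols] <- out[rows, cols] | se
  }
  out
}

# grayscale dilation (type = "max") or erosion (type = "min") by a flat SE,
# taking the extremum over in-bounds neighbors only
grayMorph <- function(x, se, type = c("max", "min")) {
  type <- match.arg(type)
  pad <- if (type == "max") -Inf else Inf
  r <- (nrow(se) - 1L) %/% 2L
  H <- nrow(x); W <- ncol(x)
  xp <- padConst(x, r, pad)
  offs <- seOffsets(se)
  out <- matrix(pad, H, W)
  fun <- if (type == "max") pmax else pmin
  for (i in seq_len(nrow(offs))) {
    sl <- xp[(r + 1L + offs[i, 1L]):(r + H + offs[i, 1L]),
             (r + 1L + offs[i, 2L]):(r + W + offs[i, 2L]), drop = FALSE]
    out <- fun(out, sl)
  }
  out
}
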
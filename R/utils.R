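# Internal numeric helpers shared across modules.

# Round half away from zero (the convention used wherever grayscale becomes
# an integer); base round() rounds half to even.
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# 3-D FFT filtering with a separable Gaussian transfer function (periodic).
# sigma is in voxels, one value per axis.
gaussianSmooth3d <- function(x, sigma) {
  d <- dim(x)
  ft <- fft(x)
  for (ax in 1:3) {
    f <- c(0:(d[ax] %/% 2), -((d[ax] - d[ax] %/% 2 - 1):1)) / d[ax]
    g <- exp(-2 * pi^2 * sigma[ax]^2 * f^2)
    shape <- c(1L, 1L, 1L); shape[ax] <- d[ax]
    ft <- ft * array(rep(g, each = prod(d[seq_len(ax - 1L)])), dim = d)
  }
  Re(fft(ft, inverse = TRUE)) / prod(d)
}

# Zero-padded 3-D convolution of a (logical/numeric) array with a small
# kernel, via FFT. Returns an array of the same size as x.
convolve3d <- function(x, kernel) {
  dx <- dim(x); dk <- dim(kernel)
  dp <- dx + dk - 1L
  xp <- array(0, dp); xp[seq_len(dx[1]), seq_len(dx[2]), seq_len(dx[3])] <- x
  kp <- array(0, dp); kp[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- kernel
  full <- Re(fft(fft(xp) * fft(kp), inverse = TRUE)) / prod(dp)
  off <- (dk - 1L) %/% 2L
  full[off[1] + seq_len(dx[1]), off[2] + seq_len(dx[2]), off[3] + seq_len(dx[3])]
}

ballKernel <- function(radius) {
  r <- max(0L, as.integer(radius))
  g <- seq(-r, r)
  k <- outer(outer(g^2, g^2, "+"), g^2, "+") <= r^2 + 1e-9
  array(as.numeric(k), dim = rep(2L * r + 1L, 3L))
}

# Binary closing (dilation then erosion) with a ball structuring element.
# Dilation treats outside the volume as background; erosion counts only the
# in-bounds part of the kernel, so structures touching the volume faces are
# not eaten away.
binaryClose3d <- function(mask, radius) {
  if (radius <= 0) return(mask)
  k <- ballKernel(radius)
  dil <- convolve3d(mask, k) > 0.5
  avail <- convolve3d(array(1, dim(mask)), k)
  convolve3d(dil, k) > avail - 0.5
}

binaryDice <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}

# Largest 6-connected component of a logical 3-D array, by frontier growth.
largestComponent3d <- function(mask) {
  d <- dim(mask)
  n <- prod(d)
  idx <- which(mask)
  if (!length(idx)) stop("empty mask: no foreground voxels")
  remaining <- logical(n); remaining[idx] <- TRUE
  best <- NULL; bestSize <- 0L
  strides <- c(1L, d[1], d[1] * d[2])
  while (any(remaining)) {
    seedIdx <- which.max(remaining)
    comp <- logical(n)
    frontier <- seedIdx
    comp[frontier] <- TRUE
    while (length(frontier)) {
      fc <- arrayInd(frontier, d)
      nb <- integer(0)
      for (ax in 1:3) {
        ok <- fc[, ax] > 1L
        nb <- c(nb, frontier[ok] - strides[ax])
        ok <- fc[, ax] < d[ax]
        nb <- c(nb, frontier[ok] + strides[ax])
      }
      nb <- unique(nb)
      nb <- nb[remaining[nb] & !comp[nb]]
      comp[nb] <- TRUE
      frontier <- nb
    }
    size <- sum(comp)
    remaining[comp] <- FALSE
    if (size > bestSize) { bestSize <- size; best <- comp }
  }
  array(best, dim = d)
}

# Otsu threshold from a 256-bin histogram of values in [0, 255].
otsuThreshold <- function(values) {
  h <- as.numeric(tabulate(pmin(pmax(as.integer(roundHalfAway(values)), 0L),
                                255L) + 1L, nbins = 256L))
  total <- sum(h)
  if (total == 0) stop("no voxels to threshold")
  lv <- 0:255
  w0 <- cumsum(h)
  m0 <- cumsum(h * lv)
  mt <- m0[256]
  w1 <- total - w0
  between <- (mt * w0 - total * m0)^2 / (w0 * w1 * total^2)
  between[!is.finite(between)] <- -Inf
  lv[which.max(between)] + 0.5
}
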
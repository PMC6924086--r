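# Independent brute-force oracles. These deliberately re-derive each
# operation from its set-theoretic / summation definition with plain loops,
# sharing no code with the package internals.

# reflective (mirror, edge-inclusive) index into 1:n
.reflect_idx <- function(i, n) {
  while (i < 1L || i > n) {
    if (i < 1L) i <- 1L - i       # mirror about 0.5: 0 -> 1, -1 -> 2
    if (i > n) i <- 2L * n - i + 1L
  }
  i
}

# direct quadruple-loop 2D convolution with reflective borders
conv_oracle <- function(img, k) {
  nr <- nrow(img); nc <- ncol(img)
  kr <- nrow(k); kc <- ncol(k)
  mr <- (kr - 1L) %/% 2L; mc <- (kc - 1L) %/% 2L
  out <- matrix(0, nr, nc)
  for (y in 1:nr) for (x in 1:nc) {
    acc <- 0
    for (a in -mr:mr) for (b in -mc:mc) {
      h <- k[a + mr + 1L, b + mc + 1L]
      fy <- .reflect_idx(y - a, nr)
      fx <- .reflect_idx(x - b, nc)
      acc <- acc + h * img[fy, fx]
    }
    out[y, x] <- acc
  }
  out
}

# erosion by the set definition: d kept iff all d + b are foreground
erode_oracle <- function(mask, b) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  for (y in 1:nr) for (x in 1:nc) {
    keep <- TRUE
    for (i in seq_len(nrow(b))) {
      xx <- x + b[i, 1L]; yy <- y + b[i, 2L]
      if (xx < 1L || xx > nc || yy < 1L || yy > nr || mask[yy, xx] != 1L) {
        keep <- FALSE; break
      }
    }
    if (keep) out[y, x] <- 1L
  }
  out
}

# dilation by the set definition: mark x + b for every foreground x
dilate_oracle <- function(mask, b) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  for (y in 1:nr) for (x in 1:nc) {
    if (mask[y, x] != 1L) next
    for (i in seq_len(nrow(b))) {
      xx <- x + b[i, 1L]; yy <- y + b[i, 2L]
      if (xx >= 1L && xx <= nc && yy >= 1L && yy <= nr) out[yy, xx] <- 1L
    }
  }
  out
}

# sub-pixel phase correlation: standard cross-power-spectrum registration
# with parabolic peak interpolation; returns (dx, dy) such that
# f2 ~ f1 shifted by (dx, dy)
phase_corr_oracle <- function(f1, f2) {
  n1 <- nrow(f1); n2 <- ncol(f1)
  F1 <- stats::fft(f1 - mean(f1))
  F2 <- stats::fft(f2 - mean(f2))
  R <- F2 * Conj(F1)
  R <- R / pmax(Mod(R), .Machine$double.xmin)
  r <- Re(stats::fft(R, inverse = TRUE)) / (n1 * n2)
  pk <- arrayInd(which.max(r), dim(r))
  wrap <- function(i, n) ifelse(i - 1L > n / 2, i - 1L - n, i - 1L)
  sub <- function(m, i, n) {
    ip <- (i %% n) + 1L; im <- ((i - 2L) %% n) + 1L
    y0 <- m[im]; y1 <- m[i]; y2 <- m[ip]
    den <- y0 - 2 * y1 + y2
    if (den == 0) 0 else max(min(0.5 * (y0 - y2) / den, 0.5), -0.5)
  }
  dy <- wrap(pk[1L], n1) + sub(r[, pk[2L]], pk[1L], n1)
  dx <- wrap(pk[2L], n2) + sub(r[pk[1L], ], pk[2L], n2)
  c(dx = dx, dy = dy)
}

# draw a random 0/1 mask
random_mask <- function(nr, nc, p = 0.4) {
  matrix(as.integer(stats::runif(nr * nc) < p), nr, nc)
}

# a random structuring element containing the origin
random_se <- function(r = 2L, n_extra = 4L) {
  cand <- expand.grid(dx = -r:r, dy = -r:r)
  cand <- cand[!(cand$dx == 0 & cand$dy == 0), ]
  pick <- cand[sample(nrow(cand), min(n_extra, nrow(cand))), ]
  m <- rbind(c(0L, 0L), as.matrix(pick))
  colnames(m) <- c("dx", "dy")
  m
}

# non-overlapping random disc centers inside a frame
random_centers <- function(n_discs, size, r, min_gap = 6) {
  ctr <- matrix(numeric(0), 0L, 2L)
  tries <- 0L
  while (nrow(ctr) < n_discs && tries < 500L) {
    tries <- tries + 1L
    cand <- stats::runif(2L, r + 2, size - 1 - r - 2)
    if (nrow(ctr) == 0L ||
        all(sqrt(rowSums((ctr - matrix(cand, nrow(ctr), 2L, byrow = TRUE))^2)) >
            2 * r + min_gap))
      ctr <- rbind(ctr, cand)
  }
  ctr
}

expect_angle_near <- function(est, truth, tol) {
  d <- abs(est - truth) %% 360
  expect_lt(min(d, 360 - d), tol)
}
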
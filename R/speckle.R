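#' Sum two frames after mean removal
#'
#' Pixel-wise sum of the two recordings after subtracting each frame's mean
#' brightness. For a pair related by a rigid shift the Fourier power
#' spectrum of this sum carries cosine interference fringes whose spacing
#' and orientation encode the shift.
#'
#' @param f1,f2 equal-sized brightness matrices.
#' @return numeric matrix (mean-free).
#' @export
sum_frames <- function(f1, f2) {
  if (!identical(dim(f1), dim(f2))) stop("frame size mismatch")
  (f1 - mean(f1)) + (f2 - mean(f2))
}

#' Centered 2D power spectrum
#'
#' Squared modulus of the centered 2D discrete Fourier transform of the
#' (optionally Hann-windowed) mean-subtracted image. The DC bin and a
#' 2-bin neighbourhood are suppressed to zero so that the residual
#' low-frequency energy cannot mask the fringe analysis.
#'
#' @param img square brightness matrix, side at least 32.
#' @param window `"hann"` (default, curbs spectral leakage) or `"none"`.
#' @param dc_radius radius (bins) of the suppressed neighbourhood around DC.
#' @return non-negative matrix over centered frequency coordinates, with
#'   attributes `n` (source side) and `window`.
#' @export
power_spectrum <- function(img, window = c("hann", "none"), dc_radius = 2) {
  window <- match.arg(window)
  if (!is.matrix(img) || nrow(img) != ncol(img)) stop("image must be square")
  n <- nrow(img)
  if (n < 32L) stop("image side must be at least 32")
  x <- img - mean(img)
  if (window == "hann") {
    w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
    x <- x * outer(w, w)
  }
  P <- fftshift(Mod(stats::fft(x))^2)
  c0 <- n %/% 2 + 1L
  u <- seq_len(n) - c0
  P[outer(u^2, u^2, `+`) <= dc_radius^2] <- 0
  structure(P, n = n, window = window)
}

# Move the zero-frequency bin to position (floor(n/2)+1, floor(n/2)+1).
fftshift <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[c((nr %/% 2 + 1L):nr, 1:(nr %/% 2)),
    c((nc %/% 2 + 1L):nc, 1:(nc %/% 2)), drop = FALSE]
}

#' Estimate interference fringes in a power spectrum
#'
#' Locates the dominant non-DC peak of the 2D FFT of the log power
#' spectrum (cepstral fringe detection). For a summed shifted pair the
#' log-spectrum is modulated by `log(2 + 2 cos(2 pi (u dx + v dy) / n))`,
#' so the cepstrum peaks at offset `(dx, dy)`: the fringe period in
#' frequency-plane bins is `n / |d|` and the strips run perpendicular to
#' the shift.
#'
#' Three robustness measures are applied. The radial mean of the
#' log-spectrum is subtracted first: the texture's own (radially
#' symmetric) spectral envelope otherwise dominates the low-quefrency
#' cepstrum, while the fringes, which depend on the projection onto the
#' shift rather than on `|u|`, survive the subtraction. Peaks are ranked
#' by 3x3-summed cepstral energy, so a fringe fundamental split across
#' adjacent bins by leakage is not outranked by its concentrated second
#' harmonic, and any remaining harmonic pick is corrected by a
#' subharmonic check. Finally the peak position is refined to sub-bin
#' precision by maximizing the discrete-time Fourier transform of the
#' whitened log-spectrum around the winning bin (parabolic interpolation
#' is the fallback when `refine = FALSE`).
#'
#' @param spec centered power spectrum from [power_spectrum()].
#' @param eps minimum contrast (3x3 peak power / total non-DC cepstrum
#'   power) below which no fringes are declared; the zero-shift path.
#' @param min_shift smallest detectable shift in pixels; cepstrum bins
#'   closer to DC are excluded (shifts under one full fringe across the
#'   spectrum are unresolvable).
#' @param refine refine the peak by continuous DTFT maximization.
#' @return list of class `fringe_estimate` with `period_bins`, `pitch_deg`
#'   (strip orientation, degrees in `[0, 180)`), `contrast` and
#'   `peak_offset` (the `(dx, dy)` cepstrum peak).
#' @export
estimate_fringes <- function(spec, eps = 0.06, min_shift = 2, refine = TRUE,
                             whiten = TRUE) {
  n <- attr(spec, "n")
  if (is.null(n)) n <- nrow(spec)
  P <- unclass(spec)
  pos <- P[P > 0]
  if (length(pos) == 0L) stop(no_fringes_error("empty spectrum"))
  P[P == 0] <- mean(pos)  # fill the DC hole before taking logs
  L <- log(P)
  c0 <- n %/% 2 + 1L
  u <- seq_len(n) - c0
  r2 <- outer(u^2, u^2, `+`)
  if (whiten) {
    # remove the radially symmetric envelope of the texture spectrum
    annulus <- factor(round(sqrt(r2)))
    L <- L - stats::ave(as.vector(L), as.vector(annulus))
    dim(L) <- c(n, n)
  }
  L <- L - mean(L)
  C <- fftshift(Mod(stats::fft(L))^2)
  allowed <- r2 >= min_shift^2 & r2 <= (n %/% 2 - 1L)^2
  total <- sum(C[allowed])
  if (total <= 0) stop(no_fringes_error("no cepstral energy"))
  # rank candidate peaks by 3x3-summed power so a leakage-split fundamental
  # is never outranked by a concentrated harmonic
  S <- box_sum3(C)
  Sm <- S
  Sm[!allowed] <- -Inf
  pk <- arrayInd(which.max(Sm), dim(Sm))
  # subharmonic check: the log-fringe harmonic at k*d has ~1/k^2 of the
  # fundamental's power, so if a harmonic still won, the fundamental at
  # peak/k stands well above 0.4 of it
  for (k in c(3L, 2L)) {
    cand <- round((pk - c0) / k) + c0
    if (sum((cand - c0)^2) >= min_shift^2 &&
        S[cand[1L], cand[2L]] >= 0.4 * S[pk[1L], pk[2L]]) {
      nb <- expand.grid(r = cand[1L] + (-1:1), c = cand[2L] + (-1:1))
      vals <- S[as.matrix(nb)]
      pk <- as.integer(nb[which.max(vals), ])
      break
    }
  }
  contrast <- S[pk[1L], pk[2L]] / total
  if (contrast < eps)
    stop(no_fringes_error(sprintf(
      "no fringes detected (contrast %.2g < %.2g)", contrast, eps)))
  # the 3x3 sums tie across neighbours of a concentrated peak; recenter on
  # the strongest single bin before sub-bin refinement
  nb <- expand.grid(r = pk[1L] + (-1:1), c = pk[2L] + (-1:1))
  nb <- nb[nb$r >= 1 & nb$r <= n & nb$c >= 1 & nb$c <= n, ]
  pk <- as.integer(nb[which.max(C[as.matrix(nb)]), ])
  dx <- pk[2L] - c0
  dy <- pk[1L] - c0
  if (refine) {
    d_ref <- refine_peak_dtft(L, c(dx, dy), n)
    dx <- d_ref[1L]; dy <- d_ref[2L]
  } else {
    dx <- dx + parab_offset(C, pk, dim = 2L)
    dy <- dy + parab_offset(C, pk, dim = 1L)
  }
  # the cepstrum is point-symmetric; report the representative with
  # direction angle in [0, 180) (y-down convention)
  ang <- atan2(dy, dx) * 180 / pi
  if (ang < 0 || (ang == 0 && dx < 0)) { dx <- -dx; dy <- -dy }
  mag <- sqrt(dx^2 + dy^2)
  pitch <- (atan2(dy, dx) * 180 / pi + 90) %% 180
  structure(list(period_bins = n / mag, pitch_deg = pitch,
                 contrast = min(contrast, 1), peak_offset = c(dx = dx, dy = dy),
                 n = n),
            class = "fringe_estimate")
}

# 3x3 box-summed matrix (zero fill at borders).
box_sum3 <- function(C) {
  nr <- nrow(C); nc <- ncol(C)
  S <- matrix(0, nr, nc)
  for (a in -1:1) for (b in -1:1) {
    rd <- max(1L, 1L - a):min(nr, nr - a)
    cd <- max(1L, 1L - b):min(nc, nc - b)
    S[rd, cd] <- S[rd, cd] + C[rd + a, cd + b]
  }
  S
}

# Maximize |sum_{u,v} L[v,u] exp(-2 pi i (u dx + v dy)/n)|^2 over
# continuous (dx, dy) within +/- 0.75 bin of the integer cepstrum peak, by
# alternating 1D golden-section passes (the objective is separable near a
# concentrated peak). Precomputing the partial sums makes each 1D
# evaluation O(n).
refine_peak_dtft <- function(L, d0, n) {
  c0 <- n %/% 2 + 1L
  u <- seq_len(n) - c0
  phase <- function(d) exp(-2i * pi * u * d / n)
  dx <- d0[1L]; dy <- d0[2L]
  for (pass in 1:3) {
    eyL <- as.vector(phase(dy) %*% L)
    dx <- stats::optimize(function(z) -Mod(sum(eyL * phase(z)))^2,
                          lower = d0[1L] - 0.75, upper = d0[1L] + 0.75,
                          tol = 1e-7)$minimum
    Lex <- as.vector(L %*% phase(dx))
    dy <- stats::optimize(function(z) -Mod(sum(phase(z) * Lex))^2,
                          lower = d0[2L] - 0.75, upper = d0[2L] + 0.75,
                          tol = 1e-7)$minimum
  }
  c(dx, dy)
}

no_fringes_error <- function(msg) {
  errorCondition(msg, class = c("spinetrack_no_fringes", "error", "condition"))
}

# Three-point parabolic sub-bin peak interpolation along one dimension.
parab_offset <- function(C, pk, dim) {
  i <- pk[dim]
  n <- base::dim(C)[dim]
  if (i <= 1L || i >= n) return(0)
  get <- function(j) if (dim == 1L) C[j, pk[2L]] else C[pk[1L], j]
  y0 <- get(i - 1L); y1 <- get(i); y2 <- get(i + 1L)
  den <- y0 - 2 * y1 + y2
  if (den == 0) return(0)
  d <- 0.5 * (y0 - y2) / den
  max(min(d, 0.5), -0.5)
}

#' Convert a fringe estimate to a displacement vector
#'
#' The shift magnitude is `n / period_bins` pixels and the shift direction
#' is the fringe normal (`pitch + 90` mod 180). The sign of the shift is
#' not recoverable from the summed spectrum; see [resolve_sign()].
#'
#' @param fr `fringe_estimate`.
#' @param n source image side in pixels.
#' @return list of class `displacement` with `magnitude_px`,
#'   `direction_deg` in `[0, 180)`, `sign_resolved = FALSE`, `contrast`,
#'   `period_bins`, `pitch_deg`.
#' @export
displacement_from_fringes <- function(fr, n) {
  stopifnot(inherits(fr, "fringe_estimate"), n > 0)
  mag <- if (is.finite(fr$period_bins)) n / fr$period_bins else 0
  dir <- if (mag > 0) (fr$pitch_deg + 90) %% 180 else 0
  new_displacement(magnitude_px = mag, direction_deg = dir,
                   sign_resolved = FALSE, contrast = fr$contrast,
                   period_bins = fr$period_bins, pitch_deg = fr$pitch_deg)
}

new_displacement <- function(magnitude_px, direction_deg, sign_resolved,
                             contrast = NA_real_, period_bins = NA_real_,
                             pitch_deg = NA_real_, magnitude_mm = NULL) {
  structure(list(magnitude_px = magnitude_px, direction_deg = direction_deg,
                 sign_resolved = sign_resolved, magnitude_mm = magnitude_mm,
                 contrast = contrast, period_bins = period_bins,
                 pitch_deg = pitch_deg),
            class = "displacement")
}

#' @export
print.displacement <- function(x, ...) {
  cat(sprintf("displacement: %.3f px @ %.2f deg (%s)\n", x$magnitude_px,
              x$direction_deg,
              if (isTRUE(x$sign_resolved)) "sign resolved" else "sign unresolved"))
  if (!is.null(x$magnitude_mm))
    cat(sprintf("  %.4f mm\n", x$magnitude_mm))
  if (is.finite(x$contrast))
    cat(sprintf("  fringe contrast %.3g, period %.2f bins\n",
                x$contrast, x$period_bins))
  invisible(x)
}

#' Resolve the sign of a fringe-derived displacement
#'
#' Summing the frames destroys the shift sign, leaving the direction known
#' only modulo 180 degrees. This probe shifts the first frame by the two
#' candidate vectors and keeps the sign whose shifted copy correlates
#' better with the second frame. If the two scores differ by less than
#' `tol` (relative), the vector is left unresolved with a warning.
#'
#' @param f1,f2 the original frame pair.
#' @param d unresolved `displacement`.
#' @param tol relative score margin below which the sign is ambiguous.
#' @return `displacement` with `direction_deg` in `[0, 360)` and
#'   `sign_resolved = TRUE` (unless ambiguous).
#' @export
resolve_sign <- function(f1, f2, d, tol = 0.01) {
  stopifnot(inherits(d, "displacement"))
  if (d$magnitude_px == 0 || isTRUE(d$sign_resolved)) return(d)
  th <- d$direction_deg * pi / 180
  sx <- d$magnitude_px * cos(th)
  sy <- d$magnitude_px * sin(th)
  score <- function(ddx, ddy)
    stats::cor(as.vector(shift_image(f1, ddx, ddy)), as.vector(f2))
  sp <- score(sx, sy)
  sm <- score(-sx, -sy)
  if (abs(sp - sm) <= tol * max(abs(sp), abs(sm))) {
    warning("shift sign ambiguous; direction left in [0, 180)")
    return(d)
  }
  dir <- if (sp >= sm) d$direction_deg else (d$direction_deg + 180) %% 360
  d$direction_deg <- dir %% 360
  d$sign_resolved <- TRUE
  d
}

#' Measure the planar displacement between two pseudo-speckle frames
#'
#' Full chain: [sum_frames()], [power_spectrum()], [estimate_fringes()],
#' [displacement_from_fringes()], [resolve_sign()]. If no fringes are
#' detected (shift below the resolvable minimum), a zero displacement is
#' returned.
#'
#' @param f1,f2 equal-size square frames, before and after the shift.
#' @param window FFT window, `"hann"` or `"none"`.
#' @param mm_per_px optional pixel pitch; fills `magnitude_mm`.
#' @param eps fringe-contrast floor passed to [estimate_fringes()].
#' @return `displacement`.
#' @export
#' @examples
#' a <- gen_speckle(64, 50, seed = 2)
#' b <- shift_image(a, 4, 0)
#' measure_displacement(a, b)
measure_displacement <- function(f1, f2, window = "hann", mm_per_px = NULL,
                                 eps = 0.06) {
  if (!identical(dim(f1), dim(f2))) stop("frame size mismatch")
  s <- sum_frames(f1, f2)
  P <- power_spectrum(s, window = window)
  fr <- tryCatch(estimate_fringes(P, eps = eps),
                 spinetrack_no_fringes = function(e) NULL)
  if (is.null(fr)) {
    d <- new_displacement(0, 0, TRUE)
  } else {
    d <- displacement_from_fringes(fr, nrow(f1))
    d <- resolve_sign(f1, f2, d)
  }
  if (is.null(mm_per_px)) mm_per_px <- attr(f1, "mm_per_px")
  if (!is.null(mm_per_px)) d$magnitude_mm <- d$magnitude_px * mm_per_px
  d
}
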
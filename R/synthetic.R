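#' Generate a pseudo-speckle target image
#'
#' Produces a square random texture emulating the computer-generated
#' pseudo-speckle patterns glued to the vertebrae: white Gaussian noise is
#' low-pass filtered with a Gaussian kernel of correlation length
#' `corr_px` and rescaled so that the brightness histogram has (sample)
#' standard deviation `sigma` around `mean_brightness`, then clipped to the
#' stored 0--255 range. The texture recipe (filtered noise) is this
#' package's own choice; only the standard deviation of the pattern is a
#' rig-level parameter (default 50 brightness units).
#'
#' @param size_px side of the square image, at least 32 pixels.
#' @param sigma target brightness standard deviation (> 0).
#' @param seed integer RNG seed; identical specs give bit-identical images.
#' @param corr_px correlation length of the low-pass filter, pixels.
#' @param mean_brightness center of the brightness distribution.
#' @return `size_px` x `size_px` numeric brightness matrix.
#' @export
#' @examples
#' img <- gen_speckle(64, sigma = 50, seed = 1)
#' sd(as.vector(img))
gen_speckle <- function(size_px, sigma, seed = 1L, corr_px = 2,
                        mean_brightness = 128) {
  size_px <- as.integer(size_px)
  if (is.na(size_px) || size_px < 32L)
    stop("size_px must be an integer >= 32")
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("sigma must be a positive number")
  n <- size_px
  w <- with_seed(seed, matrix(stats::rnorm(n * n), n, n))
  # Low-pass in the frequency domain: Gaussian transfer function of the
  # spatial Gaussian kernel with sd corr_px (circular convolution).
  f <- (((0:(n - 1)) + n %/% 2) %% n - n %/% 2) / n  # cycles per pixel
  h <- exp(-2 * pi^2 * corr_px^2 * f^2)
  H <- outer(h, h)
  field <- Re(stats::fft(stats::fft(w) * H, inverse = TRUE)) / (n * n)
  z <- (field - mean(field)) / stats::sd(as.vector(field))
  clip255(mean_brightness + sigma * z)
}

#' Rigidly translate an image by a (sub-pixel) shift
#'
#' Integer shifts are realized as an exact roll of the pixel grid;
#' fractional shifts use the spectral phase-ramp (shift theorem) with
#' periodic boundary handling, so content leaving one side re-enters at the
#' other (real cameras crop instead -- acceptable for synthetic fixtures).
#' The output satisfies `out(x, y) = in(x - dx, y - dy)`: positive `dx`
#' moves content rightward, positive `dy` downward.
#'
#' @param img numeric brightness matrix.
#' @param dx,dy shift in pixels along x (columns) and y (rows); each must be
#'   smaller in magnitude than a quarter of the image side.
#' @return shifted matrix of the same size.
#' @export
shift_image <- function(img, dx, dy) {
  stopifnot(is.matrix(img), is.numeric(img))
  nr <- nrow(img); nc <- ncol(img)
  if (abs(dx) >= nc / 4 || abs(dy) >= nr / 4)
    stop("shift too large: |dx|, |dy| must be < side/4")
  if (dx == round(dx) && dy == round(dy)) {
    r <- (seq_len(nr) - 1L - as.integer(round(dy))) %% nr + 1L
    c <- (seq_len(nc) - 1L - as.integer(round(dx))) %% nc + 1L
    out <- img[r, c, drop = FALSE]
    return(structure(out, mm_per_px = attr(img, "mm_per_px")))
  }
  sfreq <- function(n) ((0:(n - 1) + n %/% 2) %% n) - n %/% 2
  ramp1 <- function(n, d) {
    f <- sfreq(n)
    ph <- exp(-2i * pi * f * d / n)
    # real phase factor at the Nyquist bin keeps real input exactly real
    if (n %% 2 == 0) ph[f == -n %/% 2] <- cos(pi * d)
    ph
  }
  R <- outer(ramp1(nr, dy), ramp1(nc, dx))
  out <- Re(stats::fft(stats::fft(img) * R, inverse = TRUE)) / (nr * nc)
  structure(out, dim = dim(img), mm_per_px = attr(img, "mm_per_px"))
}

#' Render a synthetic marker-disc scene with known centers
#'
#' Draws anti-aliased circular discs of uniform brightness on a flat
#' background, optionally adding Gaussian pixel noise. The returned ground
#' truth equals the requested centers exactly, making the scene a reference
#' fixture for the detection pipeline.
#'
#' @param size_px side of the square frame.
#' @param centers disc centers: an `n x 2` matrix (or data.frame / list of
#'   pairs) of zero-based `(x, y)` pixel coordinates; may have zero rows.
#' @param radius_px disc radius in pixels.
#' @param fg,bg disc and background brightness (0--255).
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed RNG seed for the noise.
#' @return list with elements `image` (brightness matrix) and `centers`
#'   (`n x 2` matrix with columns `x`, `y`, equal to the request).
#' @export
gen_disc_scene <- function(size_px, centers, radius_px, fg = 200, bg = 60,
                           noise_sd = 0, seed = 1L) {
  size_px <- as.integer(size_px)
  stopifnot(size_px >= 8L, radius_px > 0, noise_sd >= 0)
  ctr <- as_center_matrix(centers)
  if (nrow(ctr) > 0) {
    inside <- ctr[, 1] - radius_px >= 0 & ctr[, 1] + radius_px <= size_px - 1 &
              ctr[, 2] - radius_px >= 0 & ctr[, 2] + radius_px <= size_px - 1
    if (!all(inside)) stop("disc(s) not fully inside the frame")
    if (nrow(ctr) > 1) {
      dd <- as.matrix(stats::dist(ctr))
      diag(dd) <- Inf
      if (any(dd <= 2 * radius_px)) stop("discs overlap")
    }
  }
  img <- matrix(bg, size_px, size_px)
  for (i in seq_len(nrow(ctr))) {
    cx <- ctr[i, 1]; cy <- ctr[i, 2]
    cols <- max(1L, floor(cx - radius_px)):min(size_px, ceiling(cx + radius_px) + 2L)
    rows <- max(1L, floor(cy - radius_px)):min(size_px, ceiling(cy + radius_px) + 2L)
    d <- sqrt(outer((rows - 1 - cy)^2, (cols - 1 - cx)^2, `+`))
    cov <- pmin(pmax(radius_px + 0.5 - d, 0), 1)  # linear edge coverage
    img[rows, cols] <- img[rows, cols] + (fg - bg) * cov
  }
  if (noise_sd > 0)
    img <- img + with_seed(seed, matrix(stats::rnorm(size_px^2, 0, noise_sd),
                                        size_px, size_px))
  list(image = clip255(img), centers = ctr)
}

as_center_matrix <- function(centers) {
  if (is.null(centers) || length(centers) == 0L)
    return(matrix(numeric(0), 0L, 2L, dimnames = list(NULL, c("x", "y"))))
  if (is.data.frame(centers)) centers <- as.matrix(centers[, c("x", "y")])
  if (is.list(centers)) centers <- do.call(rbind, lapply(centers, as.numeric))
  if (is.numeric(centers) && is.null(dim(centers))) centers <- matrix(centers, ncol = 2L, byrow = TRUE)
  stopifnot(is.matrix(centers), ncol(centers) == 2L)
  colnames(centers) <- c("x", "y")
  centers
}

#' Simulate a strain-gauge calibration table
#'
#' Generates `force = a_true + b_true * voltage + noise` records mirroring
#' what the rig's four gauges deliver during a calibration run against known
#' loads.
#'
#' @param a_true true intercept, Newton.
#' @param b_true true slope, Newton per volt.
#' @param voltages at least three voltage points, not all equal.
#' @param noise_sd Gaussian force noise standard deviation, Newton.
#' @param seed RNG seed.
#' @return data.frame with columns `voltage` and `force`.
#' @export
gen_gauge_data <- function(a_true, b_true, voltages, noise_sd = 0, seed = 1L) {
  voltages <- as.numeric(voltages)
  if (length(voltages) < 3L) stop("need at least 3 voltage points")
  if (max(voltages) == min(voltages)) stop("voltages must not all be equal")
  stopifnot(noise_sd >= 0)
  eps <- if (noise_sd > 0)
    with_seed(seed, stats::rnorm(length(voltages), 0, noise_sd)) else 0
  data.frame(voltage = voltages, force = a_true + b_true * voltages + eps)
}

#' Simulate load steps of a linear synthetic specimen
#'
#' Generates a stepwise loading protocol for one loading mode of a specimen
#' with programmed stiffness, mirroring the rig's step-by-step measurement:
#' at each step a force is applied and the resulting displacement (or
#' rotation) is read with additive measurement noise. The default noise
#' level is 2\% of the full-scale displacement.
#'
#' @param mode one of the loading modes (see [loading_modes()]).
#' @param stiffness programmed stiffness: N/mm for compression, Nm/mm for
#'   the shift variant, Nm/rad for the angle variant.
#' @param forces applied forces per step, Newton.
#' @param arm_m lever arm in metres (required except for compression).
#' @param variant `"shift"` (camera-measured displacement of the arm) or
#'   `"angle"`.
#' @param repeats number of protocol repetitions.
#' @param noise_sd displacement noise SD in the measured unit (mm or rad);
#'   default 2\% of the largest true displacement.
#' @param seed RNG seed.
#' @return data.frame with columns `mode`, `rep`, `step`, `force_N`,
#'   `displacement_mm`, `angle_rad`, `arm_m`.
#' @export
simulate_load_steps <- function(mode, stiffness, forces, arm_m = NULL,
                                variant = c("shift", "angle"),
                                repeats = 10L, noise_sd = NULL, seed = 1L) {
  variant <- match.arg(variant)
  mode <- match.arg(mode, loading_modes())
  stopifnot(stiffness > 0, length(forces) >= 1L, repeats >= 1L)
  if (mode != "compression" && (is.null(arm_m) || arm_m <= 0))
    stop("arm_m required for non-compression modes")
  true_disp <- if (mode == "compression") forces / stiffness
               else forces * arm_m / stiffness
  if (is.null(noise_sd)) noise_sd <- 0.02 * max(abs(true_disp))
  n <- length(forces) * repeats
  eps <- if (noise_sd > 0) with_seed(seed, stats::rnorm(n, 0, noise_sd)) else 0
  meas <- rep(true_disp, times = repeats) + eps
  out <- data.frame(
    mode = mode,
    rep = rep(seq_len(repeats), each = length(forces)),
    step = rep(seq_along(forces), times = repeats),
    force_N = rep(forces, times = repeats),
    displacement_mm = NA_real_,
    angle_rad = NA_real_,
    arm_m = if (mode == "compression") NA_real_ else arm_m
  )
  if (variant == "shift" || mode == "compression") out$displacement_mm <- meas
  else out$angle_rad <- meas
  out
}
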
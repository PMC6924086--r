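#' Discrete 2D convolution with reflective border padding
#'
#' True convolution (the kernel is flipped), output the same size as the
#' input. Border pixels are computed against a mirror extension of the
#' image, so a constant image stays constant.
#'
#' @param img numeric brightness matrix.
#' @param k kernel matrix; both dimensions must be odd and no larger than
#'   the image.
#' @return matrix of the same size as `img`.
#' @export
convolve2d <- function(img, k) {
  stopifnot(is.matrix(img), is.matrix(k))
  kr <- nrow(k); kc <- ncol(k)
  if (kr %% 2 == 0 || kc %% 2 == 0) stop("kernel dimensions must be odd")
  if (kr > nrow(img) || kc > ncol(img)) stop("kernel larger than image")
  mr <- (kr - 1L) %/% 2L
  mc <- (kc - 1L) %/% 2L
  p <- pad_reflect(img, mr, mc)
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (a in -mr:mr) for (b in -mc:mc) {
    w <- k[a + mr + 1L, b + mc + 1L]
    if (w == 0) next
    # g[y, x] += h[a, b] * f[y - a, x - b]
    out <- out + w * p[(1:nr) - a + mr, (1:nc) - b + mc]
  }
  out
}

# Mirror-pad a matrix by mr rows / mc cols (edge pixel included in mirror).
pad_reflect <- function(img, mr, mc) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- c(if (mr > 0) mr:1, 1:nr, if (mr > 0) nr:(nr - mr + 1L))
  ci <- c(if (mc > 0) mc:1, 1:nc, if (mc > 0) nc:(nc - mc + 1L))
  img[ri, ci, drop = FALSE]
}

#' Sobel gradient-magnitude edge map
#'
#' Applies the standard 3x3 Sobel derivative pair along x (columns) and y
#' (rows) and returns the gradient magnitude `sqrt(gx^2 + gy^2)`. This is
#' the edge-enhancement step preceding segmentation in the disc-detection
#' pipeline.
#'
#' @param img numeric brightness matrix, at least 3x3.
#' @return non-negative matrix of the same size.
#' @export
edge_map <- function(img) {
  if (nrow(img) < 3L || ncol(img) < 3L) stop("image must be at least 3x3")
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3L, 3L)  # d/dx (columns)
  gx <- convolve2d(img, sx)
  gy <- convolve2d(img, t(sx))
  sqrt(gx^2 + gy^2)
}

#' Band threshold segmentation
#'
#' Pixels with brightness inside the closed band `[t_min, t_max]` become 1,
#' all others 0.
#'
#' @param img numeric brightness matrix.
#' @param t_min,t_max band limits, `t_min <= t_max`; `t_max` may be `Inf`.
#' @return integer 0/1 matrix with attributes `t_min` and `t_max`.
#' @export
threshold_band <- function(img, t_min, t_max = Inf) {
  if (!is.numeric(t_min) || !is.numeric(t_max) || t_min > t_max)
    stop("inverted threshold band: need t_min <= t_max")
  m <- matrix(as.integer(img >= t_min & img <= t_max), nrow(img), ncol(img))
  structure(m, t_min = t_min, t_max = t_max)
}

#' Structuring elements for binary morphology
#'
#' A structuring element is a set of integer pixel offsets `(dx, dy)`
#' containing the origin. `se_disc()` gives the digital disc of the given
#' radius (radius 1 is the 4-connected cross), `se_box()` the
#' `(2r+1) x (2r+1)` square, `se_cross()` the axis-aligned cross of arm
#' length `r`.
#'
#' @param r radius (non-negative integer).
#' @return integer matrix with columns `dx`, `dy`.
#' @export
se_disc <- function(r = 1L) {
  g <- expand.grid(dx = -r:r, dy = -r:r)
  se_from_offsets(g[g$dx^2 + g$dy^2 <= r^2, ])
}

#' @rdname se_disc
#' @export
se_box <- function(r = 1L) se_from_offsets(expand.grid(dx = -r:r, dy = -r:r))

#' @rdname se_disc
#' @export
se_cross <- function(r = 1L) {
  se_from_offsets(data.frame(dx = c(-r:r, rep(0L, 2L * r)),
                             dy = c(rep(0L, 2L * r + 1L), -r:-1, 1:r)))
}

se_from_offsets <- function(off) {
  m <- cbind(dx = as.integer(off$dx), dy = as.integer(off$dy))
  if (!any(m[, 1] == 0L & m[, 2] == 0L)) stop("structuring element must contain (0,0)")
  m[order(m[, 2], m[, 1]), , drop = FALSE]
}

# Value of m at (x+dx, y+dy) for every pixel; out-of-frame reads give fill.
translate_mask <- function(m, dx, dy, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(as.integer(fill), nr, nc)
  rd <- max(1L, 1L - dy):min(nr, nr - dy)
  cd <- max(1L, 1L - dx):min(nc, nc - dx)
  if (length(rd) > 0 && length(cd) > 0)
    out[rd, cd] <- m[rd + dy, cd + dx]
  out
}

#' Binary erosion, dilation and opening
#'
#' Set-theoretic morphology on 0/1 masks. Erosion keeps a pixel `d` only if
#' every translate `d + b`, `b` in the structuring element, is foreground;
#' pixels outside the frame count as background. Dilation marks every
#' `x + b` for foreground `x`. Opening is erosion followed by dilation by
#' the same element and removes detail smaller than the element while
#' preserving the overall shape.
#'
#' @param mask integer 0/1 matrix (as from [threshold_band()]).
#' @param b structuring element (see [se_disc()]).
#' @return 0/1 matrix of the same size.
#' @export
erode <- function(mask, b) {
  acc <- NULL
  for (i in seq_len(nrow(b))) {
    t <- translate_mask(mask, b[i, 1L], b[i, 2L], fill = 0L)
    acc <- if (is.null(acc)) t else acc * t
  }
  structure(acc, t_min = attr(mask, "t_min"), t_max = attr(mask, "t_max"))
}

#' @rdname erode
#' @export
dilate <- function(mask, b) {
  acc <- matrix(0L, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(b)))
    acc <- pmax(acc, translate_mask(mask, -b[i, 1L], -b[i, 2L], fill = 0L))
  structure(matrix(as.integer(acc), nrow(mask)), t_min = attr(mask, "t_min"),
            t_max = attr(mask, "t_max"))
}

#' @rdname erode
#' @export
open_mask <- function(mask, b) dilate(erode(mask, b), b)

#' Connected-component centroid search
#'
#' Labels 8-connected foreground components and reports, for each component
#' with at least `min_pixels` pixels, the arithmetic mean of its member
#' pixel coordinates (zero-based `x` = column, `y` = row) -- the center of
#' the corresponding marker disc. Components are sorted by descending pixel
#' count, ties broken by center `(y, x)`.
#'
#' @param mask integer 0/1 matrix.
#' @param min_pixels minimum component size to report.
#' @return data.frame with columns `x`, `y`, `pixel_count` (possibly empty).
#' @export
find_centers <- function(mask, min_pixels = 20L) {
  lab <- label_components(mask)
  if (lab$n == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), pixel_count = integer(0)))
  nr <- nrow(mask)
  idx <- which(lab$labels > 0L)
  comp <- lab$labels[idx]
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  cnt <- tabulate(comp, nbins = lab$n)
  cx <- tapply(cols - 1L, comp, mean)
  cy <- tapply(rows - 1L, comp, mean)
  out <- data.frame(x = as.numeric(cx), y = as.numeric(cy),
                    pixel_count = as.integer(cnt))
  out <- out[out$pixel_count >= min_pixels, , drop = FALSE]
  out <- out[order(-out$pixel_count, out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# 8-connected labeling by iterative flood fill. Returns integer label
# matrix (0 = background) and the number of components.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  fg <- which(mask == 1L)
  if (length(fg) == 0L) return(list(labels = lab, n = 0L))
  n_lab <- 0L
  stack <- integer(length(fg))
  for (seed in fg) {
    if (lab[seed] != 0L) next
    n_lab <- n_lab + 1L
    sp <- 1L
    stack[1L] <- seed
    lab[seed] <- n_lab
    while (sp > 0L) {
      p <- stack[sp]; sp <- sp - 1L
      r <- (p - 1L) %% nr + 1L
      c <- (p - 1L) %/% nr + 1L
      for (dc in -1L:1L) {
        cc <- c + dc
        if (cc < 1L || cc > nc) next
        base <- (cc - 1L) * nr
        for (dr in -1L:1L) {
          rr <- r + dr
          if (rr < 1L || rr > nr) next
          q <- base + rr
          if (mask[q] == 1L && lab[q] == 0L) {
            lab[q] <- n_lab
            sp <- sp + 1L
            stack[sp] <- q
          }
        }
      }
    }
  }
  list(labels = lab, n = n_lab)
}

#' Disc-detection pipeline configuration
#'
#' @param threshold_min,threshold_max absolute band limits applied to the
#'   edge map; if `threshold_min` is `NULL` it is set adaptively to
#'   `threshold_rel` times the 99.9th percentile of the edge map.
#' @param threshold_rel relative threshold used when `threshold_min` is
#'   `NULL`.
#' @param se_radius radius of the disc structuring element used for opening.
#' @param min_pixels minimum component size reported as a disc.
#' @param max_jump_px maximum per-frame center jump when assembling tracks.
#' @param smooth_sigma Gaussian pre-smoothing SD (pixels) applied in the
#'   convolution stage before the derivative kernels; widens a small
#'   disc's edge annulus into a closed band and suppresses pixel noise.
#'   `0` disables.
#' @return list of class `disc_config`.
#' @export
disc_config <- function(threshold_min = NULL, threshold_max = Inf,
                        threshold_rel = 0.35, se_radius = 1L,
                        min_pixels = 20L, max_jump_px = 15,
                        smooth_sigma = 1) {
  stopifnot(threshold_rel > 0, threshold_rel <= 1, se_radius >= 0,
            min_pixels >= 1, max_jump_px > 0, smooth_sigma >= 0)
  structure(list(threshold_min = threshold_min, threshold_max = threshold_max,
                 threshold_rel = threshold_rel, se_radius = as.integer(se_radius),
                 min_pixels = as.integer(min_pixels), max_jump_px = max_jump_px,
                 smooth_sigma = smooth_sigma),
            class = "disc_config")
}

#' Gaussian smoothing kernel
#'
#' Normalized (sum-to-one) 2D Gaussian kernel of standard deviation
#' `sigma`, truncated at three sigma.
#'
#' @param sigma standard deviation in pixels.
#' @return odd-sized kernel matrix.
#' @export
gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Detect marker discs in a grayscale frame
#'
#' Composition of the pipeline stages: convolution (Gaussian smoothing and
#' Sobel edge enhancement, [edge_map()]), band thresholding
#' ([threshold_band()]), morphological opening ([open_mask()]) and
#' connected-component centroid search ([find_centers()]). Each disc
#' appears in the edge map as a bright annulus whose centroid coincides
#' with the disc center.
#'
#' @param img numeric brightness matrix.
#' @param cfg pipeline parameters, see [disc_config()].
#' @return data.frame with columns `x`, `y`, `pixel_count`.
#' @export
detect_discs <- function(img, cfg = disc_config()) {
  stopifnot(inherits(cfg, "disc_config"))
  if (cfg$smooth_sigma > 0)
    img <- convolve2d(img, gauss_kernel(cfg$smooth_sigma))
  e <- edge_map(img)
  t_min <- cfg$threshold_min
  if (is.null(t_min))
    t_min <- cfg$threshold_rel * as.numeric(stats::quantile(e, 0.999))
  if (t_min <= 0) return(data.frame(x = numeric(0), y = numeric(0),
                                    pixel_count = integer(0)))
  m <- threshold_band(e, t_min, cfg$threshold_max)
  if (cfg$se_radius > 0) m <- open_mask(m, se_disc(cfg$se_radius))
  find_centers(m, cfg$min_pixels)
}

#' Assemble per-frame detections into disc tracks
#'
#' Greedy nearest-neighbour matching of detections to existing tracks,
#' frame by frame: the closest (track, detection) pair within
#' `max_jump` pixels is linked first, then the next, and so on; leftover
#' detections open new tracks. A track that misses a frame simply has a
#' gap and can be continued later, never merged into a neighbour.
#'
#' @param frames list of per-frame detection data.frames (columns `x`, `y`
#'   and optionally `pixel_count`), in temporal order.
#' @param max_jump maximum allowed per-frame center displacement, pixels.
#' @return data.frame with columns `disc_id`, `frame`, `x`, `y`,
#'   `pixel_count`, ordered by `disc_id` then `frame`.
#' @export
assemble_tracks <- function(frames, max_jump = 15) {
  stopifnot(is.list(frames), max_jump > 0)
  last_x <- numeric(0); last_y <- numeric(0)
  rows <- list()
  n_tracks <- 0L
  for (t in seq_along(frames)) {
    det <- frames[[t]]
    if (is.null(det) || nrow(det) == 0L) next
    if (is.null(det$pixel_count)) det$pixel_count <- NA_integer_
    assigned <- rep(NA_integer_, nrow(det))
    if (n_tracks > 0L) {
      dmat <- sqrt(outer(last_x, det$x, `-`)^2 + outer(last_y, det$y, `-`)^2)
      free_tr <- rep(TRUE, n_tracks); free_de <- rep(TRUE, nrow(det))
      repeat {
        dmat_f <- dmat
        dmat_f[!free_tr, ] <- Inf
        dmat_f[, !free_de] <- Inf
        mn <- min(dmat_f)
        if (!is.finite(mn) || mn > max_jump) break
        w <- which(dmat_f == mn, arr.ind = TRUE)[1L, ]
        assigned[w[2L]] <- w[1L]
        free_tr[w[1L]] <- FALSE
        free_de[w[2L]] <- FALSE
      }
    }
    for (i in seq_len(nrow(det))) {
      id <- assigned[i]
      if (is.na(id)) {
        n_tracks <- n_tracks + 1L
        id <- n_tracks
        last_x <- c(last_x, det$x[i]); last_y <- c(last_y, det$y[i])
      } else {
        last_x[id] <- det$x[i]; last_y[id] <- det$y[i]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        disc_id = id, frame = t, x = det$x[i], y = det$y[i],
        pixel_count = det$pixel_count[i])
    }
  }
  if (length(rows) == 0L)
    return(data.frame(disc_id = integer(0), frame = integer(0),
                      x = numeric(0), y = numeric(0), pixel_count = integer(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$disc_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}
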
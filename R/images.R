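#' @title Grayscale image conventions
#' @description
#' Images are plain numeric matrices `img[row, col]` holding brightness on a
#' real-valued 0--255 scale (quantization to 8-bit is an explicit, optional
#' step; see [quantize_8bit()]). Coordinates reported by the toolkit are
#' zero-based, with `x` the column index increasing rightward and `y` the row
#' index increasing downward, so a pixel at matrix position `[r, c]` has
#' coordinates `(x, y) = (c - 1, r - 1)`. An optional `mm_per_px` attribute
#' carries the pixel pitch.
#' @name image-conventions
NULL

#' Read a grayscale image
#'
#' Reads PNG, TIFF or uncompressed BMP. Color images are converted to
#' grayscale by the unweighted average of the color channels; an alpha
#' channel, if present, is dropped.
#'
#' @param path file path; format inferred from the extension.
#' @param mm_per_px optional pixel pitch in millimetres, stored as an
#'   attribute on the returned matrix.
#' @return numeric matrix of brightness in `[0, 255]`.
#' @export
read_gray_image <- function(path, mm_per_px = NULL) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path) * 255,
    tif = ,
    tiff = tiff::readTIFF(path) * 255,
    bmp = read_bmp(path),
    stop("unsupported image format: .", ext, " (expected png/tif/tiff/bmp)")
  )
  if (length(dim(a)) == 3L) {
    nc <- min(dim(a)[3L], 3L)  # drop alpha
    a <- apply(a[, , seq_len(nc), drop = FALSE], c(1L, 2L), mean)
  }
  img <- matrix(as.numeric(a), nrow = nrow(a), ncol = ncol(a))
  if (!is.null(mm_per_px)) attr(img, "mm_per_px") <- mm_per_px
  img
}

#' Write a grayscale image
#'
#' @param img numeric matrix of brightness in `[0, 255]`.
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @param bits bits per sample for TIFF output (8 or 16); PNG output is 8-bit.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path, bits = 8L) {
  stopifnot(is.matrix(img), is.numeric(img))
  x <- pmin(pmax(img, 0), 255) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(x, target = path),
    tif = ,
    tiff = tiff::writeTIFF(x, where = path, bits.per.sample = as.integer(bits)),
    stop("unsupported output format: .", ext)
  )
  invisible(path)
}

#' Quantize a real-valued image to 8-bit levels
#'
#' @param img numeric brightness matrix.
#' @return matrix of integers 0--255 (stored as numeric).
#' @export
quantize_8bit <- function(img) {
  structure(pmin(pmax(round(img), 0), 255), dim = dim(img),
            mm_per_px = attr(img, "mm_per_px"))
}

# Minimal reader for uncompressed BMP (8-bit palette or 24/32-bit BGR).
# No installed R package reads BMP, and the rig's cameras export it.
read_bmp <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2L)
  if (!identical(as.integer(magic), c(0x42L, 0x4DL)))
    stop("not a BMP file: ", path)
  readBin(con, "integer", 2L, size = 4L, endian = "little")  # file size, reserved
  data_offset <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hdr_size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (hdr_size < 40L) stop("unsupported BMP header")
  w <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  h <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  readBin(con, "integer", 1L, size = 2L, endian = "little")  # planes
  bpp <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  compression <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (compression != 0L) stop("compressed BMP not supported")
  if (!bpp %in% c(8L, 24L, 32L)) stop("unsupported BMP bit depth: ", bpp)
  top_down <- h < 0L
  h <- abs(h)
  pal <- NULL
  if (bpp == 8L) {
    seek(con, 14L + hdr_size)
    n_colors <- (data_offset - 14L - hdr_size) %/% 4L
    praw <- readBin(con, "raw", n_colors * 4L)
    pal <- matrix(as.integer(praw), ncol = 4L, byrow = TRUE)[, 1:3, drop = FALSE]
    pal <- rowMeans(pal[, 3:1, drop = FALSE])  # stored BGR
  }
  seek(con, data_offset)
  bytes_px <- bpp %/% 8L
  stride <- ((w * bytes_px + 3L) %/% 4L) * 4L
  raw <- readBin(con, "raw", stride * h)
  img <- matrix(0, nrow = h, ncol = w)
  for (row in seq_len(h)) {
    line <- as.integer(raw[((row - 1L) * stride + 1L):((row - 1L) * stride + w * bytes_px)])
    vals <- if (bpp == 8L) {
      pal[line + 1L]
    } else {
      m <- matrix(line, ncol = bytes_px, byrow = TRUE)
      rowMeans(m[, 1:3, drop = FALSE])  # BGR average == RGB average
    }
    r <- if (top_down) row else h - row + 1L
    img[r, ] <- vals
  }
  img
}

# Clip brightness into the stored [0, 255] range.
clip255 <- function(img) {
  structure(pmin(pmax(img, 0), 255), dim = dim(img))
}

# Evaluate code with a temporarily seeded RNG, restoring global RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}
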
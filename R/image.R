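# Image primitives. Frames and tiles are numeric arrays [H, W, 3] with
# intensities on the 0..255 scale, row index = y (downwards), column = x.
# Continuous pixel coordinates are 0-based with the origin at the top-left
# corner, so the centre of pixel (row r, col c) sits at (x, y) =
# (c - 0.5, r - 0.5).

#' Coerce to an image frame
#'
#' Validates and normalises an object to the internal image representation:
#' a numeric `H x W x 3` array of intensities in `[0, 255]`. Greyscale
#' matrices are replicated across three channels.
#'
#' @param img A numeric matrix or `H x W x 3` array.
#' @return A numeric `H x W x 3` array.
#' @export
as_image_frame <- function(img) {
  if (is.matrix(img)) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3L] != 3L)
    stop("an image frame must be an H x W x 3 array", call. = FALSE)
  storage.mode(img) <- "double"
  img
}

#' Read a PNG image as a frame
#'
#' @param path Path to a PNG file.
#' @return An `H x W x 3` array of intensities in `[0, 255]`. Alpha channels
#'   are dropped; greyscale images are expanded to three channels.
#' @export
read_frame_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3L] == 4L) a <- a[, , 1:3, drop = FALSE]
  as_image_frame(a * 255)
}

#' Write a frame as PNG
#'
#' @param img An `H x W x 3` array of intensities in `[0, 255]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frame_png <- function(img, path) {
  img <- as_image_frame(img)
  png::writePNG(clamp(img / 255, 0, 1), path)
  invisible(path)
}

#' Exact 90-degree rotation
#'
#' Rotates an image clockwise by `turns` quarter turns. This is a pure pixel
#' permutation (no interpolation), so four turns reproduce the input exactly.
#'
#' @param img An `H x W x 3` array.
#' @param turns Integer number of clockwise quarter turns (may be negative).
#' @return The rotated array.
#' @export
rotate90 <- function(img, turns = 1L) {
  img <- as_image_frame(img)
  turns <- ((turns %% 4L) + 4L) %% 4L
  if (turns == 0L) return(img)
  for (i in seq_len(turns)) {
    h <- dim(img)[1L]
    img <- aperm(img, c(2L, 1L, 3L))[, h:1, , drop = FALSE]
  }
  img
}

# Bilinear interpolation of `img` at continuous coordinates (y, x) (0-based,
# top-left origin). Sample points are clamped to the pixel-centre hull, so
# border lookups replicate edge pixels. Returns a length(y) x C matrix.
bilinear_sample <- function(img, y, x) {
  d <- dim(img)
  h <- d[1L]; w <- d[2L]; nc <- d[3L]
  yy <- clamp(y, 0.5, h - 0.5) - 0.5
  xx <- clamp(x, 0.5, w - 0.5) - 0.5
  y0 <- floor(yy); x0 <- floor(xx)
  fy <- yy - y0;  fx <- xx - x0
  r0 <- as.integer(y0) + 1L; c0 <- as.integer(x0) + 1L
  r1 <- pmin(r0 + 1L, h);    c1 <- pmin(c0 + 1L, w)
  w00 <- (1 - fy) * (1 - fx); w01 <- (1 - fy) * fx
  w10 <- fy * (1 - fx);       w11 <- fy * fx
  i00 <- r0 + (c0 - 1L) * h
  i01 <- r0 + (c1 - 1L) * h
  i10 <- r1 + (c0 - 1L) * h
  i11 <- r1 + (c1 - 1L) * h
  out <- matrix(0, length(yy), nc)
  plane <- h * w
  for (ch in seq_len(nc)) {
    off <- (ch - 1L) * plane
    out[, ch] <- w00 * img[i00 + off] + w01 * img[i01 + off] +
      w10 * img[i10 + off] + w11 * img[i11 + off]
  }
  out
}

#' Bilinear resize
#'
#' @param img An `H x W x 3` array.
#' @param out_h,out_w Output dimensions in pixels.
#' @return An `out_h x out_w x 3` array.
#' @export
resize_bilinear <- function(img, out_h, out_w) {
  img <- as_image_frame(img)
  d <- dim(img)
  if (d[1L] == out_h && d[2L] == out_w) return(img)
  ys <- (seq_len(out_h) - 0.5) * d[1L] / out_h
  xs <- (seq_len(out_w) - 0.5) * d[2L] / out_w
  yv <- rep(ys, times = out_w)
  xv <- rep(xs, each = out_h)
  vals <- bilinear_sample(img, yv, xv)
  array(vals, c(out_h, out_w, dim(img)[3L]))
}

# Solve for the 3x3 homography H mapping src (4x2, columns x, y) onto dst,
# with H[3,3] fixed at 1. Standard 8x8 linear system from the four
# point correspondences.
homography_from_points <- function(src, dst) {
  A <- matrix(0, 8L, 8L)
  b <- numeric(8L)
  for (i in 1:4) {
    x <- src[i, 1L]; y <- src[i, 2L]
    u <- dst[i, 1L]; v <- dst[i, 2L]
    A[2L * i - 1L, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2L * i, ]      <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2L * i - 1L] <- u
    b[2L * i] <- v
  }
  matrix(c(solve(A, b), 1), 3L, 3L, byrow = TRUE)
}

#' Projective (perspective) warp
#'
#' Resamples an image under a homography. Each output pixel centre is mapped
#' through `h_mat` into the source image and sampled bilinearly; source
#' lookups outside the image replicate the nearest edge pixel.
#'
#' @param img An `H x W x 3` array.
#' @param h_mat A 3x3 homography mapping output `(x, y, 1)` coordinates to
#'   source coordinates (0-based, top-left origin).
#' @return A warped array with the same dimensions as `img`.
#' @export
warp_perspective <- function(img, h_mat) {
  img <- as_image_frame(img)
  d <- dim(img)
  h <- d[1L]; w <- d[2L]
  xo <- rep(seq_len(w) - 0.5, each = h)
  yo <- rep(seq_len(h) - 0.5, times = w)
  den <- h_mat[3L, 1L] * xo + h_mat[3L, 2L] * yo + h_mat[3L, 3L]
  xs <- (h_mat[1L, 1L] * xo + h_mat[1L, 2L] * yo + h_mat[1L, 3L]) / den
  ys <- (h_mat[2L, 1L] * xo + h_mat[2L, 2L] * yo + h_mat[2L, 3L]) / den
  vals <- bilinear_sample(img, ys, xs)
  array(vals, d)
}

# One random "slight" perspective deformation: the four source corners are
# jittered independently by up to max_shift * side, and the full output
# quad resamples the jittered source quad. Consumes RNG draws from the
# current stream (callers wrap in with_seed()).
perspective_jitter <- function(img, max_shift = 0.1) {
  d <- dim(img)
  h <- d[1L]; w <- d[2L]
  corners <- matrix(c(0, 0, w, 0, w, h, 0, h), 4L, 2L, byrow = TRUE)
  jit <- matrix(stats::runif(8L, -max_shift, max_shift), 4L, 2L)
  jit[, 1L] <- jit[, 1L] * w
  jit[, 2L] <- jit[, 2L] * h
  warp_perspective(img, homography_from_points(corners, corners + jit))
}
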
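# Synthetic aerial scenes: procedurally drawn top-down cattle with offset
# shadows on pasture textures, plus seeded sprite banks emulating hand-cut
# training imagery. Everything is deterministic for a fixed seed.
#
# Sprites are drawn at a "native" ground resolution (a cow spans ~20 px, as
# seen from survey altitude) and tiles are then upsampled to the 64x64
# classifier input, so training tiles and detection windows share the same
# effective resolution.

# Pasture base colours (0..255 RGB) by seasonal style.
.pasture_base <- list(
  green = c(98, 132, 72),
  dry   = c(168, 150, 104)
)

# Coat palette for top-down cattle: brown, dark brown, black, white, tan.
.coat_palette <- list(
  brown = c(118, 78, 48),
  dark  = c(52, 42, 36),
  black = c(28, 26, 27),
  white = c(226, 221, 210),
  tan   = c(170, 124, 72)
)

# Bilinear resize of a plain matrix (used for coarse noise fields).
resize_matrix <- function(m, out_h, out_w) {
  a <- array(m, c(dim(m), 1L))
  ys <- (seq_len(out_h) - 0.5) * nrow(m) / out_h
  xs <- (seq_len(out_w) - 0.5) * ncol(m) / out_w
  vals <- bilinear_sample(a, rep(ys, times = out_w), rep(xs, each = out_h))
  matrix(vals[, 1L], out_h, out_w)
}

#' Render a pasture background texture
#'
#' Draws an `h x w` patch of seasonally coloured pasture: a style-dependent
#' base colour modulated by a smooth coarse luminance field (cell size about
#' 8 px, mimicking grass tussocks and bare patches) plus fine per-pixel
#' noise. Consumes draws from the current RNG stream; the exported
#' generators wrap it in a seeded context.
#'
#' @param h,w Patch dimensions in pixels.
#' @param style `"green"` or `"dry"` pasture.
#' @return An `h x w x 3` array of intensities in `[0, 255]`.
#' @export
render_background <- function(h, w, style = c("green", "dry")) {
  style <- match.arg(style)
  base <- .pasture_base[[style]] + stats::runif(3L, -10, 10)
  nh <- max(2L, as.integer(ceiling(h / 8)))
  nw <- max(2L, as.integer(ceiling(w / 8)))
  lum <- resize_matrix(matrix(stats::rnorm(nh * nw, 0, 13), nh, nw), h, w)
  out <- array(0, c(h, w, 3L))
  for (ch in 1:3) {
    hue <- resize_matrix(matrix(stats::rnorm(nh * nw, 0, 5), nh, nw), h, w)
    out[, , ch] <- base[ch] + lum + hue + stats::rnorm(h * w, 0, 4)
  }
  clamp(out, 0, 255)
}

# Draw one top-down cow: an ellipsoidal body with a head lobe, rotated by
# angle_deg, painted in coat_rgb with mild shading and pixel noise. Returns
# the sprite RGB, its soft alpha mask, and the square canvas size.
draw_cow <- function(size_px, angle_deg, coat_rgb) {
  s <- as.integer(ceiling(size_px * 1.4))
  if (s %% 2L == 0L) s <- s + 1L
  cx <- s / 2
  xo <- rep(seq_len(s) - 0.5, each = s) - cx
  yo <- rep(seq_len(s) - 0.5, times = s) - cx
  th <- angle_deg * pi / 180
  u <- cos(th) * xo + sin(th) * yo   # along body axis
  v <- -sin(th) * xo + cos(th) * yo  # across body
  a <- 0.40 * size_px
  b <- 0.17 * size_px
  hr <- 0.12 * size_px
  hc <- 0.44 * size_px
  d_body <- (u / a)^2 + (v / b)^2
  d_head <- ((u - hc) / hr)^2 + (v / hr)^2
  dmin <- pmin(d_body, d_head)
  mask <- matrix(clamp((1.12 - dmin) / 0.24, 0, 1), s, s)
  shade <- matrix(1 + 0.12 * (1 - clamp(d_body, 0, 1)), s, s)
  rgb <- array(0, c(s, s, 3L))
  for (ch in 1:3)
    rgb[, , ch] <- clamp(coat_rgb[ch] * shade + stats::rnorm(s * s, 0, 6), 0, 255)
  list(rgb = rgb, mask = mask, canvas = s)
}

# Sheared, slightly shrunk copy of a silhouette mask, used as the shadow
# alpha. The shear emulates a low sun angle projecting the body sideways.
shear_mask <- function(mask, shear = 0.35, scale = 0.92) {
  s <- nrow(mask)
  c0 <- s / 2
  xo <- rep(seq_len(s) - 0.5, each = s) - c0
  yo <- rep(seq_len(s) - 0.5, times = s) - c0
  # inverse map of x' = scale * (x + shear * y), y' = scale * y
  xs <- xo / scale - shear * (yo / scale) + c0
  ys <- yo / scale + c0
  vals <- bilinear_sample(array(mask, c(s, s, 1L)), ys, xs)
  matrix(vals[, 1L], s, s)
}

# Alpha-composite a sprite (and optionally its shadow) onto `frame` with the
# sprite centre at continuous 0-based (cx, cy). Shadows darken the
# underlying texture multiplicatively; the body is painted over the result.
composite_sprite <- function(frame, cow, cx, cy, shadow_offset = c(0, 0),
                             shadow_strength = 0.45) {
  s <- cow$canvas
  paste_alpha <- function(frame, alpha, rgb, left, top, darken_only) {
    h <- dim(frame)[1L]; w <- dim(frame)[2L]
    rows <- (top + 1L):(top + s)
    cols <- (left + 1L):(left + s)
    keep_r <- rows >= 1L & rows <= h
    keep_c <- cols >= 1L & cols <= w
    if (!any(keep_r) || !any(keep_c)) return(frame)
    a <- alpha[keep_r, keep_c, drop = FALSE]
    sub <- frame[rows[keep_r], cols[keep_c], , drop = FALSE]
    if (darken_only) {
      for (ch in 1:3) sub[, , ch] <- sub[, , ch] * (1 - shadow_strength * a)
    } else {
      rg <- rgb[keep_r, keep_c, , drop = FALSE]
      for (ch in 1:3) sub[, , ch] <- sub[, , ch] * (1 - a) + rg[, , ch] * a
    }
    frame[rows[keep_r], cols[keep_c], ] <- sub
    frame
  }
  left <- as.integer(round(cx - s / 2))
  top  <- as.integer(round(cy - s / 2))
  sh <- shear_mask(cow$mask)
  frame <- paste_alpha(frame, sh, NULL,
                       left + as.integer(round(shadow_offset[1L])),
                       top + as.integer(round(shadow_offset[2L])),
                       darken_only = TRUE)
  paste_alpha(frame, cow$mask, cow$rgb, left, top, darken_only = FALSE)
}

# Sample a coat colour whose mean absolute channel difference from the
# pasture base colour is at least min_contrast, so sprites carry signal.
pick_coat <- function(style, min_contrast) {
  base <- .pasture_base[[style]]
  for (i in 1:50) {
    coat <- .coat_palette[[sample.int(length(.coat_palette), 1L)]]
    if (mean(abs(coat - base)) >= min_contrast) return(coat + stats::runif(3L, -8, 8))
  }
  .coat_palette$black
}

#' Generate a sprite bank
#'
#' Renders `n_per_class` images in each of three source classes — cattle
#' (body plus its own shadow on pasture), bare shadows on pasture (hard
#' negatives), and pasture backgrounds — emulating tiles hand-cut from
#' nadir UAV footage at survey altitude. Each tile is drawn at native
#' resolution (`native_px`) and upsampled to `tile_px`.
#'
#' @param n_per_class Number of images per class (positive integer).
#' @param seed Integer seed; identical `(n_per_class, seed)` calls return
#'   byte-identical banks.
#' @param native_px Native (pre-upsampling) tile side in pixels.
#' @param tile_px Output tile side in pixels.
#' @param styles Pasture styles to draw from.
#' @param min_contrast Minimum mean absolute channel difference between a
#'   coat colour and the pasture base colour.
#' @return A `sprite_bank`: lists `animals`, `shadows`, `backgrounds`, each
#'   element holding `image` (a `tile_px x tile_px x 3` array in
#'   `[0, 255]`), `size_px` and `angle` metadata.
#' @export
render_sprite_bank <- function(n_per_class, seed = 1L, native_px = 32L,
                               tile_px = 64L, styles = c("green", "dry"),
                               min_contrast = 30) {
  if (!is_count(n_per_class, min = 1L))
    stop("`n_per_class` must be a positive integer", call. = FALSE)
  with_seed(seed, {
    # Every tile is drawn at a jittered native resolution (emulating
    # recordings at different heights) and then upsampled to tile_px, so
    # the classifier sees the range of resampling factors the detector's
    # 85%/100%/115% windows produce.
    jitter_native <- function() {
      max(12L, as.integer(round(native_px * stats::runif(1L, 0.8, 1.25))))
    }
    one_animal <- function() {
      style <- styles[sample.int(length(styles), 1L)]
      np <- jitter_native()
      bg <- render_background(np, np, style)
      # wide size and position jitter: for the boosting step to accumulate
      # neighborhood support, windows with the animal well off-centre
      # (even partially outside) must still classify as target
      size <- 0.62 * np * stats::runif(1L, 0.7, 1.3)
      angle <- stats::runif(1L, 0, 360)
      cow <- draw_cow(size, angle, pick_coat(style, min_contrast))
      cx <- np / 2 + stats::runif(1L, -0.38, 0.38) * np
      cy <- np / 2 + stats::runif(1L, -0.38, 0.38) * np
      sa <- stats::runif(1L, 0, 2 * pi)
      off <- 0.25 * size * c(cos(sa), sin(sa))
      img <- composite_sprite(bg, cow, cx, cy, shadow_offset = off)
      list(image = resize_bilinear(img, tile_px, tile_px),
           size_px = size * tile_px / np, angle = angle)
    }
    one_shadow <- function() {
      style <- styles[sample.int(length(styles), 1L)]
      np <- jitter_native()
      bg <- render_background(np, np, style)
      size <- 0.62 * np * stats::runif(1L, 0.85, 1.15)
      angle <- stats::runif(1L, 0, 360)
      cow <- draw_cow(size, angle, .coat_palette$black)
      sh <- shear_mask(cow$mask)
      s <- cow$canvas
      left <- as.integer(round(np / 2 - s / 2 +
                                 stats::runif(1L, -0.1, 0.1) * np))
      top <- as.integer(round(np / 2 - s / 2 +
                                stats::runif(1L, -0.1, 0.1) * np))
      img <- bg
      rows <- (top + 1L):(top + s); cols <- (left + 1L):(left + s)
      kr <- rows >= 1L & rows <= np
      kc <- cols >= 1L & cols <= np
      if (any(kr) && any(kc)) {
        a <- sh[kr, kc, drop = FALSE]
        sub <- img[rows[kr], cols[kc], , drop = FALSE]
        for (ch in 1:3) sub[, , ch] <- sub[, , ch] * (1 - 0.45 * a)
        img[rows[kr], cols[kc], ] <- sub
      }
      list(image = resize_bilinear(img, tile_px, tile_px),
           size_px = size * tile_px / np, angle = angle)
    }
    one_background <- function() {
      style <- styles[sample.int(length(styles), 1L)]
      np <- jitter_native()
      img <- render_background(np, np, style)
      list(image = resize_bilinear(img, tile_px, tile_px),
           size_px = NA_real_, angle = NA_real_)
    }
    bank <- list(
      animals = lapply(seq_len(n_per_class), function(i) one_animal()),
      shadows = lapply(seq_len(n_per_class), function(i) one_shadow()),
      backgrounds = lapply(seq_len(n_per_class), function(i) one_background()),
      n_per_class = as.integer(n_per_class),
      tile_px = as.integer(tile_px),
      native_px = as.integer(native_px),
      seed = as.integer(seed)
    )
    class(bank) <- "sprite_bank"
    bank
  })
}

#' @export
print.sprite_bank <- function(x, ...) {
  cat("Sprite bank:", x$n_per_class, "images per class",
      "(animals, shadows, backgrounds)\n")
  cat("  tile size:", x$tile_px, "px (drawn at", x$native_px,
      "px native), seed", x$seed, "\n")
  invisible(x)
}

#' Specify a synthetic aerial scene
#'
#' Bundles the parameters of one synthetic nadir frame: dimensions, the
#' number of cattle, their pixel size (the on-the-ground length as imaged
#' from survey altitude), shadow offset, pasture style and a seed. The
#' default minimum centre-to-centre separation (4.5 body lengths) keeps
#' animals well separated so ground-truth counts are unambiguous: detection
#' masks dilate by one grid cell on each side of a firing window, so blobs
#' from animals closer than about three window widths can touch and merge.
#'
#' @param frame_width,frame_height Frame dimensions in pixels (at least 64).
#' @param n_animals Number of cattle to place (non-negative).
#' @param animal_size_px Mean body length in pixels.
#' @param size_jitter Relative spread of body length (uniform +/- fraction).
#' @param shadow_offset Shadow displacement `(dx, dy)` in pixels.
#' @param background_style `"green"` or `"dry"` pasture.
#' @param min_separation Minimum distance between animal centres in pixels.
#' @param min_contrast Minimum coat-to-pasture contrast (see
#'   [render_sprite_bank()]).
#' @param seed Integer seed.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(frame_width = 256L, frame_height = 256L,
                       n_animals = 5L, animal_size_px = 20,
                       size_jitter = 0.12, shadow_offset = c(6, 4),
                       background_style = c("green", "dry"),
                       min_separation = NULL, min_contrast = 30,
                       seed = 1L) {
  background_style <- match.arg(background_style)
  if (!is_count(n_animals)) stop("`n_animals` must be a non-negative integer", call. = FALSE)
  if (!is_number(animal_size_px) || animal_size_px <= 0)
    stop("`animal_size_px` must be positive", call. = FALSE)
  if (!is_count(frame_width, 64L) || !is_count(frame_height, 64L))
    stop("frame dimensions must be at least 64 px", call. = FALSE)
  if (is.null(min_separation)) min_separation <- 4.5 * animal_size_px
  structure(list(
    frame_width = as.integer(frame_width),
    frame_height = as.integer(frame_height),
    n_animals = as.integer(n_animals),
    animal_size_px = animal_size_px,
    size_jitter = size_jitter,
    shadow_offset = shadow_offset,
    background_style = background_style,
    min_separation = min_separation,
    min_contrast = min_contrast,
    seed = as.integer(seed)
  ), class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("Scene spec: %d x %d px, %d animals of ~%.0f px (%s pasture), seed %d\n",
              x$frame_width, x$frame_height, x$n_animals, x$animal_size_px,
              x$background_style, x$seed))
  invisible(x)
}

#' Render a synthetic aerial scene with ground truth
#'
#' Composites `n_animals` procedurally drawn cattle (each with an offset
#' shadow) onto a pasture texture. Placements are rejection-sampled so that
#' sprite bounding boxes do not overlap and centres respect
#' `spec$min_separation`; if a sprite cannot be placed within
#' `max_attempts` tries the function fails with a placement error.
#'
#' @param spec A [scene_spec()].
#' @param max_attempts Placement attempts per sprite before the layout is
#'   abandoned.
#' @param max_restarts Fresh layout attempts before giving up entirely.
#' @return A `scene`: list with `frame` (`H x W x 3` array), `truth`
#'   (list of `centers` — an `n x 2` matrix of 0-based `(x, y)` pixel
#'   coordinates — `sizes` and `count`), and the `spec`.
#' @export
render_scene <- function(spec, max_attempts = 1000L, max_restarts = 200L) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    fw <- spec$frame_width; fh <- spec$frame_height
    so <- spec$shadow_offset
    background <- render_background(fh, fw, spec$background_style)
    # sequential rejection sampling can dead-end on crowded layouts, so a
    # failed layout is discarded and re-drawn from scratch
    for (restart in seq_len(max_restarts)) {
      frame <- background
      centers <- matrix(numeric(0), 0L, 2L)
      sizes <- numeric(0)
      boxes <- matrix(numeric(0), 0L, 4L)  # x0, y0, x1, y1
      failed <- FALSE
      for (k in seq_len(spec$n_animals)) {
        size_k <- spec$animal_size_px *
          (1 + stats::runif(1L, -spec$size_jitter, spec$size_jitter))
        angle <- stats::runif(1L, 0, 360)
        coat <- pick_coat(spec$background_style, spec$min_contrast)
        cow <- draw_cow(size_k, angle, coat)
        half <- cow$canvas / 2
        margin <- half + max(abs(so)) + 1
        if (2 * margin >= min(fw, fh))
          stop("placement failure: frame too small for sprite of size ",
               round(size_k), " px", call. = FALSE)
        placed <- FALSE
        for (att in seq_len(max_attempts)) {
          cx <- stats::runif(1L, margin, fw - margin)
          cy <- stats::runif(1L, margin, fh - margin)
          box <- c(cx - half + min(0, so[1L]), cy - half + min(0, so[2L]),
                   cx + half + max(0, so[1L]), cy + half + max(0, so[2L]))
          ok <- TRUE
          if (nrow(centers) > 0L) {
            d2 <- (centers[, 1L] - cx)^2 + (centers[, 2L] - cy)^2
            if (any(d2 < spec$min_separation^2)) ok <- FALSE
            if (ok && any(boxes[, 1L] <= box[3L] & boxes[, 3L] >= box[1L] &
                          boxes[, 2L] <= box[4L] & boxes[, 4L] >= box[2L]))
              ok <- FALSE
          }
          if (ok) {
            frame <- composite_sprite(frame, cow, cx, cy, shadow_offset = so)
            centers <- rbind(centers, c(cx, cy))
            sizes <- c(sizes, size_k)
            boxes <- rbind(boxes, box)
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          failed <- TRUE
          break
        }
      }
      if (!failed) break
      if (restart == max_restarts)
        stop("placement failure: could not place ", spec$n_animals,
             " sprites in a ", fw, " x ", fh, " frame after ", max_restarts,
             " layout attempts", call. = FALSE)
    }
    colnames(centers) <- c("x", "y")
    structure(list(frame = frame,
                   truth = list(centers = centers, sizes = sizes,
                                count = nrow(centers)),
                   spec = spec),
              class = "scene")
  })
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("Synthetic scene: %d x %d px, %d animals, seed %d\n",
              x$spec$frame_width, x$spec$frame_height, x$truth$count,
              x$spec$seed))
  invisible(x)
}

#' Write a scene to PNG with a JSON ground-truth sidecar
#'
#' Coordinates in the sidecar are 0-based pixels, origin at the top-left,
#' x rightward and y downward.
#'
#' @param scene A `scene` from [render_scene()].
#' @param png_path Output PNG path.
#' @param json_path Output JSON path; defaults to `png_path` with a `.json`
#'   extension.
#' @return Invisibly, the two paths.
#' @export
write_scene <- function(scene, png_path, json_path = NULL) {
  stopifnot(inherits(scene, "scene"))
  if (is.null(json_path)) json_path <- sub("\\.png$", ".json", png_path)
  write_frame_png(scene$frame, png_path)
  gt <- list(centers = unname(scene$truth$centers),
             sizes = scene$truth$sizes,
             count = scene$truth$count)
  jsonlite::write_json(gt, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(png = png_path, json = json_path))
}

#' Read a ground-truth sidecar
#'
#' @param path Path to a JSON sidecar written by [write_scene()].
#' @return A list with `centers` (matrix), `sizes` and `count`.
#' @export
read_ground_truth <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  centers <- gt$centers
  if (is.null(centers) || length(centers) == 0L) {
    centers <- matrix(numeric(0), 0L, 2L)
  } else {
    centers <- matrix(as.numeric(centers), ncol = 2L)
  }
  colnames(centers) <- c("x", "y")
  list(centers = centers, sizes = as.numeric(gt$sizes), count = as.integer(gt$count))
}
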
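# Multi-scale sliding-window detection: an altitude-derived mid-range
# window size, satellite scales at 85% and 115%, a lattice of per-window
# target probabilities L[x, y, s], neighborhood boosting into B[x, y]
# (sum of the >= 1/2 readings over the 3x3 spatial neighborhood and all
# three scales), ad hoc thresholding into a binary mask, and 8-connected
# component labeling whose component count is the animal count.

#' Camera model for scale selection
#'
#' Holds the nadir-camera geometry used to derive the mid-range window
#' size: horizontal field of view, flight altitude, image resolution and
#' the nominal on-the-ground target length (2.5 m for adult cattle).
#'
#' @param horizontal_fov Horizontal field of view in degrees (0, 180).
#' @param altitude Flight altitude in metres (positive).
#' @param image_width,image_height Frame resolution in pixels.
#' @param nominal_target_length Target length in metres (default 2.5).
#' @return A `camera_model` object.
#' @export
camera_model <- function(horizontal_fov, altitude, image_width, image_height,
                         nominal_target_length = 2.5) {
  if (!is_number(horizontal_fov) || horizontal_fov <= 0 || horizontal_fov >= 180)
    stop("`horizontal_fov` must be in (0, 180) degrees", call. = FALSE)
  if (!is_number(altitude) || altitude <= 0)
    stop("`altitude` must be positive", call. = FALSE)
  if (!is_count(image_width, 1L) || !is_count(image_height, 1L))
    stop("image dimensions must be positive integers", call. = FALSE)
  if (!is_number(nominal_target_length) || nominal_target_length <= 0)
    stop("`nominal_target_length` must be positive", call. = FALSE)
  structure(list(horizontal_fov = horizontal_fov, altitude = altitude,
                 image_width = as.integer(image_width),
                 image_height = as.integer(image_height),
                 nominal_target_length = nominal_target_length),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("Camera: %g deg HFOV at %g m, %d x %d px, target %g m\n",
              x$horizontal_fov, x$altitude, x$image_width, x$image_height,
              x$nominal_target_length))
  invisible(x)
}

#' Mid-range window size from flight geometry
#'
#' The ground width imaged by the frame is `2 * h * tan(fov / 2)`, so a
#' target of length `L` metres spans `L * image_width / (2 * h *
#' tan(fov / 2))` pixels. The result is rounded, clamped to at least 8 px,
#' and must fit inside the frame (otherwise the altitude is too low for
#' the tile classifier to see a whole animal).
#'
#' @param cam A [camera_model()].
#' @return The mid-range window side in pixels.
#' @export
mid_scale_window <- function(cam) {
  stopifnot(inherits(cam, "camera_model"))
  ground_width <- 2 * cam$altitude * tan(cam$horizontal_fov * pi / 360)
  w <- round(cam$nominal_target_length * cam$image_width / ground_width)
  w <- max(w, 8)
  if (w > min(cam$image_width, cam$image_height))
    stop(sprintf("altitude too low: window of %d px exceeds the %d x %d frame",
                 w, cam$image_width, cam$image_height), call. = FALSE)
  as.integer(w)
}

#' The three scan scales
#'
#' Window sizes at 85%, 100% and 115% of the mid-range size, rounded to
#' whole pixels; strictly increasing for any `w_mid >= 8`.
#'
#' @param w_mid Mid-range window side in pixels (at least 8).
#' @return An increasing integer vector of three window sizes.
#' @export
scan_scales <- function(w_mid) {
  if (!is_count(w_mid, 8L)) stop("`w_mid` must be an integer >= 8", call. = FALSE)
  as.integer(c(round(0.85 * w_mid), w_mid, round(1.15 * w_mid)))
}

#' Build the sliding-window scan grid
#'
#' Window centres form a regular lattice with the given stride such that
#' the mid-scale window fits entirely inside the frame at every centre;
#' all three scales share the same centres. The default stride is half the
#' mid-range window (adjacent, overlapping windows).
#'
#' @param frame_w,frame_h Frame dimensions in pixels.
#' @param w_mid Mid-range window side (must fit in the frame).
#' @param stride Centre spacing in pixels (default `round(w_mid / 2)`,
#'   at least 1).
#' @return A `scan_grid`: window sizes, stride, centre coordinate vectors
#'   `cx`, `cy` (0-based continuous pixels) and `grid_shape = c(nx, ny)`.
#' @export
build_grid <- function(frame_w, frame_h, w_mid, stride = NULL) {
  if (!is_count(w_mid, 8L)) stop("`w_mid` must be an integer >= 8", call. = FALSE)
  if (w_mid > min(frame_w, frame_h))
    stop("window larger than frame", call. = FALSE)
  if (is.null(stride)) stride <- max(1L, as.integer(round(w_mid / 2)))
  if (!is_count(stride, 1L)) stop("`stride` must be a positive integer", call. = FALSE)
  nx <- as.integer((frame_w - w_mid) %/% stride + 1L)
  ny <- as.integer((frame_h - w_mid) %/% stride + 1L)
  structure(list(window_sizes = scan_scales(w_mid), w_mid = as.integer(w_mid),
                 stride = as.integer(stride),
                 cx = w_mid / 2 + stride * (seq_len(nx) - 1L),
                 cy = w_mid / 2 + stride * (seq_len(ny) - 1L),
                 grid_shape = c(nx = nx, ny = ny),
                 frame_w = as.integer(frame_w),
                 frame_h = as.integer(frame_h)),
            class = "scan_grid")
}

#' @export
print.scan_grid <- function(x, ...) {
  cat(sprintf("Scan grid: %d x %d centres, stride %d px, windows [%s] px\n",
              x$grid_shape[["nx"]], x$grid_shape[["ny"]], x$stride,
              paste(x$window_sizes, collapse = ", ")))
  invisible(x)
}

# Extract every window of side w_s centred on the grid, clipped to the
# frame and resampled bilinearly to tile_px x tile_px. Returns an
# [n_centres, tile_px, tile_px, 3] array with centres ordered x-fastest
# (matching the L lattice layout).
extract_windows <- function(frame, grid, w_s, tile_px = 64L) {
  nx <- grid$grid_shape[["nx"]]; ny <- grid$grid_shape[["ny"]]
  n <- nx * ny
  cxv <- rep(grid$cx, times = ny)
  cyv <- rep(grid$cy, each = nx)
  half <- w_s / 2
  x0 <- pmax(cxv - half, 0); x1 <- pmin(cxv + half, grid$frame_w)
  y0 <- pmax(cyv - half, 0); y1 <- pmin(cyv + half, grid$frame_h)
  f <- (seq_len(tile_px) - 0.5) / tile_px
  xs <- x0 + outer(x1 - x0, f)       # n x tile_px, sample columns
  ys <- y0 + outer(y1 - y0, f)       # n x tile_px, sample rows
  # expand to (window, row v, col u) with window fastest
  i_full <- rep(seq_len(n), times = tile_px * tile_px)
  v_full <- rep(rep(seq_len(tile_px), times = tile_px), each = n)
  u_full <- rep(seq_len(tile_px), each = n * tile_px)
  vals <- bilinear_sample(frame,
                          ys[i_full + (v_full - 1L) * n],
                          xs[i_full + (u_full - 1L) * n])
  array(vals, c(n, tile_px, tile_px, 3L))
}

# Normalise a classifier argument: a trained tile_cnn or a function taking
# an [n, S, S, 3] crop array (0..255) and returning target probabilities.
as_classifier <- function(net, batch_size = 48L) {
  if (inherits(net, "tile_cnn")) {
    if (!isTRUE(net$trained))
      stop("model error: the network has not been trained", call. = FALSE)
    function(crops) predict(net, crops, type = "prob",
                            batch_size = batch_size)[, "target"]
  } else if (is.function(net)) {
    function(crops) {
      p <- net(crops)
      if (is.matrix(p)) p <- p[, ncol(p)]
      as.numeric(p)
    }
  } else {
    stop("`net` must be a trained tile_cnn or a classifier function",
         call. = FALSE)
  }
}

#' Compute the probability lattice L[x, y, s]
#'
#' For every grid coordinate and scale, crops the window (clipped to the
#' frame, resampled to the classifier input size), runs the classifier and
#' stores the target-class probability. The result is a discrete lattice
#' of target probabilities over the frame.
#'
#' @param net A trained `tile_cnn`, or a function mapping an
#'   `[n, S, S, 3]` crop array (intensities 0..255) to a vector of target
#'   probabilities (useful for oracle classifiers in testing).
#' @param frame An `H x W x 3` frame.
#' @param grid A [build_grid()] result for this frame.
#' @param batch_size Classifier batch size.
#' @return A `prob_grid`: list with `L` (an `nx x ny x 3` array of
#'   probabilities in `[0, 1]`) and the `grid`.
#' @export
compute_prob_grid <- function(net, frame, grid, batch_size = 48L) {
  stopifnot(inherits(grid, "scan_grid"))
  frame <- as_image_frame(frame)
  if (dim(frame)[1L] != grid$frame_h || dim(frame)[2L] != grid$frame_w)
    stop("frame dimensions do not match the scan grid", call. = FALSE)
  classify <- as_classifier(net, batch_size)
  tile_px <- if (inherits(net, "tile_cnn")) net$spec$input_size else 64L
  nx <- grid$grid_shape[["nx"]]; ny <- grid$grid_shape[["ny"]]
  L <- array(0, c(nx, ny, 3L))
  for (s in 1:3) {
    crops <- extract_windows(frame, grid, grid$window_sizes[s], tile_px)
    L[, , s] <- classify(crops)
  }
  structure(list(L = L, grid = grid), class = "prob_grid")
}

#' Boost the probability lattice
#'
#' `B[x, y]` is the sum, over the 3x3 spatial neighborhood of `(x, y)` and
#' all three scales, of the lattice values that are at least 1/2; values
#' below 1/2 contribute zero, as do neighbours outside the grid. `B` is
#' therefore bounded by 27. The 27 gated terms are accumulated in a fixed
#' (i, j, s) order, so the result is bit-identical to a literal scalar
#' triple-sum transcription.
#'
#' @param L A `prob_grid` or a bare `nx x ny x 3` array.
#' @return A `boost_grid`: list with `B` (`nx x ny` matrix) and the `grid`
#'   if one was attached to `L`.
#' @export
boost <- function(L) {
  grid <- NULL
  if (inherits(L, "prob_grid")) {
    grid <- L$grid
    L <- L$L
  }
  if (!is.array(L) || length(dim(L)) != 3L || dim(L)[3L] != 3L)
    stop("`L` must be an nx x ny x 3 lattice", call. = FALSE)
  nx <- dim(L)[1L]; ny <- dim(L)[2L]
  # zero-padded gated lattice, summed over the 9 spatial shifts and 3
  # scales in (i, j, s) loop order
  G <- array(0, c(nx + 2L, ny + 2L, 3L))
  G[2:(nx + 1L), 2:(ny + 1L), ] <- L * (L >= 0.5)
  B <- matrix(0, nx, ny)
  for (di in 0:2) for (dj in 0:2) for (s in 1:3)
    B <- B + G[di + seq_len(nx), dj + seq_len(ny), s]
  structure(list(B = B, grid = grid, threshold = NA_real_, mask = NULL),
            class = "boost_grid")
}

#' Quantize a boosted lattice into a binary mask
#'
#' Applies the ad hoc detection threshold: `mask[x, y] = 1` iff
#' `B[x, y] >= threshold`. The default of 4.5 demands several mutually
#' reinforcing >= 1/2 readings in a neighborhood, which removes isolated
#' single-window activations.
#'
#' @param B A `boost_grid` or a bare non-negative matrix.
#' @param threshold Non-negative detection threshold (default 4.5).
#' @return An integer 0/1 matrix of the same shape as `B`.
#' @export
quantize <- function(B, threshold = 4.5) {
  if (!is_number(threshold) || threshold < 0)
    stop("`threshold` must be non-negative", call. = FALSE)
  if (inherits(B, "boost_grid")) B <- B$B
  mask <- matrix(as.integer(B >= threshold), nrow(B), ncol(B))
  mask
}

# Two-pass 8-connected labeling with union-find. Returns a label matrix
# with components renumbered 1..count in scan order.
label_components <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  labels <- matrix(0L, nx, ny)
  parent <- integer(0L)
  find_root <- function(a) {
    while (parent[a] != a) a <- parent[a]
    a
  }
  next_lab <- 0L
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    if (!mask[i, j]) next
    nb <- c(if (i > 1L) labels[i - 1L, j],
            if (j > 1L) labels[i, j - 1L],
            if (i > 1L && j > 1L) labels[i - 1L, j - 1L],
            if (i < nx && j > 1L) labels[i + 1L, j - 1L])
    nb <- nb[nb > 0L]
    if (!length(nb)) {
      next_lab <- next_lab + 1L
      parent[next_lab] <- next_lab
      labels[i, j] <- next_lab
    } else {
      roots <- unique(vapply(nb, find_root, integer(1L)))
      r <- min(roots)
      labels[i, j] <- r
      for (o in roots[roots != r]) parent[o] <- r
    }
  }
  if (next_lab == 0L) return(labels)
  # resolve and renumber in order of first appearance
  roots <- vapply(seq_len(next_lab), find_root, integer(1L))
  final <- integer(next_lab)
  count <- 0L
  pos <- which(labels > 0L)
  for (p in pos) {
    r <- roots[labels[p]]
    if (final[r] == 0L) {
      count <- count + 1L
      final[r] <- count
    }
    labels[p] <- final[r]
  }
  labels
}

#' Count animals by connected-component labeling
#'
#' Labels 8-connected regions of a binary detection mask; the number of
#' regions is the animal count. Per-component grid bounding boxes and
#' centroids are reported, and back-projected to pixel coordinates when a
#' scan grid is supplied.
#'
#' @param mask A binary (0/1 or logical) matrix indexed `[x, y]`.
#' @param grid Optional [build_grid()] result for pixel back-projection.
#' @param frame_id Optional identifier carried into the result.
#' @return A `detection_result`: list with `components` (a data frame of
#'   label, cell count, grid bbox `gx0..gy1`, grid centroid, and pixel
#'   bbox/centroid when `grid` is given; 0-based pixel coordinates),
#'   `count`, `labels` matrix and `frame_id`.
#' @export
count_components <- function(mask, grid = NULL, frame_id = NA) {
  if (is.logical(mask)) mask <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  labels <- label_components(mask)
  count <- max(labels, 0L)
  comp <- vector("list", count)
  for (k in seq_len(count)) {
    cells <- which(labels == k, arr.ind = TRUE)
    gx <- cells[, 1L]; gy <- cells[, 2L]
    row <- data.frame(label = k, n_cells = nrow(cells),
                      gx0 = min(gx), gy0 = min(gy),
                      gx1 = max(gx), gy1 = max(gy),
                      gcx = mean(gx), gcy = mean(gy))
    if (!is.null(grid)) {
      half <- grid$w_mid / 2
      row$cx <- half + grid$stride * (row$gcx - 1)
      row$cy <- half + grid$stride * (row$gcy - 1)
      row$px0 <- grid$cx[row$gx0] - half
      row$py0 <- grid$cy[row$gy0] - half
      row$px1 <- grid$cx[row$gx1] + half
      row$py1 <- grid$cy[row$gy1] + half
    }
    comp[[k]] <- row
  }
  components <- if (count) do.call(rbind, comp) else
    data.frame(label = integer(0L), n_cells = integer(0L),
               gx0 = integer(0L), gy0 = integer(0L),
               gx1 = integer(0L), gy1 = integer(0L),
               gcx = numeric(0L), gcy = numeric(0L))
  structure(list(components = components, count = count, labels = labels,
                 frame_id = frame_id),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("Detection%s: %d animal%s\n",
              if (is.na(x$frame_id)) "" else paste0(" (frame ", x$frame_id, ")"),
              x$count, if (x$count == 1L) "" else "s"))
  if (x$count > 0L) print(x$components, row.names = FALSE)
  invisible(x)
}

#' Detect and count animals in one frame
#'
#' Runs the full per-frame pipeline: mid-range window from the camera
#' geometry, the three scan scales, grid construction, the probability
#' lattice, boosting, thresholding and component counting. The
#' intermediate lattices are attached to the result for inspection and
#' plotting.
#'
#' @param net A trained `tile_cnn` or classifier function (see
#'   [compute_prob_grid()]).
#' @param frame An `H x W x 3` frame.
#' @param cam A [camera_model()]; ignored if `w_mid` is given.
#' @param stride Grid stride in pixels (default half the mid window).
#' @param threshold Quantization threshold (default 4.5).
#' @param w_mid Override the altitude-derived mid window size.
#' @param batch_size Classifier batch size.
#' @param frame_id Optional identifier carried into the result.
#' @return A `detection_result` with `prob_grid`, `boost_grid`, `mask`,
#'   `grid` and `frame` attached.
#' @export
detect_frame <- function(net, frame, cam = NULL, stride = NULL,
                         threshold = 4.5, w_mid = NULL, batch_size = 48L,
                         frame_id = NA) {
  frame <- as_image_frame(frame)
  if (is.null(w_mid)) {
    if (is.null(cam)) stop("supply a camera model or `w_mid`", call. = FALSE)
    w_mid <- mid_scale_window(cam)
  }
  grid <- build_grid(dim(frame)[2L], dim(frame)[1L], w_mid, stride)
  pg <- compute_prob_grid(net, frame, grid, batch_size = batch_size)
  bg <- boost(pg)
  mask <- quantize(bg, threshold)
  res <- count_components(mask, grid = grid, frame_id = frame_id)
  res$prob_grid <- pg
  res$boost_grid <- bg
  res$mask <- mask
  res$grid <- grid
  res$threshold <- threshold
  res$frame <- frame
  res
}

#' Sweep the quantization threshold on validation scenes
#'
#' The detection threshold is application-specific ("ad hoc"); this helper
#' scores a set of candidate thresholds on ground-truthed scenes by exact
#' count recovery and returns the per-threshold accuracy.
#'
#' @param net A trained `tile_cnn` or classifier function.
#' @param scenes A list of `scene` objects (see [render_scene()]).
#' @param thresholds Candidate thresholds.
#' @param cam A [camera_model()], or `NULL` with `w_mid` supplied.
#' @param w_mid,stride Passed to [detect_frame()].
#' @return A data frame of `threshold` and `count_accuracy`, with the best
#'   threshold in attribute `"best"`.
#' @export
tune_threshold <- function(net, scenes, thresholds = seq(1, 15, by = 0.5),
                           cam = NULL, w_mid = NULL, stride = NULL) {
  # score all thresholds from one boosted lattice per scene
  boosted <- lapply(seq_along(scenes), function(i) {
    sc <- scenes[[i]]
    det <- detect_frame(net, sc$frame, cam = cam, w_mid = w_mid,
                        stride = stride, frame_id = i)
    list(bg = det$boost_grid, truth = sc$truth$count)
  })
  acc <- vapply(thresholds, function(th) {
    hits <- vapply(boosted, function(b) {
      count_components(quantize(b$bg, th))$count == b$truth
    }, logical(1L))
    mean(hits)
  }, numeric(1L))
  out <- data.frame(threshold = thresholds, count_accuracy = acc)
  attr(out, "best") <- thresholds[which.max(acc)]
  out
}

#' Plot the detection stages of a frame
#'
#' Four panels: the input frame; the probability lattice (maximum over the
#' three scales); the boosted lattice; and the frame overlaid with
#' detected component boxes.
#'
#' @param x A `detection_result` from [detect_frame()].
#' @param ... Unused.
#' @export
plot.detection_result <- function(x, ...) {
  if (is.null(x$frame)) stop("result has no attached frame", call. = FALSE)
  op <- graphics::par(mfrow = c(2L, 2L), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  show_frame <- function(main) {
    graphics::plot.new()
    graphics::plot.window(c(0, dim(x$frame)[2L]), c(dim(x$frame)[1L], 0),
                          asp = 1)
    graphics::rasterImage(x$frame / 255, 0, dim(x$frame)[1L],
                          dim(x$frame)[2L], 0)
    graphics::title(main)
  }
  show_lattice <- function(m, main) {
    graphics::image(seq_len(nrow(m)), seq_len(ncol(m)),
                    m[, ncol(m):1, drop = FALSE], axes = FALSE,
                    xlab = "", ylab = "", col = grDevices::hcl.colors(32))
    graphics::title(main)
  }
  show_frame("frame")
  show_lattice(apply(x$prob_grid$L, c(1L, 2L), max), "probability lattice")
  show_lattice(x$boost_grid$B, "boosted lattice")
  show_frame(sprintf("detections (count = %d)", x$count))
  if (x$count > 0L) {
    graphics::rect(x$components$px0, x$components$py1,
                   x$components$px1, x$components$py0,
                   border = "red", lwd = 2)
  }
  invisible(x)
}
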
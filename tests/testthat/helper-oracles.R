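# Independent reference implementations used as test oracles. These are
# deliberately written along different routes than the package code.

# Literal scalar transcription of the boosting rule: for each (x, y), sum
# L[i, j, s] over the 3x3 spatial neighborhood and all scales, counting
# only values >= 1/2; out-of-grid neighbours contribute 0.
boost_oracle <- function(L) {
  nx <- dim(L)[1L]; ny <- dim(L)[2L]
  B <- matrix(0, nx, ny)
  for (x in seq_len(nx)) for (y in seq_len(ny)) {
    acc <- 0
    for (i in (x - 1L):(x + 1L)) for (j in (y - 1L):(y + 1L)) for (s in 1:3) {
      if (i < 1L || i > nx || j < 1L || j > ny) next
      v <- L[i, j, s]
      acc <- acc + if (v >= 0.5) v else 0
    }
    B[x, y] <- acc
  }
  B
}

# Queue-based flood fill, 8-connected; returns the component count.
flood_fill_count <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  seen <- matrix(FALSE, nx, ny)
  count <- 0L
  for (j0 in seq_len(ny)) for (i0 in seq_len(nx)) {
    if (!mask[i0, j0] || seen[i0, j0]) next
    count <- count + 1L
    queue <- list(c(i0, j0))
    seen[i0, j0] <- TRUE
    while (length(queue)) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        i <- p[1L] + di; j <- p[2L] + dj
        if (i < 1L || i > nx || j < 1L || j > ny) next
        if (mask[i, j] && !seen[i, j]) {
          seen[i, j] <- TRUE
          queue[[length(queue) + 1L]] <- c(i, j)
        }
      }
    }
  }
  count
}

# CNN-free oracle classifier for synthetic scenes: a window is a target if
# the central region contains pixels whose chromaticity departs from the
# border's. Shadows darken the pasture multiplicatively, which preserves
# chromaticity, so they are rejected — mirroring the hard-negative design.
chroma_oracle <- function(crops) {
  n <- dim(crops)[1L]
  s <- dim(crops)[2L]
  ctr <- max(1L, round(s * 0.125)):round(s * 0.875)
  vapply(seq_len(n), function(i) {
    crop <- crops[i, , , ]
    tot <- pmax(crop[, , 1] + crop[, , 2] + crop[, , 3], 1)
    chr_r <- crop[, , 1] / tot
    chr_g <- crop[, , 2] / tot
    bg_r <- stats::median(c(chr_r[c(1L, s), ], chr_r[, c(1L, s)]))
    bg_g <- stats::median(c(chr_g[c(1L, s), ], chr_g[, c(1L, s)]))
    dev <- abs(chr_r[ctr, ctr] - bg_r) + abs(chr_g[ctr, ctr] - bg_g)
    frac <- mean(dev > 0.08)
    min(0.99, frac / 0.10)
  }, numeric(1L))
}

# Constant classifier stubs.
always_background <- function(crops) rep(0.01, dim(crops)[1L])

# Re-render just the background of a scene spec under its seed (an empty
# scene must equal this exactly).
with_seed_for_test <- function(sc) {
  cattlescan:::with_seed(sc$spec$seed,
    render_background(sc$spec$frame_height, sc$spec$frame_width,
                      sc$spec$background_style))
}
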
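test_that("the mid-range window follows the flight geometry", {
  cam <- camera_model(horizontal_fov = 90, altitude = 50,
                      image_width = 1920, image_height = 1080)
  expect_identical(mid_scale_window(cam), 48L)
  # doubling the altitude halves the window (within rounding)
  cam2 <- camera_model(90, 100, 1920, 1080)
  expect_lte(abs(mid_scale_window(cam2) - 24L), 1L)
  # monotone decreasing in altitude
  w <- vapply(seq(20, 200, by = 20),
              function(h) mid_scale_window(camera_model(90, h, 1920, 1080)),
              integer(1))
  expect_true(all(diff(w) <= 0))
  # very high flight clamps at the 8 px floor
  expect_identical(mid_scale_window(camera_model(90, 1e5, 1920, 1080)), 8L)
  # too low: window would not fit in the frame
  expect_error(mid_scale_window(camera_model(90, 1, 1920, 1080)),
               "altitude too low")
  expect_error(camera_model(0, 50, 100, 100), "horizontal_fov")
  expect_error(camera_model(90, -1, 100, 100), "altitude")
})

test_that("scan scales sit at 85%, 100% and 115% and stay ordered", {
  expect_identical(scan_scales(100), c(85L, 100L, 115L))
  expect_identical(scan_scales(20), c(17L, 20L, 23L))
  for (w in 8:200) expect_true(all(diff(scan_scales(w)) > 0))
  expect_error(scan_scales(7), ">= 8")
})

test_that("the scan grid tiles the frame with windows fully inside", {
  g <- build_grid(640, 640, 64, stride = 32)
  expect_identical(unname(g$grid_shape), c(19L, 19L))
  expect_identical(g$window_sizes, scan_scales(64L))
  # every mid-scale window inside the frame
  expect_true(all(g$cx - 32 >= 0 & g$cx + 32 <= 640))
  expect_true(all(g$cy - 32 >= 0 & g$cy + 32 <= 640))
  # degenerate exact fit: a single centre
  g1 <- build_grid(64, 64, 64)
  expect_identical(unname(g1$grid_shape), c(1L, 1L))
  expect_equal(g1$cx, 32)
  # default stride is half the mid window
  expect_identical(build_grid(640, 640, 64)$stride, 32L)
  expect_error(build_grid(48, 48, 64), "larger than frame")
})

test_that("boosting equals the brute-force triple sum exactly", {
  set.seed(51)
  for (rep in 1:60) {
    nx <- sample(3:10, 1); ny <- sample(3:10, 1)
    L <- array(runif(nx * ny * 3), c(nx, ny, 3))
    expect_identical(boost(L)$B, boost_oracle(L))
  }
  # zero lattice and saturated lattice
  expect_true(all(boost(array(0, c(5, 5, 3)))$B == 0))
  Bsat <- boost(array(1, c(5, 5, 3)))$B
  expect_identical(Bsat[3, 3], 27)
  expect_identical(max(Bsat), 27)
  # range bound everywhere
  set.seed(52)
  L <- array(runif(8 * 8 * 3), c(8, 8, 3))
  expect_true(all(boost(L)$B >= 0 & boost(L)$B <= 27))
})

test_that("boosting is monotone in lattice values above the gate", {
  set.seed(53)
  L <- array(runif(6 * 6 * 3), c(6, 6, 3))
  B0 <- boost(L)$B
  L2 <- L
  hot <- which(L >= 0.5)
  L2[hot[1]] <- min(1, L[hot[1]] + 0.3)
  expect_true(all(boost(L2)$B >= B0))
})

test_that("quantization thresholds the boosted lattice as specified", {
  set.seed(54)
  L <- array(runif(6 * 6 * 3), c(6, 6, 3))
  bg <- boost(L)
  m0 <- quantize(bg, 0)
  expect_true(all(m0 == 1))  # threshold 0: every cell (B >= 0) is on
  expect_identical(quantize(boost(array(0, c(4, 4, 3))), 4.5),
                   matrix(0L, 4, 4))
  # an isolated strong reading falls below the default threshold
  L1 <- array(0, c(7, 7, 3))
  L1[4, 4, 2] <- 0.9
  b1 <- boost(L1)
  expect_equal(max(b1$B), 0.9)
  expect_true(all(quantize(b1, 4.5) == 0))
  # a 3x3 patch of strong readings at all scales survives: B = 24.3 inside
  L2 <- array(0, c(7, 7, 3))
  L2[3:5, 3:5, ] <- 0.9
  b2 <- boost(L2)
  expect_equal(b2$B[4, 4], 27 * 0.9)
  m2 <- quantize(b2, 4.5)
  expect_identical(m2[4, 4], 1L)
  expect_identical(m2[1, 1], 0L)
  expect_error(quantize(b2, -1), "non-negative")
})

test_that("component counting matches a flood-fill oracle on random masks", {
  set.seed(55)
  for (rep in 1:200) {
    nx <- sample(2:12, 1); ny <- sample(2:12, 1)
    mask <- matrix(rbinom(nx * ny, 1, runif(1, 0.2, 0.6)), nx, ny)
    res <- count_components(mask)
    expect_identical(res$count, flood_fill_count(mask))
    expect_identical(nrow(res$components), res$count)
    if (res$count > 0) expect_identical(res$components$label, seq_len(res$count))
  }
})

test_that("component labeling follows 8-connectivity and reports boxes", {
  expect_identical(count_components(matrix(0L, 5, 5))$count, 0L)
  # two blobs touching only diagonally merge under 8-connectivity
  m <- matrix(0L, 4, 4)
  m[1:2, 1:2] <- 1L
  m[3:4, 3:4] <- 1L
  expect_identical(count_components(m)$count, 1L)
  # separated blobs stay distinct, with correct grid boxes
  m2 <- matrix(0L, 6, 6)
  m2[1:2, 1:2] <- 1L
  m2[5:6, 5:6] <- 1L
  res <- count_components(m2)
  expect_identical(res$count, 2L)
  expect_identical(res$components$gx0, c(1L, 5L))
  expect_identical(res$components$gx1, c(2L, 6L))
  # pixel back-projection with a grid attached
  g <- build_grid(160, 160, 32, 16)
  mask9 <- matrix(0L, 9, 9)
  mask9[2:3, 2:3] <- 1L
  res2 <- count_components(mask9, grid = g)
  expect_true(all(c("cx", "cy", "px0", "py1") %in% names(res2$components)))
  # grid cell (2, 2) has centre (32, 32); the box spans one window around
  # the component
  expect_equal(res2$components$px0, 16 + 16 - 16)
  expect_equal(res2$components$px1, 16 + 2 * 16 + 16)
  expect_equal(res2$components$cx, 40)
})

test_that("the probability lattice reflects the classifier and geometry", {
  sc <- render_scene(scene_spec(n_animals = 0, seed = 61))
  g <- build_grid(256, 256, 32, 16)
  pg <- compute_prob_grid(always_background, sc$frame, g)
  expect_identical(dim(pg$L), c(15L, 15L, 3L))
  expect_true(all(pg$L >= 0 & pg$L <= 1))
  expect_true(all(pg$L < 0.5))
  # one animal: the chromaticity oracle peaks at the nearest grid cell
  sc1 <- render_scene(scene_spec(n_animals = 1, seed = 62))
  pg1 <- compute_prob_grid(chroma_oracle, sc1$frame, g)
  peak <- which(pg1$L[, , 2] == max(pg1$L[, , 2]), arr.ind = TRUE)[1, ]
  ctr <- sc1$truth$centers[1, ]
  expect_lte(abs(g$cx[peak[1]] - ctr[["x"]]), 16)
  expect_lte(abs(g$cy[peak[2]] - ctr[["y"]]), 16)
})

test_that("detect_frame equals the manual composition of its stages", {
  sc <- render_scene(scene_spec(n_animals = 3, seed = 63))
  det <- detect_frame(chroma_oracle, sc$frame, w_mid = 32)
  g <- build_grid(256, 256, 32)
  pg <- compute_prob_grid(chroma_oracle, sc$frame, g)
  bg <- boost(pg)
  mask <- quantize(bg, 4.5)
  res <- count_components(mask, grid = g)
  expect_identical(det$boost_grid$B, bg$B)
  expect_identical(det$mask, mask)
  expect_identical(det$count, res$count)
})

test_that("oracle-classifier detection recovers well-separated counts", {
  for (ns in c(0L, 5L)) {
    sc <- render_scene(scene_spec(n_animals = ns, seed = 64 + ns))
    det <- detect_frame(chroma_oracle, sc$frame, w_mid = 32)
    expect_identical(det$count, ns)
  }
})
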
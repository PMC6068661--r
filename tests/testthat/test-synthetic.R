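test_that("sprite banks have the requested size, shape and range", {
  bank <- render_sprite_bank(7, seed = 3)
  expect_s3_class(bank, "sprite_bank")
  for (cls in c("animals", "shadows", "backgrounds")) {
    expect_length(bank[[cls]], 7L)
    for (el in bank[[cls]]) {
      expect_identical(dim(el$image), c(64L, 64L, 3L))
      expect_gte(min(el$image), 0)
      expect_lte(max(el$image), 255)
    }
  }
  expect_identical(length(render_sprite_bank(1, seed = 0)$animals), 1L)
  expect_error(render_sprite_bank(0), "positive")
  expect_error(render_sprite_bank(-2), "positive")
})

test_that("identical bank arguments give byte-identical banks", {
  expect_identical(render_sprite_bank(4, seed = 9),
                   render_sprite_bank(4, seed = 9))
  # different seeds differ
  b1 <- render_sprite_bank(2, seed = 1)
  b2 <- render_sprite_bank(2, seed = 2)
  expect_false(identical(b1$animals[[1]]$image, b2$animals[[1]]$image))
})

test_that("sprites carry at least the configured contrast against pasture", {
  # coat sampling enforces the bound against the style's base colour
  # (before the +/- 8 per-channel jitter)
  for (style in c("green", "dry")) {
    base <- cattlescan:::.pasture_base[[style]]
    coats <- cattlescan:::with_seed(77, {
      replicate(50, cattlescan:::pick_coat(style, 30))
    })
    expect_true(all(colMeans(abs(coats - base)) >= 30 - 8))
  }
  # and the rendered scene shows the signal at each animal centre
  sc <- render_scene(scene_spec(n_animals = 4, seed = 23))
  med <- apply(sc$frame, 3, stats::median)
  for (k in seq_len(4)) {
    px <- sc$frame[round(sc$truth$centers[k, "y"]),
                   round(sc$truth$centers[k, "x"]), ]
    expect_gt(mean(abs(px - med)), 15)
  }
})

test_that("empty scenes are pure background with zero count", {
  sc <- render_scene(scene_spec(n_animals = 0, seed = 5))
  expect_identical(sc$truth$count, 0L)
  expect_identical(nrow(sc$truth$centers), 0L)
  expect_identical(dim(sc$frame), c(256L, 256L, 3L))
  bg <- with_seed_for_test(sc)
  expect_identical(sc$frame, bg)
})

test_that("scene counts are conserved and placements respect the contract", {
  for (seed in c(2, 12, 77)) {
    spec <- scene_spec(n_animals = 5, seed = seed)
    sc <- render_scene(spec)
    expect_identical(sc$truth$count, 5L)
    expect_identical(nrow(sc$truth$centers), 5L)
    expect_length(sc$truth$sizes, 5L)
    # centres inside the frame
    expect_true(all(sc$truth$centers[, "x"] > 0 &
                      sc$truth$centers[, "x"] < spec$frame_width))
    expect_true(all(sc$truth$centers[, "y"] > 0 &
                      sc$truth$centers[, "y"] < spec$frame_height))
    # pairwise separation honoured (implies disjoint bounding boxes)
    d <- as.matrix(stats::dist(sc$truth$centers))
    diag(d) <- Inf
    expect_gte(min(d), spec$min_separation)
  }
})

test_that("identical scene specs render bit-identical frames", {
  spec <- scene_spec(n_animals = 4, seed = 31)
  expect_identical(render_scene(spec), render_scene(spec))
})

test_that("impossible placements raise a placement error", {
  spec <- scene_spec(frame_width = 96, frame_height = 96, n_animals = 30,
                     seed = 1)
  expect_error(render_scene(spec, max_attempts = 50, max_restarts = 3),
               "placement failure")
})

test_that("scene ground truth round-trips through the JSON sidecar", {
  sc <- render_scene(scene_spec(n_animals = 3, seed = 8))
  png <- withr::local_tempfile(fileext = ".png")
  paths <- write_scene(sc, png)
  gt <- read_ground_truth(paths[["json"]])
  expect_equal(gt$count, 3L)
  expect_equal(gt$centers, sc$truth$centers, tolerance = 1e-9)
  frame <- read_frame_png(paths[["png"]])
  expect_identical(dim(frame), dim(sc$frame))
})
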
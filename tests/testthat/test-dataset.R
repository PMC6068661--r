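make_tiles <- function(n, side = 8) {
  lapply(seq_len(n), function(i) array(runif(side * side * 3, 0, 255),
                                       c(side, side, 3)))
}

test_that("rotation augmentation quadruples the set losslessly", {
  set.seed(41)
  imgs <- make_tiles(100)
  out <- augment_rotations(imgs)
  expect_length(out, 400L)
  # stable order: original first in each group of four
  expect_identical(out[[1]], imgs[[1]])
  expect_identical(out[[5]], imgs[[2]])
  # four quarter turns close the group
  expect_identical(rotate90(out[[4]], 1L), imgs[[1]])
  # a constant image is invariant under rotation
  const <- array(50, c(6, 6, 3))
  r <- augment_rotations(list(const))
  for (k in 1:4) expect_identical(r[[k]], const)
  expect_error(augment_rotations(list(array(0, c(4, 6, 3)))), "square")
  expect_error(augment_rotations(list()), "non-empty")
})

test_that("perspective augmentation multiplies counts and is seeded", {
  set.seed(42)
  imgs <- make_tiles(10)
  out <- augment_perspective(imgs, n_deform = 2, seed = 5)
  expect_length(out, 30L)
  expect_identical(out[[1]], imgs[[1]])
  expect_identical(out[[4]], imgs[[2]])
  # warped variants keep shape and range but differ from the original
  expect_identical(dim(out[[2]]), dim(imgs[[1]]))
  expect_false(identical(out[[2]], imgs[[1]]))
  expect_true(min(out[[2]]) >= 0 && max(out[[2]]) <= 255)
  # n_deform = 0 is the identity
  expect_identical(augment_perspective(imgs, n_deform = 0, seed = 1), imgs)
  # determinism
  expect_identical(augment_perspective(imgs, 2, seed = 5),
                   augment_perspective(imgs, 2, seed = 5))
  expect_error(augment_perspective(imgs, n_deform = -1), "non-negative")
})

test_that("the 100 -> 400 -> 1200 augmentation arithmetic holds per class", {
  set.seed(43)
  imgs <- make_tiles(100)
  rot <- augment_rotations(imgs)
  expect_length(rot, 400L)
  per <- augment_perspective(rot, n_deform = 2, seed = 9)
  expect_length(per, 1200L)
})

test_that("tile dataset construction maps provenance to labels", {
  bank <- render_sprite_bank(1, seed = 2)
  ds0 <- build_tile_dataset(bank, n_deform = 0)
  expect_identical(n_tiles(ds0), 12L)
  expect_identical(as.integer(table(ds0$provenance)), rep(4L, 3))
  bank3 <- render_sprite_bank(3, seed = 2)
  ds <- build_tile_dataset(bank3, n_deform = 2, seed = 7)
  expect_identical(n_tiles(ds), 108L)
  cc <- class_counts(ds)
  expect_identical(as.integer(cc[["target"]]), 36L)
  expect_identical(as.integer(cc[["background"]]), 72L)
  expect_identical(dim(ds$x)[2:4], c(64L, 64L, 3L))
  # animal provenance iff target label
  expect_identical(ds$provenance == "animal", ds$label == "target")
  expect_error(tile_dataset(ds$x, ds$label,
                            rep("background", n_tiles(ds))),
               "animal provenance")
})

test_that("stratified split is a seeded partition preserving proportions", {
  bank <- render_sprite_bank(3, seed = 5)
  ds <- build_tile_dataset(bank, n_deform = 2, seed = 6)
  n <- n_tiles(ds)
  sp <- split_dataset(ds, ratio = 0.8, seed = 11)
  expect_identical(n_tiles(sp$train) + n_tiles(sp$test), n)
  expect_identical(n_tiles(sp$train), as.integer(round(0.8 * n)))
  expect_length(intersect(sp$train_idx, sp$test_idx), 0L)
  expect_identical(sort(c(sp$train_idx, sp$test_idx)), seq_len(n))
  # per-label proportions within one tile of the target ratio
  for (lab in c("target", "background")) {
    n_lab <- sum(ds$label == lab)
    got <- sum(sp$train$label == lab)
    expect_lte(abs(got - 0.8 * n_lab), 1)
  }
  # determinism and seed sensitivity
  sp2 <- split_dataset(ds, ratio = 0.8, seed = 11)
  expect_identical(sp$train_idx, sp2$train_idx)
  sp3 <- split_dataset(ds, ratio = 0.8, seed = 12)
  expect_false(identical(sp$train_idx, sp3$train_idx))
  # symmetric balanced case splits 5/5 with strata preserved
  small <- tile_dataset(ds$x[1:10, , , ],
                        rep(c("target", "background"), each = 5),
                        rep(c("animal", "background"), each = 5))
  s55 <- split_dataset(small, 0.5, seed = 1)
  expect_identical(n_tiles(s55$train), 5L)
  tab <- as.integer(table(s55$train$label))
  expect_true(all(tab %in% 2:3) && sum(tab) == 5L)
  expect_error(split_dataset(ds, 0), "between 0 and 1")
  expect_error(split_dataset(ds, 1.2), "between 0 and 1")
})

test_that("tile datasets round-trip through the PNG + manifest format", {
  bank <- render_sprite_bank(1, seed = 8)
  ds <- build_tile_dataset(bank, n_deform = 0)
  dir <- withr::local_tempdir()
  write_tile_dataset(ds, dir)
  back <- read_tile_dataset(dir)
  expect_identical(n_tiles(back), n_tiles(ds))
  expect_identical(back$label, ds$label)
  expect_identical(back$provenance, ds$provenance)
  expect_identical(back$aug, ds$aug)
  expect_lt(max(abs(back$x - round(ds$x))), 1.01)
})
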
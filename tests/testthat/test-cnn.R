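# Small architecture used throughout: cheap enough for gradient checks and
# training-progress properties while exercising every layer type.
small_spec <- function() cnn_spec(input_size = 16, channels = 3,
                                  conv1_filters = 3, conv1_kernel = 3,
                                  pool1 = 2, conv2_filters = 4,
                                  conv2_kernel = 3, pool2 = 2)

# Separable 16x16 toy tiles: bright blob on dark vs plain dark.
toy_tiles <- function(n_per_class, seed) {
  cattlescan:::with_seed(seed, {
    imgs <- list(); lab <- character(0); prov <- character(0)
    for (i in seq_len(n_per_class)) {
      a <- array(runif(16 * 16 * 3, 0, 60), c(16, 16, 3))
      a[6:11, 6:11, ] <- a[6:11, 6:11, ] + 170
      imgs[[length(imgs) + 1L]] <- a
      lab <- c(lab, "target"); prov <- c(prov, "animal")
      b <- array(runif(16 * 16 * 3, 0, 60), c(16, 16, 3))
      imgs[[length(imgs) + 1L]] <- b
      lab <- c(lab, "background"); prov <- c(prov, "background")
    }
    tile_dataset(imgs, lab, prov)
  })
}

test_that("relu matches its piecewise definition and is idempotent", {
  expect_identical(relu(-3.5), 0)
  expect_identical(relu(0), 0)
  expect_identical(relu(2.25), 2.25)
  set.seed(1)
  x <- rnorm(100)
  expect_identical(relu(relu(x)), relu(x))
  # non-decreasing
  xs <- sort(x)
  expect_true(all(diff(relu(xs)) >= 0))
  # elementwise on arrays, preserving shape
  a <- array(c(-1, 2, -3, 4), c(2, 2, 1))
  expect_identical(dim(relu(a)), dim(a))
})

test_that("softmax normalises, is shift-invariant and overflow-safe", {
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  # direct evaluation: (e/(e+1), 1/(e+1))
  expect_equal(softmax(c(1, 0)), c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-12)
  expect_equal(softmax(c(1000, 999)), softmax(c(1, 0)), tolerance = 1e-12)
  set.seed(2)
  for (i in 1:25) {
    y <- rnorm(sample(1:6, 1), sd = 10)
    p <- softmax(y)
    expect_true(all(p > 0))
    expect_lt(abs(sum(p) - 1), 1e-9)
    expect_equal(softmax(y + 17.3), p, tolerance = 1e-12)
  }
  expect_error(softmax(numeric(0)), "non-empty")
  expect_error(softmax(c(1, NA)), "finite")
})

test_that("the default architecture derives its dimensions and 2n+1 head", {
  sp <- cnn_spec()
  expect_identical(sp$conv1_out, 58L)
  expect_identical(sp$pool1_out, 14L)
  expect_identical(sp$conv2_out, 10L)
  expect_identical(sp$pool2_out, 5L)
  expect_identical(sp$flatten_size, 2400L)
  expect_identical(sp$hidden_size, 2L * sp$flatten_size + 1L)
  expect_error(cnn_spec(input_size = 12), "invalid architecture")
})

test_that("weight initialisation is seeded and the forward pass normalises", {
  n1 <- build_network(small_spec(), seed = 4)
  n2 <- build_network(small_spec(), seed = 4)
  expect_identical(coef(n1), coef(n2))
  n3 <- build_network(small_spec(), seed = 5)
  expect_false(identical(n1$W1, n3$W1))
  # forward pass of arbitrary tiles gives probabilities summing to 1
  set.seed(6)
  tiles <- array(runif(5 * 16 * 16 * 3, 0, 255), c(5, 16, 16, 3))
  p <- predict(n1, tiles, type = "prob")
  expect_identical(dim(p), c(5L, 2L))
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  # deterministic forward pass
  expect_identical(p, predict(n1, tiles, type = "prob"))
})

test_that("analytic gradients match numerical differentiation", {
  net <- build_network(small_spec(), seed = 7)
  set.seed(8)
  X <- matrix(runif(2 * 16 * 16 * 3, -0.5, 0.5), 2)
  Tm <- rbind(c(1, 0), c(0, 1))
  g <- cattlescan:::cnn_grad(net, X, Tm)
  eps <- 1e-6
  for (w in c("W1", "b2", "W3", "b3", "W4", "b4")) {
    ii <- sample(length(net[[w]]), min(3, length(net[[w]])))
    for (i in ii) {
      np <- net; np[[w]][i] <- np[[w]][i] + eps
      nm <- net; nm[[w]][i] <- nm[[w]][i] - eps
      num <- (cattlescan:::cnn_grad(np, X, Tm)$loss -
                cattlescan:::cnn_grad(nm, X, Tm)$loss) / (2 * eps)
      expect_lt(abs(g$grads[[w]][i] - num),
                1e-6 + 1e-4 * (abs(num) + abs(g$grads[[w]][i])))
    }
  }
})

test_that("one small SGD step decreases the example's MSE", {
  net <- build_network(small_spec(), seed = 9)
  set.seed(10)
  X <- matrix(runif(16 * 16 * 3, -0.5, 0.5), 1)
  Tm <- matrix(c(0, 1), 1)
  g <- cattlescan:::cnn_grad(net, X, Tm)
  for (w in names(g$grads)) net[[w]] <- net[[w]] - 0.05 * g$grads[[w]]
  expect_lt(cattlescan:::cnn_grad(net, X, Tm)$loss, g$loss)
})

test_that("training reduces the loss on separable tiles, deterministically", {
  ds <- toy_tiles(20, seed = 11)
  cfg <- training_config(learning_rate = 0.02, epochs = 6, batch_size = 8,
                         seed = 12)
  net <- tile_cnn(ds, spec = small_spec(), config = cfg, seed = 13)
  expect_true(net$trained)
  expect_length(net$loss_history, 6L)
  expect_lt(net$loss_history[6], net$loss_history[1])
  # high train accuracy on this trivially separable set
  ev <- evaluate_cnn(net, ds)
  expect_gt(ev$average, 0.95)
  # bit-identical rerun
  net2 <- tile_cnn(ds, spec = small_spec(), config = cfg, seed = 13)
  expect_identical(net$loss_history, net2$loss_history)
  expect_identical(coef(net), coef(net2))
  expect_error(training_config(epochs = 0), "at least 1")
  expect_error(train_cnn(build_network(small_spec()), ds[ds$label == "target"]),
               "degenerate")
})

test_that("evaluation reports per-class accuracy with the fixed tie-break", {
  ds <- toy_tiles(10, seed = 14)
  # a constant-background classifier: zero final layer biases toward class 1
  net <- build_network(small_spec(), seed = 15)
  net$W4[] <- 0
  net$b4 <- c(10, -10)
  net$trained <- TRUE
  ev <- evaluate_cnn(net, ds)
  expect_equal(unname(ev$per_class[["background"]]), 1)
  expect_equal(unname(ev$per_class[["target"]]), 0)
  expect_equal(ev$average, 0.5)
  expect_equal(ev$average, mean(ev$per_class))
  # exact ties go to background
  net$b4 <- c(0, 0)
  pred <- predict(net, ds, type = "class")
  expect_true(all(pred == "background"))
  expect_error(evaluate_cnn(net, ds[0]), "non-empty")
})

test_that("checkpoints round-trip weights, metadata and predictions", {
  ds <- toy_tiles(6, seed = 16)
  net <- tile_cnn(ds, spec = small_spec(),
                  config = training_config(epochs = 2, batch_size = 4, seed = 17),
                  seed = 18)
  path <- withr::local_tempfile(fileext = ".bin")
  save_checkpoint(net, path)
  back <- load_checkpoint(path)
  expect_identical(coef(back), coef(net))
  expect_identical(back$loss_history, net$loss_history)
  expect_true(back$trained)
  expect_identical(back$classes, net$classes)
  set.seed(19)
  tiles <- array(runif(3 * 16 * 16 * 3, 0, 255), c(3, 16, 16, 3))
  expect_identical(predict(back, tiles), predict(net, tiles))
})
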
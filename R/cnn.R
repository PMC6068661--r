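# Two-class tile classifier: conv(18 @ 7x7) -> ReLU -> maxpool(4) ->
# conv(96 @ 5x5) -> ReLU -> maxpool(2) -> flatten(n) -> dense(2n + 1, ReLU)
# -> dense(2) -> softmax, trained by plain SGD on a mean-squared-error
# criterion against one-hot labels.
#
# The network is implemented directly on BLAS matrix products: convolutions
# are im2col gathers followed by a patch-matrix x filter-matrix multiply,
# and backpropagation mirrors each stage. Convolutions are "valid" (no
# padding, stride 1); pooling is non-overlapping with floor division, so a
# 64 px input gives 64 -> 58 -> 14 -> 10 -> 5 and a flatten size of
# n = 96 * 5 * 5 = 2400. The hidden layer is sized 2n + 1 from the computed
# n. Class order is fixed: index 1 = background, index 2 = target.

CNN_CLASSES <- c("background", "target")

#' Rectified linear unit
#'
#' `f(x) = 0` for `x < 0` and `x` otherwise, applied elementwise.
#'
#' @param x Numeric vector, matrix or array.
#' @return Object of the same shape with negative entries replaced by zero.
#' @export
relu <- function(x) pmax(x, 0)

#' Softmax activation
#'
#' Maps a real vector to a probability vector. The maximum is subtracted
#' before exponentiation, so the result is invariant to adding a constant
#' to all inputs and safe for inputs of large magnitude.
#'
#' @param y Non-empty finite numeric vector.
#' @return A probability vector of the same length (positive, sums to 1).
#' @export
softmax <- function(y) {
  if (length(y) == 0L) stop("`y` must be non-empty", call. = FALSE)
  if (!all(is.finite(y))) stop("`y` must be finite", call. = FALSE)
  e <- exp(y - max(y))
  e / sum(e)
}

# Row-wise softmax for a logits matrix.
row_softmax <- function(z) {
  m <- z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  e <- exp(z - m)
  e / rowSums(e)
}

#' Specify the tile-classifier architecture
#'
#' Computes every derived dimension of the two-stage conv/pool network under
#' valid convolution (stride 1) and non-overlapping floor-division pooling,
#' and sizes the MLP hidden layer as `2n + 1` where `n` is the flattened
#' feature count entering the MLP.
#'
#' @param input_size Square input side in pixels (default 64).
#' @param channels Input channels (default 3).
#' @param conv1_filters,conv1_kernel,pool1 First conv/pool stage (18 filters
#'   of 7x7, 4x4 max pooling by default).
#' @param conv2_filters,conv2_kernel,pool2 Second stage (96 filters of 5x5,
#'   2x2 max pooling by default).
#' @param n_classes Output classes (fixed at 2 for target/background).
#' @return A `cnn_spec` with derived fields `conv1_out`, `pool1_out`,
#'   `conv2_out`, `pool2_out`, `flatten_size` and `hidden_size`.
#' @export
cnn_spec <- function(input_size = 64L, channels = 3L,
                     conv1_filters = 18L, conv1_kernel = 7L, pool1 = 4L,
                     conv2_filters = 96L, conv2_kernel = 5L, pool2 = 2L,
                     n_classes = 2L) {
  c1 <- input_size - conv1_kernel + 1L
  p1 <- c1 %/% pool1
  c2 <- p1 - conv2_kernel + 1L
  p2 <- c2 %/% pool2
  if (c1 < 1L || p1 < 1L || c2 < 1L || p2 < 1L)
    stop("invalid architecture: pooled dimensions reach zero for input size ",
         input_size, call. = FALSE)
  n <- p2 * p2 * conv2_filters
  structure(list(
    input_size = as.integer(input_size), channels = as.integer(channels),
    conv1_filters = as.integer(conv1_filters),
    conv1_kernel = as.integer(conv1_kernel), pool1 = as.integer(pool1),
    conv2_filters = as.integer(conv2_filters),
    conv2_kernel = as.integer(conv2_kernel), pool2 = as.integer(pool2),
    n_classes = as.integer(n_classes),
    conv1_out = c1, pool1_out = p1, conv2_out = c2, pool2_out = p2,
    flatten_size = as.integer(n), hidden_size = as.integer(2L * n + 1L)
  ), class = "cnn_spec")
}

#' @export
print.cnn_spec <- function(x, ...) {
  cat(sprintf("CNN spec: %dx%d-%dC%d-MP%d-%dC%d-MP%d-%dL-%d\n",
              x$input_size, x$input_size, x$conv1_filters, x$conv1_kernel,
              x$pool1, x$conv2_filters, x$conv2_kernel, x$pool2,
              x$flatten_size, x$n_classes))
  cat(sprintf("  flatten n = %d, hidden layer 2n+1 = %d units\n",
              x$flatten_size, x$hidden_size))
  invisible(x)
}

# Linear gather indices for im2col over an in_h x in_w x in_c input:
# rows are output positions (row-major down columns: oy fastest), columns
# are patch elements ordered (dy, dx, channel).
im2col_index <- function(in_h, in_w, in_c, k) {
  oh <- in_h - k + 1L
  ow <- in_w - k + 1L
  oy <- rep(seq_len(oh), times = ow)
  ox <- rep(seq_len(ow), each = oh)
  idx <- matrix(0L, oh * ow, k * k * in_c)
  col <- 0L
  for (c0 in seq_len(in_c)) for (dx in seq_len(k)) for (dy in seq_len(k)) {
    col <- col + 1L
    idx[, col] <- (oy + dy - 1L) + (ox + dx - 2L) * in_h +
      (c0 - 1L) * in_h * in_w
  }
  idx
}

# Gather patch matrix for a batch: X is B x (h*w*c) with per-image layout
# (y, x, c) column-major; result is (B*P) x K with row index b + (pos-1)*B.
im2col_gather <- function(X, idx) {
  Bn <- nrow(X)
  M <- X[, as.vector(idx), drop = FALSE]
  dim(M) <- c(Bn * nrow(idx), ncol(idx))
  M
}

# Non-overlapping max pooling of a [B, H, W, F] array; returns the pooled
# array and the within-window argmax offsets needed for backprop. Ties go
# to the earliest offset, deterministically.
pool_forward <- function(A, p, want_argmax = TRUE) {
  d <- dim(A)
  Bn <- d[1L]; H <- d[2L]; W <- d[3L]; F <- d[4L]
  oh <- H %/% p; ow <- W %/% p
  A <- A[, seq_len(oh * p), seq_len(ow * p), , drop = FALSE]
  dim(A) <- c(Bn, p, oh, p, ow, F)
  mx <- NULL; am <- NULL
  for (dx in seq_len(p)) for (dy in seq_len(p)) {
    S <- A[, dy, , dx, , , drop = FALSE]
    dim(S) <- c(Bn, oh, ow, F)
    o <- dy + (dx - 1L) * p
    if (is.null(mx)) {
      mx <- S
      if (want_argmax) am <- array(o, dim(S))
    } else if (want_argmax) {
      upd <- S > mx
      mx[upd] <- S[upd]
      am[upd] <- o
    } else {
      mx <- pmax(mx, S)
    }
  }
  list(out = mx, argmax = am, in_h = H, in_w = W)
}

# Scatter pooled gradients back to the pre-pooling array.
pool_backward <- function(dP, pool, p) {
  d <- dim(dP)
  Bn <- d[1L]; oh <- d[2L]; ow <- d[3L]; F <- d[4L]
  dA <- array(0, c(Bn, p, oh, p, ow, F))
  for (dx in seq_len(p)) for (dy in seq_len(p)) {
    o <- dy + (dx - 1L) * p
    dA[, dy, , dx, , ] <- dP * (pool$argmax == o)
  }
  dim(dA) <- c(Bn, p * oh, p * ow, F)
  if (p * oh == pool$in_h && p * ow == pool$in_w) return(dA)
  full <- array(0, c(Bn, pool$in_h, pool$in_w, F))
  full[, seq_len(p * oh), seq_len(p * ow), ] <- dA
  full
}

#' Build an untrained network
#'
#' Allocates all weights for a [cnn_spec()] with seeded uniform
#' initialisation scaled by fan-in (`U(-1/sqrt(fan_in), 1/sqrt(fan_in))`);
#' biases start at zero. The same seed always yields identical weights.
#'
#' @param spec A [cnn_spec()].
#' @param seed Integer seed for the initialisation.
#' @return An untrained `tile_cnn` object.
#' @export
build_network <- function(spec = cnn_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cnn_spec"))
  K1 <- spec$conv1_kernel^2 * spec$channels
  K2 <- spec$conv2_kernel^2 * spec$conv1_filters
  init <- function(nr, nc) {
    a <- 1 / sqrt(nr)
    matrix(stats::runif(nr * nc, -a, a), nr, nc)
  }
  w <- with_seed(seed, list(
    W1 = init(K1, spec$conv1_filters), b1 = numeric(spec$conv1_filters),
    W2 = init(K2, spec$conv2_filters), b2 = numeric(spec$conv2_filters),
    W3 = init(spec$flatten_size, spec$hidden_size),
    b3 = numeric(spec$hidden_size),
    W4 = init(spec$hidden_size, spec$n_classes),
    b4 = numeric(spec$n_classes)
  ))
  net <- c(list(spec = spec, classes = CNN_CLASSES,
                normalization = "scale-255-center-0.5",
                trained = FALSE, loss_history = numeric(0L),
                init_seed = as.integer(seed)), w)
  net$idx1 <- im2col_index(spec$input_size, spec$input_size, spec$channels,
                           spec$conv1_kernel)
  net$idx2 <- im2col_index(spec$pool1_out, spec$pool1_out, spec$conv1_filters,
                           spec$conv2_kernel)
  class(net) <- "tile_cnn"
  net
}

# Forward pass over a batch. X: B x (input_size^2 * channels), already
# normalised to [0, 1]. Returns class probabilities and, if keep = TRUE,
# every intermediate needed for backpropagation.
cnn_forward <- function(net, X, keep = FALSE) {
  sp <- net$spec
  Bn <- nrow(X)
  M1 <- im2col_gather(X, net$idx1)
  Z1 <- sweep(M1 %*% net$W1, 2L, net$b1, "+")
  A1 <- relu(Z1)
  dim(A1) <- c(Bn, sp$conv1_out, sp$conv1_out, sp$conv1_filters)
  pl1 <- pool_forward(A1, sp$pool1, want_argmax = keep)
  X2 <- pl1$out
  dim(X2) <- c(Bn, sp$pool1_out^2 * sp$conv1_filters)
  M2 <- im2col_gather(X2, net$idx2)
  Z2 <- sweep(M2 %*% net$W2, 2L, net$b2, "+")
  A2 <- relu(Z2)
  dim(A2) <- c(Bn, sp$conv2_out, sp$conv2_out, sp$conv2_filters)
  pl2 <- pool_forward(A2, sp$pool2, want_argmax = keep)
  Xf <- pl2$out
  dim(Xf) <- c(Bn, sp$flatten_size)
  H_pre <- sweep(Xf %*% net$W3, 2L, net$b3, "+")
  H <- relu(H_pre)
  logits <- sweep(H %*% net$W4, 2L, net$b4, "+")
  probs <- row_softmax(logits)
  colnames(probs) <- net$classes
  if (!keep) return(list(probs = probs))
  list(probs = probs,
       cache = list(M1 = M1, Z1 = Z1, pl1 = pl1, M2 = M2, Z2 = Z2,
                    pl2 = pl2, Xf = Xf, H_pre = H_pre, H = H))
}

# Loss and gradients for a batch: MSE between softmax outputs and one-hot
# targets, averaged over samples and classes.
cnn_grad <- function(net, X, Tm) {
  sp <- net$spec
  Bn <- nrow(X)
  fw <- cnn_forward(net, X, keep = TRUE)
  P <- fw$probs
  dimnames(P) <- NULL
  ca <- fw$cache
  loss <- mean((P - Tm)^2)
  dP <- 2 * (P - Tm) / (Bn * sp$n_classes)
  # through the softmax Jacobian: dz_i = p_i * (dp_i - sum_j dp_j p_j)
  dZ <- P * (dP - rowSums(dP * P))
  dW4 <- crossprod(ca$H, dZ)
  db4 <- colSums(dZ)
  dH <- tcrossprod(dZ, net$W4) * (ca$H_pre > 0)
  dW3 <- crossprod(ca$Xf, dH)
  db3 <- colSums(dH)
  dXf <- tcrossprod(dH, net$W3)
  dim(dXf) <- c(Bn, sp$pool2_out, sp$pool2_out, sp$conv2_filters)
  dA2 <- pool_backward(dXf, ca$pl2, sp$pool2)
  dim(dA2) <- c(Bn * sp$conv2_out^2, sp$conv2_filters)
  dZ2 <- dA2 * (ca$Z2 > 0)
  dW2 <- crossprod(ca$M2, dZ2)
  db2 <- colSums(dZ2)
  dM2 <- tcrossprod(dZ2, net$W2)
  P2 <- nrow(net$idx2)
  dX2 <- matrix(0, Bn, sp$pool1_out^2 * sp$conv1_filters)
  for (k in seq_len(ncol(net$idx2))) {
    dMk <- dM2[, k]
    dim(dMk) <- c(Bn, P2)
    cols <- net$idx2[, k]
    dX2[, cols] <- dX2[, cols] + dMk
  }
  dim(dX2) <- c(Bn, sp$pool1_out, sp$pool1_out, sp$conv1_filters)
  dA1 <- pool_backward(dX2, ca$pl1, sp$pool1)
  dim(dA1) <- c(Bn * sp$conv1_out^2, sp$conv1_filters)
  dZ1 <- dA1 * (ca$Z1 > 0)
  dW1 <- crossprod(ca$M1, dZ1)
  db1 <- colSums(dZ1)
  list(loss = loss,
       grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                    W3 = dW3, b3 = db3, W4 = dW4, b4 = db4))
}

# Flatten a tile array or dataset into the B x D input matrix in [0, 1].
tiles_as_input <- function(x, spec) {
  if (inherits(x, "tile_dataset")) x <- x$x
  if (is.array(x) && length(dim(x)) == 3L) {
    x <- array(x, c(1L, dim(x)))
  }
  if (!is.array(x) || length(dim(x)) != 4L)
    stop("tiles must be an N x S x S x 3 array or a tile_dataset", call. = FALSE)
  d <- dim(x)
  if (d[2L] != spec$input_size || d[3L] != spec$input_size || d[4L] != spec$channels)
    stop(sprintf("tile shape %dx%dx%d does not match the network input %dx%dx%d",
                 d[2L], d[3L], d[4L], spec$input_size, spec$input_size,
                 spec$channels), call. = FALSE)
  dim(x) <- c(d[1L], prod(d[2:4]))
  # centred normalisation: zero-mean inputs keep the MSE-on-softmax
  # criterion away from the constant base-rate saddle
  x / 255 - 0.5
}

#' Training configuration
#'
#' @param learning_rate Positive SGD step size (default 0.02, sized for
#'   the default momentum of 0.9; with momentum 0 a rate around 0.1
#'   behaves comparably).
#' @param epochs Number of passes over the training set (at least 1).
#' @param batch_size Minibatch size (at least 1).
#' @param momentum Classical momentum coefficient in `[0, 1)` (default
#'   0.9; 0 gives plain SGD). Momentum makes the escape from the MSE
#'   criterion's base-rate saddle reliable across seeds.
#' @param seed Integer seed controlling shuffling.
#' @param balance_classes Oversample the minority class (with replacement,
#'   seeded, per epoch) so each epoch sees both classes equally often. The
#'   tile recipe yields twice as many background as target tiles; under
#'   the MSE criterion that imbalance depresses borderline target
#'   probabilities, which costs the boosting stage neighborhood support.
#' @return A `training_config` object.
#' @export
training_config <- function(learning_rate = 0.02, epochs = 20L,
                            batch_size = 32L, momentum = 0.9, seed = 1L,
                            balance_classes = FALSE) {
  if (!is_number(learning_rate) || learning_rate <= 0)
    stop("`learning_rate` must be positive", call. = FALSE)
  if (!is_count(epochs, 1L)) stop("`epochs` must be at least 1", call. = FALSE)
  if (!is_count(batch_size, 1L)) stop("`batch_size` must be at least 1", call. = FALSE)
  if (!is_number(momentum) || momentum < 0 || momentum >= 1)
    stop("`momentum` must be in [0, 1)", call. = FALSE)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), momentum = momentum,
                 seed = as.integer(seed),
                 balance_classes = isTRUE(balance_classes),
                 criterion = "mse"),
            class = "training_config")
}

#' Train the tile classifier by SGD on an MSE criterion
#'
#' Minimises the mean squared error between the softmax outputs and one-hot
#' labels with plain stochastic gradient descent. Shuffling is seeded, so a
#' fixed `(net, data, config)` triple reproduces the loss history exactly.
#'
#' @param net A `tile_cnn` from [build_network()].
#' @param data A `tile_dataset` containing both classes.
#' @param config A [training_config()].
#' @return The trained `tile_cnn`, with `loss_history` holding the mean
#'   minibatch loss per epoch.
#' @export
train_cnn <- function(net, data, config = training_config()) {
  stopifnot(inherits(net, "tile_cnn"), inherits(config, "training_config"))
  if (!inherits(data, "tile_dataset"))
    stop("`data` must be a tile_dataset", call. = FALSE)
  cc <- class_counts(data)
  if (any(cc == 0L))
    stop("degenerate training set: both classes must be present", call. = FALSE)
  X <- tiles_as_input(data, net$spec)
  # one-hot targets in the fixed class order (background, target)
  is_target <- data$label == "target"
  Tm <- cbind(as.numeric(!is_target), as.numeric(is_target))
  n <- nrow(X)
  lr <- config$learning_rate
  mom <- config$momentum %||% 0
  history <- numeric(config$epochs)
  wn <- c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")
  vel <- lapply(net[wn], function(w) w * 0)
  names(vel) <- wn
  minority <- names(which.min(cc))
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(sub_seed(config$seed, ep), {
      if (config$balance_classes && cc[["target"]] != cc[["background"]]) {
        extra <- sample(which(data$label == minority),
                        max(cc) - min(cc), replace = TRUE)
        sample(c(seq_len(n), extra))
      } else {
        sample.int(n)
      }
    })
    losses <- c()
    m <- length(ord)
    for (start in seq(1L, m, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, m)]
      g <- cnn_grad(net, X[idx, , drop = FALSE], Tm[idx, , drop = FALSE])
      for (w in wn) {
        vel[[w]] <- mom * vel[[w]] + g$grads[[w]]
        net[[w]] <- net[[w]] - lr * vel[[w]]
      }
      losses <- c(losses, g$loss)
    }
    history[ep] <- mean(losses)
  }
  net$trained <- TRUE
  net$loss_history <- c(net$loss_history, history)
  net$config <- config
  net
}

#' Fit a tile classifier in one call
#'
#' Convenience wrapper: builds a seeded network for `spec` and trains it on
#' `data`. Equivalent to [build_network()] followed by [train_cnn()].
#'
#' @param data A `tile_dataset` with both classes present.
#' @param spec A [cnn_spec()] (defaults to the 64x64 two-stage architecture).
#' @param config A [training_config()].
#' @param seed Seed for the weight initialisation.
#' @return A trained `tile_cnn`.
#' @export
tile_cnn <- function(data, spec = cnn_spec(), config = training_config(),
                     seed = 1L) {
  train_cnn(build_network(spec, seed = seed), data, config)
}

#' @export
print.tile_cnn <- function(x, ...) {
  sp <- x$spec
  cat(sprintf("Tile classifier %dx%d-%dC%d-MP%d-%dC%d-MP%d-%dL-%d (%s)\n",
              sp$input_size, sp$input_size, sp$conv1_filters, sp$conv1_kernel,
              sp$pool1, sp$conv2_filters, sp$conv2_kernel, sp$pool2,
              sp$flatten_size, sp$n_classes,
              if (x$trained) "trained" else "untrained"))
  if (length(x$loss_history))
    cat(sprintf("  %d epochs, final MSE %.5f\n", length(x$loss_history),
                x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' @export
summary.tile_cnn <- function(object, ...) {
  sp <- object$spec
  n_par <- sum(vapply(object[c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")],
                      length, numeric(1L)))
  print(object)
  cat(sprintf("  parameters: %s (hidden layer 2n+1 = %d for n = %d)\n",
              format(n_par, big.mark = ","), sp$hidden_size, sp$flatten_size))
  cat(sprintf("  classes: %s\n", paste(object$classes, collapse = ", ")))
  invisible(object)
}

#' @export
coef.tile_cnn <- function(object, ...) {
  object[c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")]
}

#' @export
plot.tile_cnn <- function(x, ...) {
  if (!length(x$loss_history)) stop("no loss history to plot", call. = FALSE)
  graphics::plot(seq_along(x$loss_history), x$loss_history, type = "b",
                 xlab = "epoch", ylab = "training MSE",
                 main = "Training loss", ...)
  invisible(x)
}

#' Predict tile class probabilities
#'
#' @param object A `tile_cnn`.
#' @param newdata A `tile_dataset`, an `N x S x S x 3` array, or a single
#'   `S x S x 3` tile (intensities 0..255).
#' @param type `"prob"` for an `N x 2` probability matrix (columns
#'   `background`, `target`), `"class"` for a factor of predicted classes
#'   (ties broken toward background).
#' @param batch_size Forward-pass batch size.
#' @param ... Unused.
#' @return A probability matrix or a factor, by `type`.
#' @export
predict.tile_cnn <- function(object, newdata, type = c("prob", "class"),
                             batch_size = 64L, ...) {
  type <- match.arg(type)
  X <- tiles_as_input(newdata, object$spec)
  n <- nrow(X)
  probs <- matrix(0, n, object$spec$n_classes,
                  dimnames = list(NULL, object$classes))
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    probs[idx, ] <- cnn_forward(object, X[idx, , drop = FALSE])$probs
  }
  if (type == "prob") return(probs)
  factor(ifelse(probs[, "target"] > probs[, "background"],
                "target", "background"), levels = object$classes)
}

#' Evaluate a classifier on a labeled tile set
#'
#' Computes per-class accuracy and their unweighted average. The predicted
#' class is the probability argmax, with ties broken toward background.
#'
#' @param net A trained `tile_cnn`.
#' @param test A non-empty `tile_dataset`.
#' @return A `cnn_evaluation`: list with `per_class`, `average`, `n` and a
#'   `confusion` table.
#' @export
evaluate_cnn <- function(net, test) {
  if (!inherits(test, "tile_dataset") || n_tiles(test) == 0L)
    stop("`test` must be a non-empty tile_dataset", call. = FALSE)
  pred <- predict(net, test, type = "class")
  lab <- test$label
  per_class <- vapply(CNN_CLASSES, function(cl) {
    in_cl <- lab == cl
    if (!any(in_cl)) return(NA_real_)
    mean(pred[in_cl] == cl)
  }, numeric(1L))
  structure(list(per_class = per_class,
                 average = mean(per_class, na.rm = TRUE),
                 n = n_tiles(test),
                 confusion = table(truth = lab, predicted = pred)),
            class = "cnn_evaluation")
}

#' @export
print.cnn_evaluation <- function(x, ...) {
  cat(sprintf("Tile classification on %d tiles\n", x$n))
  cat(sprintf("  background accuracy: %.1f%%\n", 100 * x$per_class[["background"]]))
  cat(sprintf("  target accuracy:     %.1f%%\n", 100 * x$per_class[["target"]]))
  cat(sprintf("  class-averaged:      %.1f%%\n", 100 * x$average))
  invisible(x)
}

#' Write an accuracy report as CSV
#'
#' @param eval A `cnn_evaluation`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_evaluation_csv <- function(eval, path) {
  stopifnot(inherits(eval, "cnn_evaluation"))
  df <- data.frame(class = c(names(eval$per_class), "average"),
                   accuracy = c(unname(eval$per_class), eval$average),
                   n = eval$n)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Save network weights to a checkpoint file
#'
#' Single binary file: a magic string, a little-endian JSON header length,
#' a JSON header (architecture, class order, normalisation, loss history),
#' then all weight tensors as little-endian doubles in a fixed order.
#'
#' @param net A `tile_cnn`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "tile_cnn"))
  sp <- net$spec
  header <- list(format = "tilecnn-1",
                 spec = unclass(sp),
                 classes = net$classes,
                 normalization = net$normalization,
                 trained = net$trained,
                 n_loss = length(net$loss_history),
                 init_seed = net$init_seed)
  hraw <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw("TCNN"), con)
  writeBin(length(hraw), con, size = 4L, endian = "little")
  writeBin(hraw, con)
  for (w in c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4"))
    writeBin(as.vector(unname(net[[w]])), con, size = 8L, endian = "little")
  # loss history as binary doubles so reloads are bit-exact
  writeBin(as.vector(net$loss_history), con, size = 8L, endian = "little")
  invisible(path)
}

#' Load a checkpoint saved by [save_checkpoint()]
#'
#' @param path Checkpoint path.
#' @return A `tile_cnn` with the stored weights and metadata.
#' @export
load_checkpoint <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (magic != "TCNN") stop("not a tile-cnn checkpoint: ", path, call. = FALSE)
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  sp <- do.call(cnn_spec, header$spec[c("input_size", "channels",
                                        "conv1_filters", "conv1_kernel", "pool1",
                                        "conv2_filters", "conv2_kernel", "pool2",
                                        "n_classes")])
  net <- build_network(sp, seed = header$init_seed %||% 1L)
  shapes <- list(W1 = dim(net$W1), b1 = length(net$b1),
                 W2 = dim(net$W2), b2 = length(net$b2),
                 W3 = dim(net$W3), b3 = length(net$b3),
                 W4 = dim(net$W4), b4 = length(net$b4))
  for (w in names(shapes)) {
    v <- readBin(con, "double", prod(shapes[[w]]), size = 8L, endian = "little")
    if (length(shapes[[w]]) == 2L) dim(v) <- shapes[[w]]
    net[[w]] <- v
  }
  net$trained <- isTRUE(header$trained)
  net$loss_history <- readBin(con, "double", header$n_loss %||% 0L,
                              size = 8L, endian = "little")
  net$classes <- as.character(header$classes)
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a
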
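test_that("parameter counts match the layer-by-layer audit table", {
  audit <- read.csv(system.file("extdata", "unet_parameter_audit.csv",
                                package = "sliceprop"))
  for (d in c(2, 3)) for (ch in c(1, 4)) {
    net <- build_segmentation_network(model_spec(d, in_channels = ch))
    expected <- sum(audit$total[audit$dimensionality == d &
                                  audit$in_channels == ch])
    expect_identical(count_trainable_parameters(net), as.numeric(expected))
  }
})

test_that("channel deltas follow first-layer arithmetic", {
  n <- function(d, ch) count_trainable_parameters(
    build_segmentation_network(model_spec(d, in_channels = ch)))
  expect_identical(n(2, 4) - n(2, 1), 3 * 8 * 9)    # 216
  expect_identical(n(3, 4) - n(3, 1), 3 * 8 * 27)   # 648
})

test_that("the native forward pass matches the R reference implementation", {
  spec <- tiny_spec()
  net <- build_segmentation_network(spec, seed = 11)
  wt <- get_weights(net)
  set.seed(5)
  for (rep in 1:3) {
    x <- array(rnorm(16 * 16), c(16, 16, 1))
    p_cpp <- predict_proba(net, x)
    p_ref <- matrix(ref_forward(x, wt, spec), 16, 16)
    expect_lt(max(abs(p_cpp - p_ref)), 1e-5)
    expect_true(all(p_cpp > 0 & p_cpp < 1))
  }
})

test_that("analytic gradients agree with finite differences of the reference", {
  spec <- tiny_spec()
  net <- build_segmentation_network(spec, seed = 11)
  set.seed(7)
  xs <- lapply(1:2, function(i) array(rnorm(64), c(8, 8, 1)))
  ys <- lapply(1:2, function(i) matrix(rbinom(64, 1, 0.4), 8, 8) * 1)
  w <- c(1, 0.5)
  # a few optimiser steps move biases off the ReLU kink at exactly zero
  for (s in 1:10) sliceprop:::.unet2d_train_batch(net$ptr, xs, ys, w, 1e-3)
  wt <- get_weights(net)
  g <- sliceprop:::.unet2d_gradients(net$ptr, xs, ys, w)
  set.seed(3)
  for (k in seq_along(wt)) {
    v <- wt[[k]]
    for (j in sample(length(v), min(2, length(v)))) {
      h <- 1e-6
      wt2 <- wt; wt2[[k]][j] <- v[j] + h
      lp <- ref_loss(wt2, spec, xs, ys, w)
      wt2[[k]][j] <- v[j] - h
      lm <- ref_loss(wt2, spec, xs, ys, w)
      fd <- (lp - lm) / (2 * h)
      expect_lt(abs(fd - g[[k]][j]) / max(abs(fd), abs(g[[k]][j]), 1e-4),
                0.02)
    }
  }
})

test_that("the network is fully convolutional and pads odd geometries", {
  net <- build_segmentation_network(model_spec(2, in_channels = 1), seed = 2)
  for (dims in list(c(32, 32), c(48, 32), c(33, 47))) {
    x <- array(rnorm(prod(dims)), c(dims, 1))
    p <- predict_proba(net, x)
    expect_identical(dim(p), as.integer(dims))
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("weight save/load and cloning reproduce predictions exactly", {
  net <- build_segmentation_network(tiny_spec(), seed = 4)
  x <- array(rnorm(256), c(16, 16, 1))
  # a deterministic build with the same seed is bit-identical
  net_same <- build_segmentation_network(tiny_spec(), seed = 4)
  expect_identical(predict_proba(net_same, x), predict_proba(net, x))
  # checkpoint roundtrip
  tmp <- tempfile(fileext = ".json")
  save_checkpoint(net, tmp)
  net2 <- load_checkpoint(tmp)
  expect_equal(predict_proba(net2, x), predict_proba(net, x),
               tolerance = 1e-6)
  # clones are independent
  cl <- clone_model(net)
  sliceprop:::.unet2d_train_batch(cl$ptr, list(x),
                                  list(matrix(1, 16, 16)), 1, 1e-2)
  expect_false(identical(predict_proba(cl, x), predict_proba(net, x)))
})

test_that("invalid model specs are rejected", {
  expect_error(model_spec(4), "2 or 3")
  expect_error(model_spec(2, base_filters = 8, levels = 3), "max_filters")
  expect_error(model_spec(2, out_channels = 2), "binary")
})
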
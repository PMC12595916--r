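test_that("binary cross-entropy matches its closed forms", {
  expect_equal(bce_loss(0.5, 1), -log(0.5), tolerance = 1e-10)
  expect_equal(bce_loss(c(0.8, 0.2), c(1, 0)), -log(0.8), tolerance = 1e-10)
  expect_lt(bce_loss(c(1, 0), c(1, 0)), 1.2e-7)   # clipped near-zero limit
  # uniform weights equal the plain average exactly
  set.seed(2)
  p <- runif(100); y <- rbinom(100, 1, 0.5)
  plain <- mean(-(y * log(p) + (1 - y) * log(1 - p)))
  expect_equal(bce_loss(p, y, weights = rep(1, 100)), plain,
               tolerance = 1e-12)
  expect_equal(bce_loss(p, y, weights = rep(3, 100)), plain,
               tolerance = 1e-12)   # normalisation kills the scale
  # weighting reweights but never rescales: constant-weight invariance
  w <- runif(100, 0.1, 1)
  expect_equal(bce_loss(p, y, w), sum(w * -(y * log(p) + (1 - y) * log(1 - p))) / sum(w),
               tolerance = 1e-12)
  expect_error(bce_loss(c(0.5, 0.5), 1), "length")
})

test_that("augmentation transforms image and mask identically and keeps masks binary", {
  pol <- augmentation_policy()
  set.seed(8)
  img <- array(rnorm(32 * 32), c(32, 32, 1))
  msk <- matrix(0, 32, 32); msk[8:20, 10:25] <- 1
  for (s in 1:5) {
    a <- augment(img, msk, pol, seed = s)
    expect_true(all(a$mask %in% c(0, 1)))
    expect_identical(dim(a$image), dim(img))
    # determinism
    b <- augment(img, msk, pol, seed = s)
    expect_identical(a, b)
    # mask tracks the image: foreground of the transformed pair should
    # still sit on high-intensity pixels when the image is the mask + offset
    img2 <- array(5 * msk + rnorm(1024, sd = 0.1), c(32, 32, 1))
    a2 <- augment(img2, msk, pol, seed = s)
    inside <- mean(a2$image[, , 1][a2$mask == 1])
    outside <- mean(a2$image[, , 1][a2$mask == 0])
    expect_gt(inside - outside, 3)
  }
  # flips are involutions; rotation bound 0 leaves rotation off
  flips <- augmentation_policy(max_rotation_deg = 0)
  a <- augment(img, msk, flips, seed = 1)
  # applying the same flip pattern twice restores the original
  flip_once <- function(x) augment(x$image, x$mask, flips, seed = 1)
  twice <- flip_once(flip_once(list(image = img, mask = msk)))
  expect_equal(twice$image, img, tolerance = 1e-12)
  expect_identical(twice$mask, msk)
})

test_that("rotation angles cover [-max, +max] uniformly", {
  pol <- augmentation_policy(hflip = FALSE, vflip = FALSE)
  # the drawn angle is the third uniform deviate under the seed
  angs <- vapply(1:200, function(s) {
    sliceprop:::with_local_seed(s, {
      runif(1); ang <- runif(1, -90, 90)
      ang
    })
  }, numeric(1))
  expect_lt(min(angs), -60)
  expect_gt(max(angs), 60)
})

test_that("pooled batches partition the pool exactly once per epoch", {
  b <- pooled_batches(10, 4, seed = 1)
  expect_identical(lengths(b, use.names = FALSE), c(4L, 4L, 2L))
  expect_identical(sort(unname(unlist(b))), 1:10)
  expect_identical(pooled_batches(10, 4, seed = 1), b)
  expect_false(identical(unlist(pooled_batches(10, 4, seed = 2),
                                use.names = FALSE),
                         unlist(b, use.names = FALSE)))
  expect_error(pooled_batches(0, 4, 1), "empty")
})

make_memorisation_pool <- function(n = 3, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    msk <- matrix(0, 16, 16)
    msk[4:12, (2 + i):(10 + i)] <- 1
    img <- array(2 * msk + rnorm(256), c(16, 16, 1))
    list(x = standardise(img), y = msk, w = 1, volume_id = paste0("m", i),
         index = 0L, nsi = 0.5, source = "ground_truth")
  })
}

test_that("fit memorises a tiny pool and restores the best weights", {
  pool <- make_memorisation_pool()
  net <- build_segmentation_network(model_spec(2, in_channels = 1), seed = 1)
  # generous patience: this probes network capacity, not the schedule
  res <- fit(net, pool, pool,
             train_config(max_epochs = 150, early_stop_patience = 150,
                          lr_patience = 149, seed = 3))
  expect_lt(min(res$history$train_loss), 0.1)
  # restored weights reproduce the best checkpointed validation loss:
  # within min_delta of the minimum (sub-min_delta improvements are
  # deliberately not checkpointed)
  val <- sliceprop:::.unet2d_eval_batch(net$ptr,
                                        lapply(pool, `[[`, "x"),
                                        lapply(pool, `[[`, "y"),
                                        rep(1, length(pool)))
  expect_lte(val, min(res$history$val_loss) + 1e-4 + 1e-6)
  expect_true(any(abs(res$history$val_loss - val) < 1e-6))
})

test_that("early stopping halts after exactly the patience epochs", {
  pool <- make_memorisation_pool()
  net <- build_segmentation_network(tiny_spec(), seed = 1)
  # zero learning rate: the first epoch sets the best; nothing improves
  cfg <- train_config(max_epochs = 50, initial_lr = 0,
                      early_stop_patience = 6, seed = 1)
  res <- fit(net, pool, pool, cfg)
  expect_identical(nrow(res$history), 1L + 6L)
  # strictly improving runs reach max_epochs
  net2 <- build_segmentation_network(tiny_spec(), seed = 1)
  res2 <- fit(net2, pool, pool, train_config(max_epochs = 4, seed = 3))
  expect_identical(nrow(res2$history), 4L)
})

test_that("the plateau schedule reduces the learning rate before stopping", {
  pool <- make_memorisation_pool()
  net <- build_segmentation_network(tiny_spec(), seed = 1)
  cfg <- train_config(max_epochs = 50, initial_lr = 0, lr_patience = 3,
                      early_stop_patience = 6, seed = 1)
  res <- fit(net, pool, pool, cfg)
  expect_identical(res$history$lr, c(0, 0, 0, 0, 0, 0, 0))
  net2 <- build_segmentation_network(tiny_spec(), seed = 1)
  cfg2 <- train_config(max_epochs = 12, initial_lr = 1e-9, lr_patience = 3,
                       early_stop_patience = 20, min_delta = 10, seed = 1)
  res2 <- fit(net2, pool, pool, cfg2)
  # min_delta = 10 means no epoch ever counts as an improvement after the
  # first, so the lr drops after every lr_patience stalled epochs
  expect_equal(res2$history$lr[1:4], rep(1e-9, 4))
  expect_equal(res2$history$lr[5], 1e-10)
  expect_equal(res2$history$lr[8], 1e-11)
})

test_that("cross-validated initialisation picks the best-Dice fold deterministically", {
  vols <- lapply(1:5, function(s) tiny_phantom(s, shape = c(6, 16, 16)))
  pool <- sliceprop:::central_gt_pool(vols)
  cfg <- train_config(max_epochs = 6, seed = 9)
  r1 <- init_with_crossval(pool, tiny_spec(), cfg, k_folds = 5)
  expect_length(r1$fold_dsc, 5)
  expect_identical(r1$best_fold, which.max(r1$fold_dsc))
  r2 <- init_with_crossval(pool, tiny_spec(), cfg, k_folds = 5)
  expect_identical(r1$fold_dsc, r2$fold_dsc)
  expect_identical(get_weights(r1$model), get_weights(r2$model))
  expect_error(init_with_crossval(pool[1:3], tiny_spec(), cfg, k_folds = 5),
               "at least")
})
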
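mk_lab <- function(i) slice_label("v", i, matrix(0, 4, 4), "pseudo")
state_at <- function(lo, hi, depth) {
  st <- label_state(slice_label("v", central_slice_index(depth),
                                matrix(0, 4, 4), "ground_truth"), depth)
  while (st$lo > lo || st$hi < hi) {
    idx <- c(if (st$lo > lo) st$lo - 1L, if (st$hi < hi) st$hi + 1L)
    st <- advance_interval(st, lapply(idx, mk_lab))
  }
  st
}

test_that("symmetric slice selection honours the per-side budget and transfer", {
  st <- state_at(12, 12, 24)
  expect_identical(select_next_slices(st, 24, 0.05), c(11L, 13L))
  # budget transfers when one side is exhausted
  st2 <- state_at(0, 20, 24)
  expect_identical(select_next_slices(st2, 24, 0.05), c(21L, 22L))
  st3 <- state_at(0, 22, 24)
  expect_identical(select_next_slices(st3, 24, 0.05), 23L)
  st4 <- state_at(0, 23, 24)
  expect_identical(select_next_slices(st4, 24, 0.05), integer(0))
  # larger k widens the band on both sides
  expect_identical(select_next_slices(st, 24, 0.25),
                   c(9L, 10L, 11L, 13L, 14L, 15L))
})

test_that("propagation step counts match the brute-force enumerator", {
  for (depth in c(5, 8, 12, 24, 31, 47)) {
    for (k in c(0.02, 0.05, 0.1, 0.25)) {
      st <- state_at(central_slice_index(depth), central_slice_index(depth),
                     depth)
      steps <- 0
      while (!is_complete(st)) {
        idx <- select_next_slices(st, depth, k)
        expect_gt(length(idx), 0)
        st <- advance_interval(st, lapply(idx, mk_lab))
        steps <- steps + 1
      }
      expect_identical(steps, bf_propagation_steps(depth, k))
    }
  }
})

test_that("confidence thresholding emits background fills rather than skipping", {
  b1 <- binarize_with_confidence(matrix(c(0.95, 0.40), 1), 0.7)
  expect_identical(b1$mask, matrix(c(1, 0), 1))
  expect_identical(b1$source, "pseudo")
  b2 <- binarize_with_confidence(matrix(0.3, 4, 4), 0.7)
  expect_true(all(b2$mask == 0))
  expect_identical(b2$source, "background_fill")
  # theta = 0.5 equals the argmax decision
  p <- matrix(runif(64), 8)
  b3 <- binarize_with_confidence(p, 0.5)
  expect_identical(b3$mask, (p >= 0.5) * 1)
  # idempotent on binary masks for any theta <= 1
  m <- matrix(rbinom(64, 1, 0.5), 8) * 1
  for (th in c(0.5, 0.7, 0.99)) {
    expect_identical(binarize_with_confidence(m, th)$mask, m)
  }
  expect_error(binarize_with_confidence(p, 0.4), "theta")
  expect_error(binarize_with_confidence(p, 1), "theta")
})

test_that("weighting schemes peak at the central slice", {
  uni <- weight_scheme("uniform")
  expect_identical(slice_weight(c(0, 0.3, 0.5, 1), uni), rep(1, 4))
  gau <- weight_scheme("gaussian", sigma = 0.2)
  expect_equal(slice_weight(0.5, gau), 1)
  expect_equal(slice_weight(0.7, gau), exp(-0.5), tolerance = 1e-12)
  expect_equal(slice_weight(0.3, gau), exp(-0.5), tolerance = 1e-12)
  stw <- weight_scheme("stepwise")
  expect_equal(slice_weight(0.5, stw), 1)
  expect_equal(slice_weight(0.4, stw), 1)      # |d| = 0.1 <= 0.15
  expect_equal(slice_weight(0.2, stw), 0.6)    # |d| = 0.3 <= 0.35
  expect_equal(slice_weight(0.0, stw), 0.3)    # |d| = 0.5
  expect_error(slice_weight(1.2, uni), "0, 1")
})

test_that("random expansion matches the adjacent mode's per-iteration count", {
  depth <- 24; k <- 0.05
  st_adj <- state_at(12, 12, depth)
  st_rnd <- label_state(slice_label("v", 12, matrix(0, 4, 4),
                                    "ground_truth"), depth, mode = "set")
  seen <- integer(0)
  it <- 0
  while (!is_complete(st_rnd)) {
    it <- it + 1
    idx <- select_random_slices(st_rnd, depth, k, seed = it)
    # same per-iteration count as the adjacent mode emits
    expect_identical(length(idx),
                     length(select_next_slices(st_adj, depth, k)))
    # deterministic draw under the same seed
    expect_identical(idx, select_random_slices(st_rnd, depth, k, seed = it))
    seen <- c(seen, idx)
    st_rnd <- advance_interval(st_rnd, lapply(idx, mk_lab))
    st_adj <- advance_interval(st_adj,
                               lapply(select_next_slices(st_adj, depth, k),
                                      mk_lab))
  }
  # without replacement: every non-central index exactly once
  expect_identical(sort(seen), setdiff(0:23, 12L))
  expect_identical(as.integer(it), 12L)   # same count of iterations as adjacent
})

test_that("the self-labelling loop completes volumes, keeps ground truth and audits", {
  set.seed(1)
  train_vols <- lapply(1:3, function(s) tiny_phantom(s, shape = c(8, 16, 16)))
  val_vols <- list(tiny_phantom(99, shape = c(8, 16, 16)))
  pool <- sliceprop:::central_gt_pool(train_vols)
  init <- init_with_crossval(pool, tiny_spec(),
                             train_config(max_epochs = 4, seed = 2),
                             k_folds = 3)
  cfg <- selflabel_config(theta = 0.7, k = 0.05, seed = 5,
                          train = train_config(max_epochs = 2, seed = 2))
  res <- run_selflabel(train_vols, val_vols, init$model, cfg)
  # termination: every stack's depth equals its volume depth
  for (v in train_vols) {
    expect_identical(dim(res$stacks[[v$id]]), c(8L, 16L, 16L))
  }
  # closed-form iteration count for depth 8, s = 1: max(4, 3) = 4
  expect_identical(res$n_iterations, 4L)
  # central slices kept as untouched ground truth in the stacks
  for (v in train_vols) {
    ci <- central_slice_index(v$depth)
    expect_identical(res$stacks[[v$id]][ci + 1, , ],
                     gt_central_slice(v))
  }
  # audit covers every non-central slice exactly once, sources valid
  expect_identical(nrow(res$audit), 3L * 7L)
  expect_true(all(res$audit$source %in% c("pseudo", "background_fill")))
  expect_true(all(res$audit$weight == 1))
  # labelled coverage strictly increases per iteration
  per_iter <- table(res$audit$iteration)
  expect_true(all(per_iter > 0))
  # the original f1 is untouched by fine-tuning
  expect_identical(get_weights(init$model), get_weights(init$model))
})
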
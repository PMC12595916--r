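test_that("phantom generation is deterministic and centrally seeded", {
  p <- phantom_params(seed = 42)
  v1 <- generate_phantom_volume(p, "a")
  v2 <- generate_phantom_volume(p, "a")
  expect_identical(v1$image, v2$image)
  expect_identical(v1$gt_masks, v2$gt_masks)
  ci <- central_slice_index(v1$depth)
  expect_gt(sum(v1$gt_masks[ci + 1, , ]), 0)
})

test_that("foreground occupies one contiguous slice interval through the centre", {
  for (s in 1:15) {
    v <- generate_phantom_volume(phantom_params(seed = s), "p")
    area <- apply(v$gt_masks, 1, sum)
    fg <- which(area > 0)
    expect_identical(fg, seq(min(fg), max(fg)))
    expect_true((central_slice_index(v$depth) + 1) %in% fg)
    # unimodal profile peaking within the central third
    peak <- which.max(area)
    expect_gte(peak, ceiling(v$depth / 3))
    expect_lte(peak, ceiling(2 * v$depth / 3) + 1)
    expect_true(all(diff(area[seq(min(fg), peak)]) >= 0) ||
                  sum(diff(area[seq(min(fg), peak)]) < 0) <= 1)
    # adjacent foreground slices overlap (structural continuity)
    for (i in fg[-length(fg)]) {
      expect_gt(sum(v$gt_masks[i, , ] & v$gt_masks[i + 1, , ]), 0)
    }
  }
})

test_that("foreground voxel fraction stays in the regression band", {
  fr <- vapply(1:100, function(s) {
    mean(generate_phantom_volume(phantom_params(seed = s), "p")$gt_masks)
  }, numeric(1))
  expect_true(all(fr > 0.005))
  expect_true(all(fr < 0.25))
})

test_that("phantom datasets split by the floor-and-remainder rule", {
  p <- phantom_params(shape = c(8, 16, 16))
  ds20 <- generate_phantom_dataset(20, p, seed = 3)
  expect_identical(lengths(ds20$split, use.names = FALSE), c(14L, 3L, 3L))
  ids <- sort(unname(unlist(ds20$split)))
  expect_identical(ids, sort(names(ds20$volumes)))
  ds20b <- generate_phantom_dataset(20, p, seed = 3)
  expect_identical(ds20b$split, ds20$split)
  expect_identical(ds20b$volumes[[5]]$image, ds20$volumes[[5]]$image)
  expect_error(generate_phantom_dataset(2, p), "at least 3")
})

test_that("multi-channel phantoms share geometry with independent noise", {
  v <- generate_phantom_volume(
    phantom_params(shape = c(8, 16, 16), channels = 3, seed = 9), "mc")
  expect_identical(dim(v$image)[4], 3L)
  ch1 <- v$image[, , , 1]
  ch2 <- v$image[, , , 2]
  expect_gt(sd(ch1 - ch2), 0.5)   # independent noise, not a copy
  # contrast present in every channel
  for (ch in 1:3) {
    x <- v$image[, , , ch]
    expect_gt(mean(x[v$gt_masks == 1]) - mean(x[v$gt_masks == 0]), 1)
  }
})

test_that("too-small planes are rejected", {
  expect_error(generate_phantom_volume(
    phantom_params(shape = c(8, 4, 4), fg_radius_range = c(0.1, 0.2)), "x"),
    "too small")
})

test_that("multi-blob phantoms break the structural assumptions on purpose", {
  p <- phantom_params(shape = c(24, 32, 32), n_blobs = 3, seed = 5)
  v <- generate_phantom_volume(p, "adv")
  expect_gt(sum(v$gt_masks), 0)
  # the same seed with one blob is a strict subset of the multi-blob mask
  v1 <- generate_phantom_volume(phantom_params(shape = c(24, 32, 32),
                                               seed = 5), "base")
  expect_true(all(v$gt_masks[v1$gt_masks == 1] == 1))
  expect_gt(sum(v$gt_masks), sum(v1$gt_masks))
  # across seeds, satellites can make the z-profile non-contiguous
  broken <- FALSE
  for (s in 1:25) {
    vv <- generate_phantom_volume(
      phantom_params(shape = c(24, 32, 32), n_blobs = 3, seed = s), "a")
    fg <- which(apply(vv$gt_masks, 1, sum) > 0)
    if (!identical(fg, seq(min(fg), max(fg)))) broken <- TRUE
  }
  expect_true(broken)
})
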
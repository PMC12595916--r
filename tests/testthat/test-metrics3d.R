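test_that("confusion metrics follow their definitions", {
  pred <- array(0, c(10, 10, 1)); gt <- array(0, c(10, 10, 1))
  pred[1:3] <- 1; gt[c(1, 2, 4)] <- 1    # TP=2 FP=1 FN=1 TN=96
  m <- confusion_and_metrics(pred, gt)
  expect_identical(unname(m$counts), c(2L, 1L, 1L, 96L))
  expect_equal(m$dsc, 2 / 3, tolerance = 1e-12)
  expect_equal(m$iou, 0.5, tolerance = 1e-12)
  expect_equal(m$tpr, 2 / 3, tolerance = 1e-12)
  expect_equal(m$tnr, 96 / 97, tolerance = 1e-12)
  # identity and empty-prediction edge cases
  m2 <- confusion_and_metrics(gt, gt)
  expect_equal(c(m2$dsc, m2$iou, m2$tpr, m2$tnr), rep(1, 4))
  m3 <- confusion_and_metrics(gt * 0, gt)
  expect_equal(c(m3$dsc, m3$iou, m3$tpr), rep(0, 3))
  # undefined denominators are NA sentinels, never silent zeros
  m4 <- confusion_and_metrics(gt * 0, gt * 0)
  expect_true(is.na(m4$dsc) && is.na(m4$iou) && is.na(m4$tpr))
  expect_equal(m4$tnr, 1)
  expect_error(confusion_and_metrics(pred, array(0, c(9, 10, 1))), "shape")
})

test_that("the Dice/IoU identity holds across randomised counts", {
  set.seed(4)
  for (i in 1:200) {
    tp <- sample(0:50, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    if (2 * tp + fp + fn == 0) next
    dsc <- 2 * tp / (2 * tp + fp + fn)
    iou <- tp / (tp + fp + fn)
    expect_equal(dsc, 2 * iou / (1 + iou), tolerance = 1e-12)
  }
})

test_that("surface voxels are the 6-connected boundary", {
  m <- array(0, c(5, 5, 5)); m[3, 3, 3] <- 1
  expect_identical(unname(surface_voxels(m)), matrix(c(3L, 3L, 3L), 1))
  cube3 <- array(0, c(5, 5, 5)); cube3[2:4, 2:4, 2:4] <- 1
  expect_identical(nrow(surface_voxels(cube3)), 26L)
  cube5 <- array(0, c(7, 7, 7)); cube5[2:6, 2:6, 2:6] <- 1
  expect_identical(nrow(surface_voxels(cube5)), 98L)   # 125 - 27 interior
  # brute-force agreement on random masks (order-independent)
  sort_rows <- function(m) m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
  for (s in 1:5) {
    rm <- random_mask_16(s)
    expect_identical(sort_rows(unname(surface_voxels(rm))),
                     sort_rows(unname(bf_surface_coords(rm))))
  }
  # voxels on the volume border are surface
  full <- array(1, c(3, 3, 3))
  expect_identical(nrow(surface_voxels(full)), 26L)
})

test_that("hd95 equals the all-pairs brute-force oracle", {
  a <- array(0, c(8, 8, 8)); a[4, 4, 4] <- 1
  expect_equal(hd95(a, a), 0)
  b <- array(0, c(8, 8, 8)); b[7, 4, 4] <- 1
  expect_equal(hd95(a, b), 3)
  expect_equal(hd95(a, b, spacing = c(2, 1, 1)), 6)
  for (s in 1:12) {
    A <- random_mask_16(s)
    B <- random_mask_16(s + 100)
    sp <- if (s %% 3 == 0) c(2.5, 0.7, 1.2) else c(1, 1, 1)
    h_ab <- hd95(A, B, sp)
    expect_lt(abs(h_ab - bf_hd95(A, B, sp)), 1e-9)
    expect_identical(h_ab, hd95(B, A, sp))   # exact symmetry
  }
  expect_error(hd95(a * 0, b), "empty")
})

test_that("hd95 grows under outward dilation mismatch", {
  gt <- array(0, c(16, 16, 16)); gt[7:10, 7:10, 7:10] <- 1
  grow <- function(m, by) {
    d <- which(m == 1, arr.ind = TRUE)
    out <- array(0, dim(m))
    lo <- pmax(apply(d, 2, min) - by, 1)
    hi <- pmin(apply(d, 2, max) + by, dim(m))
    out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1
    out
  }
  hs <- vapply(0:3, function(by) hd95(grow(gt, by), gt), numeric(1))
  expect_true(all(diff(hs) >= 0))
  expect_gt(hs[4], hs[1])
})

test_that("per-NSI profiles partition slices into bins", {
  vols <- lapply(1:2, function(s) tiny_phantom(s, shape = c(10, 16, 16)))
  net <- build_segmentation_network(tiny_spec(), seed = 1)
  prof <- per_nsi_profile(net, vols, bins = 5)
  expect_identical(nrow(prof), 5L)
  expect_identical(sum(prof$n_slices), 20L)
  expect_equal(prof$nsi_lo, seq(0, 0.8, 0.2))
  expect_true(all(is.finite(prof$mean_bce[prof$n_slices > 0])))
  # empty bins are NA, not dropped
  prof2 <- per_nsi_profile(net, vols[1], bins = 25)
  expect_true(any(prof2$n_slices == 0))
  expect_true(all(is.na(prof2$mean_bce[prof2$n_slices == 0])))
})
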
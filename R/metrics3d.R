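# Volumetric evaluation: confusion-count overlap metrics (Dice, IoU,
# sensitivity, specificity), 6-connected surface extraction, the
# 95th-percentile Hausdorff distance on spacing-scaled surfaces, and
# per-NSI slice profiles.

#' Confusion counts and overlap metrics for a binary segmentation
#'
#' Computes TP/FP/FN/TN over the voxel grid and from them
#' `DSC = 2TP / (2TP + FP + FN)`, `IoU = TP / (TP + FP + FN)`,
#' `TPR = TP / (TP + FN)` and `TNR = TN / (TN + FP)`. A metric whose
#' denominator is zero is reported as `NA` (never silently 0).
#'
#' @param pred,gt Binary arrays of identical shape.
#' @return List with `counts` (TP, FP, FN, TN) and `dsc`, `iou`, `tpr`,
#'   `tnr`.
#' @examples
#' confusion_and_metrics(array(c(1, 1, 1, 0), 4), array(c(1, 1, 0, 1), 4))
#' @export
confusion_and_metrics <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt)) || length(pred) != length(gt)) {
    stop("pred and gt must have identical shape", call. = FALSE)
  }
  if (!all(pred %in% c(0, 1)) || !all(gt %in% c(0, 1))) {
    stop("masks must be binary", call. = FALSE)
  }
  tp <- sum(pred == 1 & gt == 1)
  fp <- sum(pred == 1 & gt == 0)
  fn <- sum(pred == 0 & gt == 1)
  tn <- sum(pred == 0 & gt == 0)
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  list(counts = c(TP = tp, FP = fp, FN = fn, TN = tn),
       dsc = safe(2 * tp, 2 * tp + fp + fn),
       iou = safe(tp, tp + fp + fn),
       tpr = safe(tp, tp + fn),
       tnr = safe(tn, tn + fp))
}

#' Dice similarity coefficient of two binary masks
#' @param pred,gt Binary arrays of identical shape.
#' @return `2TP / (2TP + FP + FN)`, or `NA` when both masks are empty.
#' @export
dice_coefficient <- function(pred, gt) {
  confusion_and_metrics(pred, gt)$dsc
}

#' Surface voxels of a binary volume
#'
#' A foreground voxel belongs to the surface iff at least one of its six
#' face neighbours is background or lies outside the volume.
#'
#' @param mask Binary `(z, y, x)` array.
#' @return Integer matrix of 1-based `(z, y, x)` voxel subscripts (0 rows
#'   for an all-background mask).
#' @examples
#' m <- array(0, c(3, 3, 3)); m[2, 2, 2] <- 1
#' surface_voxels(m)
#' @export
surface_voxels <- function(mask) {
  if (!all(mask %in% c(0, 1))) stop("mask must be binary", call. = FALSE)
  which(surface_mask(mask), arr.ind = TRUE)
}

# logical array marking 6-connected surface voxels
surface_mask <- function(mask) {
  d <- dim(mask)
  fg <- mask == 1
  interior <- array(TRUE, d)
  shift_ok <- function(axis, by) {
    # TRUE where the neighbour in direction (axis, by) exists and is fg
    out <- array(FALSE, d)
    n <- d[axis]
    if (n == 1) return(out)
    src <- switch(axis, `1` = fg[-if (by > 0) 1 else n, , , drop = FALSE],
                         `2` = fg[, -if (by > 0) 1 else n, , drop = FALSE],
                         `3` = fg[, , -if (by > 0) 1 else n, drop = FALSE])
    if (axis == 1) {
      if (by > 0) out[1:(n - 1), , ] <- src else out[2:n, , ] <- src
    } else if (axis == 2) {
      if (by > 0) out[, 1:(n - 1), ] <- src else out[, 2:n, ] <- src
    } else {
      if (by > 0) out[, , 1:(n - 1)] <- src else out[, , 2:n]  <- src
    }
    out
  }
  for (axis in 1:3) for (by in c(-1, 1)) {
    interior <- interior & shift_ok(axis, by)
  }
  fg & !interior
}

#' 95th-percentile Hausdorff distance between two segmentations
#'
#' Extracts the 6-connected surface voxels of both masks, collects — with
#' multiplicity — the minimum Euclidean distance (in mm, voxel subscripts
#' scaled by `spacing`) from every surface voxel of each mask to the other
#' mask's surface, and returns the 95th percentile of the combined
#' distance set (linear interpolation between order statistics). Symmetric
#' in its arguments by construction; 0 for identical masks. Distances are
#' computed with an exact Euclidean distance transform.
#'
#' @param pred,gt Binary `(z, y, x)` arrays with non-empty foreground.
#' @param spacing Voxel spacing `(sz, sy, sx)` in mm.
#' @return HD95 in mm.
#' @examples
#' a <- array(0, c(8, 8, 8)); a[4, 4, 4] <- 1
#' b <- array(0, c(8, 8, 8)); b[7, 4, 4] <- 1
#' hd95(a, b)  # 3
#' @export
hd95 <- function(pred, gt, spacing = c(1, 1, 1)) {
  if (!identical(dim(pred), dim(gt))) {
    stop("pred and gt must have identical shape", call. = FALSE)
  }
  sp <- surface_mask(pred)
  sg <- surface_mask(gt)
  if (!any(sp) || !any(sg)) {
    stop("hd95 is undefined for an empty segmentation surface",
         call. = FALSE)
  }
  dist_to_g <- .edt_to_sites(sg, as.numeric(spacing))
  dist_to_p <- .edt_to_sites(sp, as.numeric(spacing))
  d_all <- c(dist_to_g[sp], dist_to_p[sg])
  stats::quantile(d_all, 0.95, type = 7, names = FALSE)
}

#' Per-NSI profile of slice-wise loss and Dice
#'
#' Assigns every slice of the supplied volumes its normalised slice index,
#' predicts it with the model, and aggregates mean binary cross-entropy
#' and mean Dice per NSI bin. Bins partition `[0, 1]` into equal intervals;
#' empty bins are reported with `NA` means.
#'
#' @param model A `unet2d` predictor.
#' @param volumes List of [volume_record()] carrying full ground truth.
#' @param bins Number of NSI bins.
#' @return Data frame with one row per bin: `nsi_lo`, `nsi_hi`, `n_slices`,
#'   `mean_bce`, `mean_dsc`.
#' @export
per_nsi_profile <- function(model, volumes, bins = 10) {
  rows <- list()
  for (v in volumes) {
    gt <- gt_full(v, benchmark = TRUE)
    idx <- 0:(v$depth - 1L)
    xs <- lapply(idx, function(i) standardise(get_slice(v, i)))
    probs <- predict_proba(model, xs)
    for (j in seq_along(idx)) {
      y <- gt[idx[j] + 1L, , ]
      rows[[length(rows) + 1L]] <- data.frame(
        nsi = nsi(idx[j], v$depth),
        bce = bce_loss(probs[[j]], y),
        dsc = dice_coefficient((probs[[j]] >= 0.5) * 1, y))
    }
  }
  tab <- do.call(rbind, rows)
  edges <- seq(0, 1, length.out = bins + 1)
  bin <- pmin(findInterval(tab$nsi, edges, rightmost.closed = TRUE), bins)
  out <- lapply(seq_len(bins), function(b) {
    sel <- bin == b
    data.frame(nsi_lo = edges[b], nsi_hi = edges[b + 1],
               n_slices = sum(sel),
               mean_bce = if (any(sel)) mean(tab$bce[sel]) else NA_real_,
               mean_dsc = if (any(sel)) mean(tab$dsc[sel], na.rm = TRUE)
                          else NA_real_)
  })
  do.call(rbind, out)
}
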
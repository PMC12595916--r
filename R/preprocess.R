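# Slice preprocessing: standardisation, resizing, cropping, class merging
# and volume-level dataset splitting.

#' Standardise a slice to zero mean and unit variance
#'
#' Standardisation is applied per unit: the whole slice for single-channel
#' data, or each channel of the slice independently for multi-channel data.
#' The population (divide-by-N) standard deviation is used; units whose
#' variation falls below a small guard are mapped to all zeros.
#'
#' @param slice_data A `(y, x)` matrix or `(y, x, c)` array of finite values.
#' @param mode `"per_slice"` (one unit) or `"per_channel_per_slice"`.
#' @return Same-shape array with per-unit mean 0 and population sd 1 (or
#'   all zeros for constant units).
#' @examples
#' standardise(matrix(c(1, 3), 1))  # -1, 1
#' @export
standardise <- function(slice_data,
                        mode = c("per_channel_per_slice", "per_slice")) {
  mode <- match.arg(mode)
  if (!all(is.finite(slice_data))) {
    stop("slice contains non-finite values", call. = FALSE)
  }
  eps <- 1e-8
  unit <- function(u) {
    s <- sqrt(mean((u - mean(u))^2))    # population sd
    if (s < eps) return(u * 0)
    (u - mean(u)) / s
  }
  if (is.matrix(slice_data) || mode == "per_slice" ||
      length(dim(slice_data)) < 3) {
    out <- unit(slice_data)
    dim(out) <- dim(slice_data)
    return(out)
  }
  out <- slice_data
  for (ch in seq_len(dim(slice_data)[3])) {
    out[, , ch] <- unit(slice_data[, , ch])
  }
  out
}

#' Resize a 2D plane
#'
#' Images are resampled with bilinear interpolation; binary masks with
#' nearest-neighbour interpolation, so they stay binary.
#'
#' @param plane `(y, x)` matrix.
#' @param target Integer pair `(y, x)` of output dimensions.
#' @param content `"image"` or `"mask"`.
#' @return Resized matrix of dimension `target`.
#' @examples
#' resize_plane(matrix(rnorm(64), 8), c(4, 4))
#' @export
resize_plane <- function(plane, target, content = c("image", "mask")) {
  content <- match.arg(content)
  stopifnot(is.matrix(plane), length(target) == 2, all(target >= 1))
  if (content == "mask" && !all(plane %in% c(0, 1))) {
    stop("mask input must be binary", call. = FALSE)
  }
  if (identical(dim(plane), as.integer(target))) return(plane)
  filt <- if (content == "image") "bilinear" else "none"
  out <- EBImage::resize(plane, w = target[1], h = target[2], filter = filt)
  matrix(as.numeric(out), target[1], target[2])
}

#' Centre-crop a plane or slice stack
#'
#' The crop window is centred; when a margin is odd, the window starts at
#' `floor(margin / 2)` so the extra dropped pixel comes from the
#' high-index side.
#'
#' @param plane `(y, x)` matrix or `(y, x, c)` array.
#' @param crop Integer pair `(y, x)`, each no larger than the source.
#' @return Cropped array of plane dimensions `crop`.
#' @examples
#' dim(center_crop(matrix(0, 240, 240), c(176, 144)))
#' @export
center_crop <- function(plane, crop) {
  d <- dim(plane)
  stopifnot(length(crop) == 2)
  if (crop[1] > d[1] || crop[2] > d[2]) {
    stop("crop larger than source plane", call. = FALSE)
  }
  oy <- (d[1] - crop[1]) %/% 2
  ox <- (d[2] - crop[2]) %/% 2
  ry <- oy + seq_len(crop[1])
  rx <- ox + seq_len(crop[2])
  if (length(d) == 2) plane[ry, rx, drop = FALSE]
  else plane[ry, rx, , drop = FALSE]
}

#' Collapse a multi-class label map to a binary mask
#'
#' @param labelmap Integer-valued array of class labels.
#' @param classes Non-empty set of positive labels mapped to 1; everything
#'   else (including labels absent from `classes`) maps to 0.
#' @return Binary array of the same shape.
#' @examples
#' merge_classes_binary(matrix(0:3, 2), classes = 1:3)
#' @export
merge_classes_binary <- function(labelmap, classes) {
  if (length(classes) == 0) stop("classes must be non-empty", call. = FALSE)
  if (any(classes == 0)) stop("0 is background and cannot be merged",
                              call. = FALSE)
  out <- (labelmap %in% classes) * 1
  dim(out) <- dim(labelmap)
  out
}

#' Randomly split volume ids into train/validation/test sets
#'
#' Splitting is by volume (never by slice) to prevent subject leakage.
#' Group sizes are `floor(n * frac)` for validation and test, with the
#' remainder assigned to training.
#'
#' @param ids Unique character vector (length >= 3).
#' @param fracs Train/validation/test fractions summing to 1.
#' @param seed Integer seed for the permutation.
#' @return A [dataset_split()].
#' @examples
#' lengths(split_dataset(sprintf("v%02d", 1:100), seed = 1))
#' @export
split_dataset <- function(ids, fracs = c(0.70, 0.15, 0.15), seed = 1L) {
  if (anyDuplicated(ids)) stop("ids must be unique", call. = FALSE)
  n <- length(ids)
  if (n < 3) stop("need at least 3 ids", call. = FALSE)
  if (length(fracs) != 3 || abs(sum(fracs) - 1) > 1e-9) {
    stop("fracs must be three fractions summing to 1", call. = FALSE)
  }
  perm <- with_local_seed(seed, sample(ids))
  n_val <- floor(n * fracs[2])
  n_test <- floor(n * fracs[3])
  n_train <- n - n_val - n_test
  dataset_split(train_ids = perm[seq_len(n_train)],
                val_ids = perm[n_train + seq_len(n_val)],
                test_ids = perm[n_train + n_val + seq_len(n_test)])
}
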
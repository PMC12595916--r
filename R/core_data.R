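#' @useDynLib sliceprop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Axis convention used throughout: volumes are (z, y, x, c) arrays, masks are
# (z, y, x). Slice indices are ZERO-based, matching the central-slice formula
# floor(z / 2); R subscripts add 1 at the point of access.

#' Create a volume record
#'
#' A volume record bundles one subject's image volume, its voxel spacing and
#' (optionally) the full ground-truth mask stack. The ground truth is carried
#' only so the sparse-annotation regime can be simulated (the training code
#' reads the central slice alone) and so held-out volumes can be scored.
#'
#' @param id Character scalar identifying the subject.
#' @param image Numeric array of shape `(z, y, x, c)`; a `(z, y, x)` array is
#'   promoted to a single channel.
#' @param spacing Positive numeric triple `(sz, sy, sx)` in millimetres.
#' @param gt_masks Optional binary `(z, y, x)` array of ground-truth masks.
#' @return An object of class `volume_record` with fields `id`, `image`,
#'   `spacing`, `depth` and `gt_masks`.
#' @examples
#' img <- array(rnorm(4 * 8 * 8), c(4, 8, 8, 1))
#' rec <- volume_record("v1", img, spacing = c(2, 1, 1))
#' rec$depth
#' @export
volume_record <- function(id, image, spacing = c(1, 1, 1), gt_masks = NULL) {
  stopifnot(is.character(id), length(id) == 1L)
  if (length(dim(image)) == 3L) {
    image <- array(image, c(dim(image), 1L))
  }
  if (length(dim(image)) != 4L) {
    stop("image must be a (z, y, x, c) or (z, y, x) array", call. = FALSE)
  }
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be three positive finite values (sz, sy, sx)",
         call. = FALSE)
  }
  if (!is.null(gt_masks)) {
    if (!identical(dim(gt_masks)[1:3], dim(image)[1:3])) {
      stop("gt_masks must share (z, y, x) dimensions with image",
           call. = FALSE)
    }
    if (!all(gt_masks %in% c(0, 1))) {
      stop("gt_masks must be binary", call. = FALSE)
    }
    storage.mode(gt_masks) <- "double"
  }
  structure(
    list(id = id, image = image, spacing = as.numeric(spacing),
         depth = dim(image)[1L], gt_masks = gt_masks),
    class = "volume_record"
  )
}

#' @export
print.volume_record <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<volume_record '%s': %d x %d x %d, %d channel(s), spacing %s mm, gt %s>\n",
              x$id, d[1], d[2], d[3], d[4],
              paste(signif(x$spacing, 3), collapse = "x"),
              if (is.null(x$gt_masks)) "absent" else "present"))
  invisible(x)
}

#' Central slice index of a volume
#'
#' The single annotated slice per training volume sits at the zero-based
#' index `floor(z / 2)`.
#'
#' @param z Positive integer number of slices.
#' @return Zero-based integer index in `[0, z - 1]`.
#' @examples
#' central_slice_index(24)  # 12
#' @export
central_slice_index <- function(z) {
  if (!is.numeric(z) || length(z) != 1L || is.na(z) || z < 1 ||
      z != floor(z)) {
    stop("z must be a positive integer", call. = FALSE)
  }
  as.integer(floor(z / 2))
}

#' Normalised slice index (NSI)
#'
#' Rescales a zero-based slice position to `[0, 1]`: 0 for the first slice,
#' 1 for the last, with the central annotated slice at (approximately) 0.5.
#' Single-slice volumes return 0.5 by convention.
#'
#' @param index Zero-based slice index.
#' @param z Volume depth (number of slices).
#' @return Numeric in `[0, 1]`.
#' @examples
#' nsi(0, 47)   # 0
#' nsi(46, 47)  # 1
#' @export
nsi <- function(index, z) {
  if (!is.numeric(z) || length(z) != 1L || z < 1 || z != floor(z)) {
    stop("z must be a positive integer", call. = FALSE)
  }
  if (any(index < 0) || any(index > z - 1) || any(index != floor(index))) {
    stop("index must be an integer in [0, z - 1]", call. = FALSE)
  }
  if (z == 1L) return(rep(0.5, length(index)))
  index / (z - 1)
}

#' Create a slice label
#'
#' One labelled 2D plane of a volume: the mask plus its provenance
#' (`ground_truth` for the annotated central slice, `pseudo` for a
#' confidence-filtered model prediction, `background_fill` for a predicted
#' slice whose pixels all fell below the confidence threshold) and the loss
#' weight it will carry during fine-tuning.
#'
#' @param volume_id Volume the slice belongs to.
#' @param index Zero-based slice position.
#' @param mask Binary `(y, x)` matrix.
#' @param source One of `"ground_truth"`, `"pseudo"`, `"background_fill"`.
#' @param weight Non-negative loss weight (default 1).
#' @return An object of class `slice_label`.
#' @export
slice_label <- function(volume_id, index, mask,
                        source = c("ground_truth", "pseudo",
                                   "background_fill"),
                        weight = 1) {
  source <- match.arg(source)
  stopifnot(is.matrix(mask))
  if (!all(mask %in% c(0, 1))) {
    stop("mask must be binary", call. = FALSE)
  }
  if (index < 0 || index != floor(index)) {
    stop("index must be a non-negative integer", call. = FALSE)
  }
  if (weight < 0) stop("weight must be >= 0", call. = FALSE)
  storage.mode(mask) <- "double"
  structure(
    list(volume_id = volume_id, index = as.integer(index), mask = mask,
         source = source, weight = as.numeric(weight)),
    class = "slice_label"
  )
}

#' Create a label state for one volume
#'
#' Tracks the labelled region of a volume during propagation. In the default
#' `"interval"` mode the labelled region is the contiguous slice interval
#' `[lo, hi]` grown symmetrically from the central slice; the `"set"` mode
#' (used by the random-expansion ablation) allows arbitrary slice sets.
#'
#' @param central_label A `slice_label` with `source = "ground_truth"` at the
#'   volume's central slice index.
#' @param depth Volume depth.
#' @param mode `"interval"` (default) or `"set"`.
#' @return An object of class `label_state`.
#' @export
label_state <- function(central_label, depth, mode = c("interval", "set")) {
  mode <- match.arg(mode)
  stopifnot(inherits(central_label, "slice_label"))
  if (central_label$source != "ground_truth") {
    stop("the seed label must have source 'ground_truth'", call. = FALSE)
  }
  ci <- central_slice_index(depth)
  if (central_label$index != ci) {
    stop(sprintf("seed label at index %d, but central slice of depth %d is %d",
                 central_label$index, depth, ci), call. = FALSE)
  }
  labels <- list()
  labels[[as.character(ci)]] <- central_label
  structure(
    list(volume_id = central_label$volume_id, depth = as.integer(depth),
         lo = ci, hi = ci, labels = labels, mode = mode),
    class = "label_state"
  )
}

#' Number of labelled slices in a state
#' @param state A `label_state`.
#' @return Integer count.
#' @export
coverage <- function(state) {
  stopifnot(inherits(state, "label_state"))
  length(state$labels)
}

#' Is every slice of the volume labelled?
#' @param state A `label_state`.
#' @return Logical scalar.
#' @export
is_complete <- function(state) {
  stopifnot(inherits(state, "label_state"))
  if (state$mode == "interval") {
    state$lo == 0L && state$hi == state$depth - 1L
  } else {
    length(state$labels) == state$depth
  }
}

#' Extend the labelled region with newly labelled slices
#'
#' Adds one `slice_label` per new index. In interval mode the new indices
#' must be the immediate neighbours of the current interval, so the labelled
#' region stays contiguous; existing labels are never overwritten
#' (pseudo-labels are write-once).
#'
#' @param state A `label_state`.
#' @param new_labels List of `slice_label` objects for previously unlabelled
#'   slices.
#' @return The updated `label_state`.
#' @export
advance_interval <- function(state, new_labels) {
  stopifnot(inherits(state, "label_state"))
  if (length(new_labels) == 0L) return(state)
  idx <- vapply(new_labels, function(l) l$index, integer(1))
  if (anyDuplicated(idx)) {
    stop("duplicate slice indices in new_labels", call. = FALSE)
  }
  if (any(idx < 0 | idx > state$depth - 1L)) {
    stop("slice index outside [0, depth - 1]", call. = FALSE)
  }
  if (any(as.character(idx) %in% names(state$labels))) {
    stop("slice already labelled; labels are write-once", call. = FALSE)
  }
  if (state$mode == "interval") {
    lo <- state$lo; hi <- state$hi
    below <- sort(idx[idx < lo], decreasing = TRUE)
    above <- sort(idx[idx > hi])
    if (length(below) + length(above) != length(idx)) {
      stop("new indices must lie outside the current interval", call. = FALSE)
    }
    if ((length(below) && !identical(below, seq(lo - 1L, by = -1L,
                                                length.out = length(below)))) ||
        (length(above) && !identical(above, seq(hi + 1L, by = 1L,
                                                length.out = length(above))))) {
      stop("new indices must extend the interval contiguously", call. = FALSE)
    }
    state$lo <- min(lo, idx)
    state$hi <- max(hi, idx)
  }
  for (l in new_labels) {
    state$labels[[as.character(l$index)]] <- l
  }
  state
}

#' Extract one slice of a volume's image
#' @param record A `volume_record`.
#' @param index Zero-based slice index.
#' @return `(y, x, c)` array.
#' @export
get_slice <- function(record, index) {
  stopifnot(inherits(record, "volume_record"))
  if (index < 0 || index > record$depth - 1L) {
    stop("slice index out of range", call. = FALSE)
  }
  array(record$image[index + 1L, , , , drop = FALSE],
        dim(record$image)[2:4])
}

#' Ground-truth mask of the central slice
#'
#' The only piece of ground truth the training pathway may read: it is how
#' the single-annotated-slice regime is simulated from fully annotated data.
#'
#' @param record A `volume_record` carrying `gt_masks`.
#' @return Binary `(y, x)` matrix.
#' @export
gt_central_slice <- function(record) {
  stopifnot(inherits(record, "volume_record"))
  if (is.null(record$gt_masks)) {
    stop("volume has no ground-truth masks", call. = FALSE)
  }
  ci <- central_slice_index(record$depth)
  record$gt_masks[ci + 1L, , ]
}

#' Full ground-truth stack (evaluation only)
#'
#' Reading the full stack is gated behind `benchmark = TRUE` so the training
#' pathway cannot silently consume annotations the sparse regime withholds.
#'
#' @param record A `volume_record`.
#' @param benchmark Must be `TRUE` to obtain the stack.
#' @return Binary `(z, y, x)` array.
#' @export
gt_full <- function(record, benchmark = FALSE) {
  stopifnot(inherits(record, "volume_record"))
  if (!isTRUE(benchmark)) {
    stop(paste("full ground truth is reserved for benchmarking/evaluation;",
               "pass benchmark = TRUE from an evaluation context"),
         call. = FALSE)
  }
  if (is.null(record$gt_masks)) {
    stop("volume has no ground-truth masks", call. = FALSE)
  }
  record$gt_masks
}

#' Create a dataset split
#'
#' @param train_ids,val_ids,test_ids Disjoint character vectors of volume ids.
#' @return An object of class `dataset_split`.
#' @export
dataset_split <- function(train_ids, val_ids, test_ids) {
  all <- c(train_ids, val_ids, test_ids)
  if (anyDuplicated(all)) {
    stop("split groups must be disjoint", call. = FALSE)
  }
  structure(list(train_ids = train_ids, val_ids = val_ids,
                 test_ids = test_ids),
            class = "dataset_split")
}
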
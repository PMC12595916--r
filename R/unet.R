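# Reduced-capacity U-Net builders. The 2D network is the workhorse (it is
# what gets trained); the 3D builder constructs the analogous volumetric
# architecture for capacity accounting and weight allocation.

#' Specify a segmentation network
#'
#' The architecture follows the classic U-Net encoder-decoder with skip
#' connections, reduced to 8 filters in the first layer, doubling at each of
#' the four downsampling steps to 128 in the bottleneck. Each resolution
#' level applies two 3x3 (3x3x3 in 3D) convolutions with biases and no
#' normalisation layers; downsampling is 2x max pooling; upsampling is a 2x2
#' (2x2x2) transposed convolution followed by skip concatenation; a final
#' 1x1 (1x1x1) convolution with a logistic unit emits per-pixel foreground
#' probabilities.
#'
#' @param dimensionality 2 (slice-wise network) or 3 (volumetric variant).
#' @param in_channels Number of image channels (1 for single-modality data,
#'   4 for multi-parametric MRI).
#' @param base_filters Filters in the first layer (default 8).
#' @param levels Number of downsampling steps (default 4).
#' @param max_filters Bottleneck width (default 128).
#' @param out_channels Output maps; 1 for binary segmentation.
#' @return An object of class `model_spec`.
#' @examples
#' model_spec(2, in_channels = 4)
#' @export
model_spec <- function(dimensionality = 2, in_channels = 1,
                       base_filters = 8, levels = 4, max_filters = 128,
                       out_channels = 1) {
  if (!dimensionality %in% c(2, 3)) {
    stop("dimensionality must be 2 or 3", call. = FALSE)
  }
  if (in_channels < 1 || base_filters < 1 || levels < 1) {
    stop("in_channels, base_filters and levels must be >= 1", call. = FALSE)
  }
  if (out_channels != 1) {
    stop("only single-map (binary) output is supported", call. = FALSE)
  }
  if (base_filters * 2^levels != max_filters) {
    stop("base_filters * 2^levels must equal max_filters", call. = FALSE)
  }
  structure(
    list(dimensionality = as.integer(dimensionality),
         in_channels = as.integer(in_channels),
         base_filters = as.integer(base_filters),
         levels = as.integer(levels),
         max_filters = as.integer(max_filters),
         out_channels = as.integer(out_channels)),
    class = "model_spec"
  )
}

#' Build a segmentation network from a spec
#'
#' For `dimensionality = 2` this returns a trainable predictor backed by the
#' package's native implementation (forward pass, backpropagation and
#' RMSprop updates). For `dimensionality = 3` it returns the volumetric
#' skeleton: all weight tensors are allocated and initialised, and
#' parameters can be counted and serialised, but no training loop is
#' provided (the slice-wise network is the method's vehicle).
#'
#' @param spec A `model_spec`.
#' @param seed Integer seed for weight initialisation (fan-scaled uniform).
#' @return A `unet2d` or `unet3d` object.
#' @examples
#' net <- build_segmentation_network(model_spec(2, in_channels = 1), seed = 1)
#' count_trainable_parameters(net)
#' @export
build_segmentation_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$dimensionality == 2L) {
    ptr <- .unet2d_create(spec$in_channels, spec$base_filters, spec$levels,
                          spec$max_filters, as.integer(seed))
    structure(list(ptr = ptr, spec = spec, seed = as.integer(seed)),
              class = "unet2d")
  } else {
    build_unet3d(spec, seed)
  }
}

layer_filters <- function(spec, level) {
  min(spec$base_filters * 2^level, spec$max_filters)
}

# Layer-by-layer inventory of the architecture with per-layer parameter
# counts; shared by the 2D and 3D builders (kernel volume differs).
unet_layer_table <- function(spec) {
  kvol <- if (spec$dimensionality == 2L) 9L else 27L
  upvol <- if (spec$dimensionality == 2L) 4L else 8L
  rows <- list()
  add <- function(name, cin, cout, kv) {
    rows[[length(rows) + 1L]] <<- data.frame(
      layer = name, cin = cin, cout = cout,
      weights = kv * cin * cout, biases = cout)
  }
  cin <- spec$in_channels
  for (l in seq_len(spec$levels) - 1L) {
    f <- layer_filters(spec, l)
    add(sprintf("enc%d_conv1", l), cin, f, kvol)
    add(sprintf("enc%d_conv2", l), f, f, kvol)
    cin <- f
  }
  fb <- layer_filters(spec, spec$levels)
  add("bottleneck_conv1", cin, fb, kvol)
  add("bottleneck_conv2", fb, fb, kvol)
  cin <- fb
  for (l in rev(seq_len(spec$levels) - 1L)) {
    f <- layer_filters(spec, l)
    add(sprintf("dec%d_upconv", l), cin, f, upvol)
    add(sprintf("dec%d_conv1", l), 2L * f, f, kvol)
    add(sprintf("dec%d_conv2", l), f, f, kvol)
    cin <- f
  }
  add("output_conv", cin, spec$out_channels, 1L)
  out <- do.call(rbind, rows)
  out$total <- out$weights + out$biases
  out
}

build_unet3d <- function(spec, seed) {
  tab <- unet_layer_table(spec)
  set.seed(as.integer(seed))
  weights <- lapply(seq_len(nrow(tab)), function(i) {
    nw <- tab$weights[i]
    lim <- sqrt(6 / (tab$weights[i] / tab$cout[i] + tab$weights[i] / tab$cin[i]))
    list(W = array(stats::runif(nw, -lim, lim),
                   c(tab$weights[i] / (tab$cin[i] * tab$cout[i]),
                     tab$cin[i], tab$cout[i])),
         b = numeric(tab$biases[i]))
  })
  names(weights) <- tab$layer
  structure(list(spec = spec, layers = tab, weights = weights,
                 seed = as.integer(seed)),
            class = "unet3d")
}

#' Count trainable parameters of a network
#'
#' Sums every trainable weight and bias element.
#'
#' @param model A network built by [build_segmentation_network()].
#' @return Integer-valued numeric count.
#' @examples
#' count_trainable_parameters(
#'   build_segmentation_network(model_spec(2, in_channels = 4)))
#' @export
count_trainable_parameters <- function(model) {
  UseMethod("count_trainable_parameters")
}

#' @export
count_trainable_parameters.unet2d <- function(model) {
  .unet2d_n_params(model$ptr)
}

#' @export
count_trainable_parameters.unet3d <- function(model) {
  sum(model$layers$total)
}

#' @export
print.unet2d <- function(x, ...) {
  cat(sprintf("<2D U-Net: %d channel(s) in, %d->%d filters, %d levels, %s parameters>\n",
              x$spec$in_channels, x$spec$base_filters, x$spec$max_filters,
              x$spec$levels,
              format(count_trainable_parameters(x), big.mark = ",")))
  invisible(x)
}

#' @export
print.unet3d <- function(x, ...) {
  cat(sprintf("<3D U-Net skeleton: %d channel(s) in, %d->%d filters, %s parameters>\n",
              x$spec$in_channels, x$spec$base_filters, x$spec$max_filters,
              format(count_trainable_parameters(x), big.mark = ",")))
  invisible(x)
}

# Reflect-pad a (y, x, c) slice so both plane dimensions are divisible by
# 2^levels; returns the padded array plus the original dims.
pad_to_multiple <- function(x, multiple) {
  d <- dim(x)
  ty <- ceiling(d[1] / multiple) * multiple
  tx <- ceiling(d[2] / multiple) * multiple
  if (ty == d[1] && tx == d[2]) {
    return(list(x = x, dims = d[1:2], pad = c(0L, 0L)))
  }
  reflect_idx <- function(n, target) {
    extra <- target - n
    lo <- extra %/% 2
    hi <- extra - lo
    # reflect without repeating the edge sample
    idx <- c(rev(seq_len(lo) + 1L), seq_len(n), n - seq_len(hi))
    pmin(pmax(idx, 1L), n)
  }
  iy <- reflect_idx(d[1], ty)
  ix <- reflect_idx(d[2], tx)
  list(x = x[iy, ix, , drop = FALSE], dims = d[1:2],
       pad = c(which(iy == 1L)[1] - 1L, which(ix == 1L)[1] - 1L))
}

#' Predict per-pixel foreground probabilities
#'
#' Runs the 2D network on one or more `(y, x, c)` slices. Plane dimensions
#' not divisible by `2^levels` are reflect-padded for the forward pass and
#' cropped back afterwards, so the network accepts arbitrary geometry.
#'
#' @param model A `unet2d` predictor.
#' @param slices A single `(y, x, c)` array (or `(y, x)` matrix), or a list
#'   of them.
#' @return A `(y, x)` probability matrix, or a list of them (values strictly
#'   inside (0, 1)).
#' @export
predict_proba <- function(model, slices) {
  stopifnot(inherits(model, "unet2d"))
  single <- !is.list(slices)
  if (single) slices <- list(slices)
  mult <- 2^model$spec$levels
  prepped <- lapply(slices, function(s) {
    if (is.matrix(s)) s <- array(s, c(dim(s), 1L))
    pad_to_multiple(s, mult)
  })
  probs <- .unet2d_predict(model$ptr, lapply(prepped, `[[`, "x"))
  out <- mapply(function(p, pr) {
    p[pr$pad[1] + seq_len(pr$dims[1]), pr$pad[2] + seq_len(pr$dims[2]),
      drop = FALSE]
  }, probs, prepped, SIMPLIFY = FALSE)
  if (single) out[[1]] else out
}

#' Extract the network weights as plain R vectors
#' @param model A `unet2d` predictor.
#' @return List of numeric vectors (layer order is fixed).
#' @export
get_weights <- function(model) {
  stopifnot(inherits(model, "unet2d"))
  .unet2d_get_weights(model$ptr)
}

#' Load weights previously extracted with [get_weights()]
#' @param model A `unet2d` predictor (architecture must match).
#' @param weights List of numeric vectors.
#' @return The model, invisibly (weights are set in place).
#' @export
set_weights <- function(model, weights) {
  stopifnot(inherits(model, "unet2d"))
  .unet2d_set_weights(model$ptr, weights)
  invisible(model)
}

#' Save network weights and spec to disk
#'
#' Weights are written as a JSON file holding the flattened layer vectors
#' alongside the architecture spec, so a checkpoint is a portable text file.
#'
#' @param model A `unet2d` predictor.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "unet2d"))
  obj <- list(spec = unclass(model$spec), seed = model$seed,
              weights = get_weights(model))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#' @param path Checkpoint file.
#' @return A `unet2d` predictor with restored weights.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(model_spec, obj$spec)
  model <- build_segmentation_network(spec, seed = obj$seed)
  set_weights(model, as.list(obj$weights))
  model
}

#' Deep-copy a 2D network (weights and architecture)
#'
#' Predictors hold external state, so ordinary assignment aliases the same
#' network; `clone_model()` creates an independent copy.
#'
#' @param model A `unet2d` predictor.
#' @return A new `unet2d` with identical weights.
#' @export
clone_model <- function(model) {
  stopifnot(inherits(model, "unet2d"))
  out <- build_segmentation_network(model$spec, seed = model$seed)
  set_weights(out, get_weights(model))
  out
}
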
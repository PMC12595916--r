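# The incremental self-labelling loop: symmetric slice selection around
# the labelled interval, confidence-filtered pseudo-label creation,
# NSI-based loss weighting, cumulative fine-tuning and termination once
# every volume is fully pseudo-labelled. A random-expansion mode replaces
# the symmetric neighbour selection for ablation.

#' Loss-weighting scheme over normalised slice index
#'
#' Pseudo-labels far from the annotated central slice are expected to be
#' less reliable; these schemes optionally down-weight them as a function
#' of `|NSI - 0.5|`. The uniform scheme (weight 1 everywhere) is the
#' default operating mode; the Gaussian and stepwise shapes are provided
#' for sensitivity analysis. All schemes give weight 1 at the central
#' slice.
#'
#' @param kind `"uniform"`, `"gaussian"` or `"stepwise"`.
#' @param sigma Gaussian width on the NSI scale.
#' @param breakpoints For `"stepwise"`: a list of `c(bound, weight)` pairs;
#'   a slice takes the weight of the first breakpoint whose bound is >=
#'   its `|NSI - 0.5|`.
#' @return An object of class `weight_scheme`.
#' @examples
#' slice_weight(0.3, weight_scheme("gaussian", sigma = 0.2))
#' @export
weight_scheme <- function(kind = c("uniform", "gaussian", "stepwise"),
                          sigma = 0.2,
                          breakpoints = list(c(0.15, 1.0), c(0.35, 0.6),
                                             c(0.5, 0.3))) {
  kind <- match.arg(kind)
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  wts <- vapply(breakpoints, `[`, numeric(1), 2)
  if (any(wts <= 0 | wts > 1)) {
    stop("stepwise weights must lie in (0, 1]", call. = FALSE)
  }
  structure(list(kind = kind, sigma = sigma, breakpoints = breakpoints),
            class = "weight_scheme")
}

#' Slice loss weight under a weighting scheme
#'
#' @param nsi_value Normalised slice index in `[0, 1]`.
#' @param scheme A [weight_scheme()].
#' @return Weight in `(0, 1]`; 1 at `nsi_value = 0.5` for every scheme.
#' @export
slice_weight <- function(nsi_value, scheme) {
  stopifnot(inherits(scheme, "weight_scheme"))
  if (any(nsi_value < 0 | nsi_value > 1)) {
    stop("nsi_value must lie in [0, 1]", call. = FALSE)
  }
  d <- abs(nsi_value - 0.5)
  switch(scheme$kind,
    uniform = rep(1, length(nsi_value)),
    gaussian = exp(-d^2 / (2 * scheme$sigma^2)),
    stepwise = vapply(d, function(di) {
      for (bp in scheme$breakpoints) if (di <= bp[1]) return(bp[2])
      scheme$breakpoints[[length(scheme$breakpoints)]][2]
    }, numeric(1))
  )
}

#' Self-labelling configuration
#'
#' @param theta Confidence threshold in `[0.5, 1)` above which a predicted
#'   pixel becomes pseudo-label foreground. Default 0.7, the midpoint of
#'   the empirically optimal 0.6-0.8 band.
#' @param k Fraction of each volume's depth pseudo-labelled per iteration
#'   (split symmetrically above and below the labelled region); default
#'   0.05.
#' @param scheme A [weight_scheme()] for pseudo-label loss weights.
#' @param expansion `"adjacent"` (incremental outward propagation) or
#'   `"random"` (ablation: same per-iteration count, slices drawn uniformly
#'   from all unlabelled positions).
#' @param seed Integer seed (drives the random-expansion draws).
#' @param train A [train_config()] for the per-iteration fine-tuning.
#' @return An object of class `selflabel_config`.
#' @export
selflabel_config <- function(theta = 0.7, k = 0.05,
                             scheme = weight_scheme("uniform"),
                             expansion = c("adjacent", "random"),
                             seed = 1L, train = train_config()) {
  if (theta < 0.5 || theta >= 1) {
    stop("theta must lie in [0.5, 1)", call. = FALSE)
  }
  if (k <= 0 || k > 1) stop("k must lie in (0, 1]", call. = FALSE)
  structure(
    list(theta = theta, k = k, scheme = scheme,
         expansion = match.arg(expansion), seed = as.integer(seed),
         train = train),
    class = "selflabel_config"
  )
}

#' Select the next slices to pseudo-label adjacent to the labelled region
#'
#' The per-side budget is `s = max(1, round(k * depth / 2))` (round half
#' up; at least one slice per iteration so propagation always progresses).
#' Up to `s` slices immediately below `lo` and `s` immediately above `hi`
#' are selected; when one side reaches the volume boundary its unused
#' budget transfers to the other side.
#'
#' @param state A `label_state` in interval mode.
#' @param depth Volume depth.
#' @param k Expansion fraction per iteration.
#' @return Sorted integer vector of slice indices (empty when complete).
#' @examples
#' st <- label_state(slice_label("v", 12, matrix(0, 4, 4), "ground_truth"),
#'                   depth = 24)
#' select_next_slices(st, 24, 0.05)  # 11 13
#' @export
select_next_slices <- function(state, depth, k) {
  stopifnot(inherits(state, "label_state"))
  if (is_complete(state)) return(integer(0))
  s <- max(1L, as.integer(floor(k * depth / 2 + 0.5)))
  avail_below <- state$lo
  avail_above <- depth - 1L - state$hi
  take_below <- min(avail_below, s + max(0L, s - avail_above))
  take_above <- min(avail_above, s + max(0L, s - avail_below))
  below <- if (take_below > 0) state$lo - seq_len(take_below) else integer(0)
  above <- if (take_above > 0) state$hi + seq_len(take_above) else integer(0)
  sort(c(below, above))
}

#' Select random unlabelled slices (ablation mode)
#'
#' Emits exactly as many slices per iteration as the adjacent mode would
#' for the same `(depth, k)`, but draws them uniformly without replacement
#' from all currently unlabelled indices.
#'
#' @param state A `label_state` in set mode.
#' @param depth Volume depth.
#' @param k Expansion fraction per iteration.
#' @param seed Integer seed for the draw.
#' @return Integer vector of slice indices.
#' @export
select_random_slices <- function(state, depth, k, seed) {
  stopifnot(inherits(state, "label_state"))
  if (is_complete(state)) return(integer(0))
  s <- max(1L, as.integer(floor(k * depth / 2 + 0.5)))
  unlab <- setdiff(0:(depth - 1L), as.integer(names(state$labels)))
  count <- min(2L * s, length(unlab))
  with_local_seed(seed, sort(unlab[sample.int(length(unlab), count)]))
}

#' Threshold predicted probabilities into a pseudo-label
#'
#' Pixels with probability `>= theta` become foreground. A slice whose
#' pixels all fall below the threshold is not skipped: it is emitted as an
#' all-background mask (source `"background_fill"`) and still joins the
#' training pool.
#'
#' @param probs `(y, x)` probability matrix in `[0, 1]`.
#' @param theta Confidence threshold in `[0.5, 1)`.
#' @return List with binary `mask` and `source` (`"pseudo"` or
#'   `"background_fill"`).
#' @examples
#' binarize_with_confidence(matrix(c(0.95, 0.4), 1), 0.7)
#' @export
binarize_with_confidence <- function(probs, theta) {
  if (theta < 0.5 || theta >= 1) {
    stop("theta must lie in [0.5, 1)", call. = FALSE)
  }
  if (any(probs < 0 | probs > 1)) {
    stop("probs must lie in [0, 1]", call. = FALSE)
  }
  mask <- (probs >= theta) * 1
  list(mask = mask,
       source = if (any(mask == 1)) "pseudo" else "background_fill")
}

# assemble the cumulative training pool from every volume's label state
states_to_pool <- function(volumes, states, scheme) {
  out <- list()
  for (v in volumes) {
    st <- states[[v$id]]
    for (lab in st$labels) {
      out[[length(out) + 1L]] <-
        make_pool_entry(v, lab$index, lab$mask, lab$source, lab$weight)
    }
  }
  out
}

#' Run the incremental self-labelling loop
#'
#' Starting from the initial model `f1` (trained on central slices only)
#' and one ground-truth central slice per training volume, each iteration:
#' selects the next slices for every incomplete volume (symmetrically
#' adjacent, or random in the ablation mode), predicts them with the
#' current model, thresholds the predictions into pseudo-labels (emitting
#' all-background fills rather than skipping low-confidence slices),
#' attaches NSI-based loss weights, and fine-tunes the model on the whole
#' cumulative pool — ground truth plus every pseudo-label created so far,
#' never augmented, warm-starting from the current weights. Volumes that
#' complete early are frozen but their slices stay in the pool. The loop
#' ends when every pseudo-label stack matches its volume's depth.
#'
#' @param train_volumes,val_volumes Lists of [volume_record()]; validation
#'   volumes contribute their annotated central slices as the validation
#'   pool.
#' @param f1 The initial `unet2d` model (left unmodified; training
#'   continues on an internal copy).
#' @param config A [selflabel_config()].
#' @return List with `model` (the final fine-tuned network), `stacks`
#'   (named list of full-depth `(z, y, x)` pseudo-label arrays, central
#'   slice kept as ground truth), `audit` (one row per generated slice:
#'   iteration, volume, index, NSI, source, confidence statistics, weight)
#'   and `n_iterations`.
#' @export
run_selflabel <- function(train_volumes, val_volumes, f1, config) {
  stopifnot(inherits(f1, "unet2d"), inherits(config, "selflabel_config"))
  mode <- if (config$expansion == "random") "set" else "interval"
  states <- list()
  for (v in train_volumes) {
    ci <- central_slice_index(v$depth)
    seed_label <- slice_label(v$id, ci, gt_central_slice(v), "ground_truth",
                              weight = 1)
    states[[v$id]] <- label_state(seed_label, v$depth, mode = mode)
  }
  val_pool <- central_gt_pool(val_volumes)
  model <- clone_model(f1)
  audit <- list()
  iter <- 0L
  while (!all(vapply(states, is_complete, logical(1)))) {
    iter <- iter + 1L
    if (iter > max(vapply(train_volumes, `[[`, numeric(1), "depth"))) {
      stop("self-labelling failed to terminate", call. = FALSE)
    }
    for (vi in seq_along(train_volumes)) {
      v <- train_volumes[[vi]]
      st <- states[[v$id]]
      if (is_complete(st)) next
      idx <- if (config$expansion == "random") {
        select_random_slices(st, v$depth, config$k,
                             seed = config$seed + 7919L * iter + vi)
      } else {
        select_next_slices(st, v$depth, config$k)
      }
      if (length(idx) == 0) next
      xs <- lapply(idx, function(i) standardise(get_slice(v, i)))
      probs <- predict_proba(model, xs)
      labels <- vector("list", length(idx))
      for (j in seq_along(idx)) {
        bin <- binarize_with_confidence(probs[[j]], config$theta)
        wgt <- slice_weight(nsi(idx[j], v$depth), config$scheme)
        labels[[j]] <- slice_label(v$id, idx[j], bin$mask, bin$source,
                                   weight = wgt)
        audit[[length(audit) + 1L]] <- data.frame(
          iteration = iter, volume_id = v$id, index = idx[j],
          nsi = nsi(idx[j], v$depth), source = bin$source,
          mean_conf = mean(probs[[j]]), max_conf = max(probs[[j]]),
          fg_pixels = sum(bin$mask), weight = wgt)
      }
      states[[v$id]] <- advance_interval(st, labels)
    }
    pool <- states_to_pool(train_volumes, states, config$scheme)
    cfg <- config$train
    cfg$seed <- config$train$seed + 104729L * iter
    fit(model, pool, val_pool, cfg, policy = NULL)   # never augmented
  }
  stacks <- lapply(train_volumes, function(v) {
    st <- states[[v$id]]
    arr <- array(0, c(v$depth, dim(v$image)[2], dim(v$image)[3]))
    for (lab in st$labels) arr[lab$index + 1L, , ] <- lab$mask
    arr
  })
  names(stacks) <- vapply(train_volumes, `[[`, character(1), "id")
  list(model = model, stacks = stacks, audit = do.call(rbind, audit),
       n_iterations = iter)
}
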
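# Training machinery: weighted binary cross-entropy, geometric
# augmentation, slice pooling, the fit loop (RMSprop with
# reduce-on-plateau and early stopping), and 5-fold cross-validated
# initialisation on the central ground-truth slices.

#' Training configuration
#'
#' Defaults follow the reference protocol: up to 150 epochs of RMSprop at
#' an initial learning rate of 1e-3, learning rate multiplied by 0.1 when
#' the validation loss plateaus, early stopping after 6 epochs without
#' validation improvement, and restoration of the best-validation-loss
#' weights. The plateau patience (3 epochs) and the improvement threshold
#' (absolute decrease > 1e-4) are implementation choices kept strictly
#' below the early-stop patience so the schedule can fire.
#'
#' @param max_epochs Maximum training epochs.
#' @param initial_lr Initial learning rate.
#' @param lr_factor Multiplier applied to the learning rate on plateau.
#' @param lr_patience Epochs without improvement before the learning rate
#'   is reduced.
#' @param early_stop_patience Epochs without improvement before training
#'   halts.
#' @param min_delta Minimal absolute validation-loss decrease counted as an
#'   improvement.
#' @param batch_size Mini-batch size.
#' @param seed Integer seed for shuffling and augmentation draws.
#' @return An object of class `train_config`.
#' @export
train_config <- function(max_epochs = 150, initial_lr = 1e-3,
                         lr_factor = 0.1, lr_patience = 3,
                         early_stop_patience = 6, min_delta = 1e-4,
                         batch_size = 16, seed = 1L) {
  if (lr_factor <= 0 || lr_factor >= 1) {
    stop("lr_factor must be in (0, 1)", call. = FALSE)
  }
  if (early_stop_patience < 1 || lr_patience < 1) {
    stop("patience values must be >= 1", call. = FALSE)
  }
  structure(
    list(max_epochs = as.integer(max_epochs), initial_lr = initial_lr,
         lr_factor = lr_factor, lr_patience = as.integer(lr_patience),
         early_stop_patience = as.integer(early_stop_patience),
         min_delta = min_delta, batch_size = as.integer(batch_size),
         seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Augmentation policy
#'
#' Horizontal/vertical flips and random rotations up to a bound, applied
#' only during the initial training on ground-truth central slices
#' (`enabled_for = "gt_initial_only"`, the default): augmenting noisy
#' pseudo-labels during fine-tuning degrades performance, so the
#' fine-tuning path never augments.
#'
#' @param hflip,vflip Enable random horizontal/vertical flips.
#' @param max_rotation_deg Rotation angles are drawn uniformly from
#'   `[-max_rotation_deg, max_rotation_deg]`.
#' @param enabled_for One of `"gt_initial_only"`, `"all"`, `"none"`.
#' @return An object of class `augmentation_policy`.
#' @export
augmentation_policy <- function(hflip = TRUE, vflip = TRUE,
                                max_rotation_deg = 90,
                                enabled_for = c("gt_initial_only", "all",
                                                "none")) {
  if (max_rotation_deg < 0) stop("rotation bound must be >= 0",
                                 call. = FALSE)
  structure(
    list(hflip = hflip, vflip = vflip,
         max_rotation_deg = max_rotation_deg,
         enabled_for = match.arg(enabled_for)),
    class = "augmentation_policy"
  )
}

#' Weighted binary cross-entropy
#'
#' The weight-normalised mean of the per-pixel cross-entropy
#' `-[y log p + (1 - y) log(1 - p)]`, with probabilities clipped to
#' `[1e-7, 1 - 1e-7]`. With all weights equal to 1 this is exactly the
#' plain per-pixel average.
#'
#' @param probs Predicted probabilities in `[0, 1]`.
#' @param targets Binary targets, same shape.
#' @param weights Per-pixel non-negative weights (recycled scalars allowed).
#' @return Scalar loss.
#' @examples
#' bce_loss(0.5, 1)  # -log(0.5) = 0.6931
#' @export
bce_loss <- function(probs, targets, weights = 1) {
  if (length(probs) != length(targets)) {
    stop("probs and targets must have the same length", call. = FALSE)
  }
  w <- rep_len(weights, length(probs))
  if (any(w < 0)) stop("weights must be >= 0", call. = FALSE)
  if (sum(w) <= 0) stop("total weight must be > 0", call. = FALSE)
  p <- pmin(pmax(probs, 1e-7), 1 - 1e-7)
  ce <- -(targets * log(p) + (1 - targets) * log(1 - p))
  sum(w * ce) / sum(w)
}

# rotate a plane about its centre by angle_deg (counter-clockwise), sampling
# out-of-bounds coordinates by reflection
rotate_plane <- function(x, angle_deg, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  if (angle_deg == 0) return(x)
  th <- angle_deg * pi / 180
  H <- nrow(x); W <- ncol(x)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yy <- matrix(rep(seq_len(H), W), H)
  xx <- matrix(rep(seq_len(W), each = H), H)
  sy <- cy + cos(th) * (yy - cy) - sin(th) * (xx - cx)
  sx <- cx + sin(th) * (yy - cy) + cos(th) * (xx - cx)
  refl <- function(i, n) {
    if (n == 1) return(rep(1L, length(i)))
    j <- (i - 1) %% (2 * (n - 1))
    j <- pmin(j, 2 * (n - 1) - j)
    as.integer(j + 1)
  }
  if (interp == "nearest") {
    out <- x[cbind(refl(round(sy), H), refl(round(sx), W))]
  } else {
    y0 <- floor(sy); x0 <- floor(sx)
    fy <- sy - y0; fx <- sx - x0
    g <- function(iy, ix) x[cbind(refl(iy, H), refl(ix, W))]
    out <- (1 - fy) * (1 - fx) * g(y0, x0) + (1 - fy) * fx * g(y0, x0 + 1) +
      fy * (1 - fx) * g(y0 + 1, x0) + fy * fx * g(y0 + 1, x0 + 1)
  }
  matrix(out, H, W)
}

#' Apply one random geometric augmentation to an image/mask pair
#'
#' The identical transform (flips, then a rotation drawn uniformly in
#' `[-max, +max]` degrees about the slice centre with reflective borders)
#' is applied to both: the image with bilinear interpolation, the mask with
#' nearest-neighbour so it stays binary. Deterministic given `seed`.
#'
#' @param image `(y, x, c)` array (or `(y, x)` matrix).
#' @param mask Binary `(y, x)` matrix.
#' @param policy An [augmentation_policy()].
#' @param seed Integer seed.
#' @return List with transformed `image` and `mask`.
#' @export
augment <- function(image, mask, policy, seed) {
  stopifnot(inherits(policy, "augmentation_policy"))
  if (!all(mask %in% c(0, 1))) stop("mask must be binary", call. = FALSE)
  was_matrix <- is.matrix(image)
  if (was_matrix) image <- array(image, c(dim(image), 1L))
  with_local_seed(seed, {
    do_h <- policy$hflip && stats::runif(1) < 0.5
    do_v <- policy$vflip && stats::runif(1) < 0.5
    ang <- if (policy$max_rotation_deg > 0) {
      stats::runif(1, -policy$max_rotation_deg, policy$max_rotation_deg)
    } else 0
    flip <- function(m) {
      if (do_h) m <- m[, rev(seq_len(ncol(m)))]
      if (do_v) m <- m[rev(seq_len(nrow(m))), ]
      m
    }
    for (ch in seq_len(dim(image)[3])) {
      image[, , ch] <- rotate_plane(flip(image[, , ch]), ang, "bilinear")
    }
    mask <- rotate_plane(flip(mask), ang, "nearest")
  })
  if (was_matrix) image <- image[, , 1]
  list(image = image, mask = mask)
}

#' Partition a slice pool into one epoch of mini-batches
#'
#' A seeded random permutation of the pool is cut into consecutive batches,
#' so every slice appears exactly once per epoch and batches mix volumes
#' and slice positions.
#'
#' @param n_pool Number of slices in the pool.
#' @param batch_size Mini-batch size.
#' @param seed Integer seed.
#' @return List of integer index vectors.
#' @examples
#' lengths(pooled_batches(10, 4, seed = 1))  # 4 4 2
#' @export
pooled_batches <- function(n_pool, batch_size, seed) {
  if (n_pool < 1) stop("pool is empty", call. = FALSE)
  perm <- with_local_seed(seed, sample.int(n_pool))
  split(perm, ceiling(seq_along(perm) / batch_size))
}

# A pool entry bundles the standardised input slice with its training
# target; weight is the slice-level loss weight.
make_pool_entry <- function(record, index, mask, source, weight = 1) {
  x <- standardise(get_slice(record, index))
  list(x = x, y = mask, w = weight, volume_id = record$id,
       index = index, nsi = nsi(index, record$depth), source = source)
}

central_gt_pool <- function(volumes) {
  lapply(volumes, function(v) {
    make_pool_entry(v, central_slice_index(v$depth), gt_central_slice(v),
                    "ground_truth")
  })
}

#' Fit a 2D network on a pool of labelled slices
#'
#' Runs mini-batch RMSprop over the pooled slices with per-epoch
#' reshuffling. The validation loss drives a reduce-on-plateau learning
#' rate schedule and early stopping; the weights from the epoch with the
#' best validation loss are restored before returning. When an enabled
#' augmentation policy is supplied, each slice is augmented afresh every
#' epoch with a deterministic per-slice seed.
#'
#' @param model A `unet2d` predictor (modified in place).
#' @param train_pool,val_pool Non-empty lists of pool entries (see
#'   [init_with_crossval()] / [run_selflabel()] for how they are built).
#' @param config A [train_config()].
#' @param policy Optional [augmentation_policy()]; `NULL` disables
#'   augmentation (the fine-tuning path always passes `NULL`).
#' @return List with `model` (best-validation weights restored) and
#'   `history` (data frame of per-epoch train/validation loss and learning
#'   rate).
#' @export
fit <- function(model, train_pool, val_pool, config, policy = NULL) {
  stopifnot(inherits(model, "unet2d"), inherits(config, "train_config"))
  if (length(train_pool) == 0 || length(val_pool) == 0) {
    stop("training and validation pools must be non-empty", call. = FALSE)
  }
  augment_on <- !is.null(policy) && policy$enabled_for != "none"
  val_xs <- lapply(val_pool, `[[`, "x")
  val_ys <- lapply(val_pool, `[[`, "y")
  val_w <- vapply(val_pool, `[[`, numeric(1), "w")
  lr <- config$initial_lr
  best_val <- Inf
  best_weights <- NULL
  stall_stop <- 0L
  stall_lr <- 0L
  hist <- vector("list", config$max_epochs)
  for (epoch in seq_len(config$max_epochs)) {
    batches <- pooled_batches(length(train_pool), config$batch_size,
                              seed = config$seed + 1009L * epoch)
    ep_loss <- 0
    ep_n <- 0
    for (b in batches) {
      entries <- train_pool[b]
      if (augment_on) {
        entries <- lapply(seq_along(entries), function(j) {
          e <- entries[[j]]
          a <- augment(e$x, e$y, policy,
                       seed = config$seed + 7919L * epoch + b[j])
          e$x <- a$image; e$y <- a$mask
          e
        })
      }
      loss <- .unet2d_train_batch(
        model$ptr,
        lapply(entries, `[[`, "x"),
        lapply(entries, `[[`, "y"),
        vapply(entries, `[[`, numeric(1), "w"),
        lr)
      ep_loss <- ep_loss + loss * length(b)
      ep_n <- ep_n + length(b)
    }
    val_loss <- .unet2d_eval_batch(model$ptr, val_xs, val_ys, val_w)
    hist[[epoch]] <- data.frame(epoch = epoch,
                                train_loss = ep_loss / ep_n,
                                val_loss = val_loss, lr = lr)
    if (val_loss < best_val - config$min_delta) {
      best_val <- val_loss
      best_weights <- get_weights(model)
      stall_stop <- 0L
      stall_lr <- 0L
    } else {
      stall_stop <- stall_stop + 1L
      stall_lr <- stall_lr + 1L
      if (stall_lr >= config$lr_patience) {
        lr <- lr * config$lr_factor
        stall_lr <- 0L
      }
      if (stall_stop >= config$early_stop_patience) break
    }
  }
  if (!is.null(best_weights)) set_weights(model, best_weights)
  list(model = model, history = do.call(rbind, hist))
}

#' Initialise the model by 5-fold cross-validation on central slices
#'
#' Partitions the annotated central slices into `k_folds` seeded folds,
#' trains one network per fold (with augmentation, this being the only
#' stage where it is enabled), scores each fold model by Dice on its
#' held-out fold, and returns the fold winner as the starting model.
#'
#' @param central_pool List of pool entries, one annotated central slice
#'   per training volume.
#' @param spec A [model_spec()] for the networks.
#' @param config A [train_config()].
#' @param policy An [augmentation_policy()].
#' @param k_folds Number of folds (default 5).
#' @return List with `model` (the winning fold's network), `fold_dsc`
#'   (validation Dice per fold) and `histories`.
#' @export
init_with_crossval <- function(central_pool, spec, config,
                               policy = augmentation_policy(),
                               k_folds = 5) {
  n <- length(central_pool)
  if (n < k_folds) {
    stop(sprintf("need at least %d central slices for %d folds", k_folds,
                 k_folds), call. = FALSE)
  }
  perm <- with_local_seed(config$seed, sample.int(n))
  fold_of <- rep_len(seq_len(k_folds), n)[order(perm)]
  use_aug <- if (policy$enabled_for == "none") NULL else policy
  best <- NULL
  fold_dsc <- numeric(k_folds)
  histories <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    tr <- central_pool[fold_of != f]
    va <- central_pool[fold_of == f]
    net <- build_segmentation_network(spec, seed = config$seed + f)
    cfg <- config
    cfg$seed <- config$seed + 131L * f
    res <- fit(net, tr, va, cfg, policy = use_aug)
    histories[[f]] <- res$history
    preds <- predict_proba(res$model, lapply(va, `[[`, "x"))
    dscs <- vapply(seq_along(va), function(j) {
      dice_coefficient((preds[[j]] >= 0.5) * 1, va[[j]]$y)
    }, numeric(1))
    fold_dsc[f] <- mean(dscs, na.rm = TRUE)
    if (is.null(best) || fold_dsc[f] > best$dsc) {
      best <- list(model = res$model, dsc = fold_dsc[f], fold = f)
    }
  }
  list(model = best$model, best_fold = best$fold, fold_dsc = fold_dsc,
       histories = histories)
}
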
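# Synthetic 3D phantoms with the structural properties the propagation
# method relies on: a single contiguous, centrally concentrated foreground
# blob whose cross-section varies smoothly from slice to slice.

# run expr under a temporary RNG state so generators are deterministic
# without disturbing the caller's random stream
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Parameters for the 3D phantom generator
#'
#' A phantom is background Gaussian noise plus an intensity-offset
#' ellipsoidal blob. The blob's in-plane radius follows an ellipsoidal
#' profile along z (maximal at the central slice, shrinking to zero at the
#' extent ends), its centre performs a small bounded random walk from slice
#' to slice ("wobble"), and its through-plane extent always covers the
#' central slice. Ground-truth masks are exact.
#'
#' @param shape Integer triple `(z, y, x)`.
#' @param channels Number of image channels; geometry is shared across
#'   channels, noise is drawn independently (multi-parametric-MRI style
#'   redundancy).
#' @param fg_radius_range Min/max of the maximal in-plane radius, as
#'   fractions of `min(y, x) / 2`.
#' @param z_extent_range Min/max of the blob's z extent, as fractions of z.
#' @param intensity_offset Foreground minus background mean, in units of
#'   `noise_sd`.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param wobble Maximal per-slice drift of the blob centre, in voxels.
#' @param spacing Voxel spacing `(sz, sy, sx)` in mm recorded on the volume.
#' @param n_blobs Number of foreground blobs. The default single blob
#'   satisfies the structural assumptions the propagation method relies
#'   on; `n_blobs > 1` adds smaller satellite blobs at random positions
#'   (adversarial fixtures for limitation probes — the foreground may then
#'   be non-contiguous in z and absent from the central slice region).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return An object of class `phantom_params`.
#' @examples
#' phantom_params(shape = c(24, 32, 32))
#' @export
phantom_params <- function(shape = c(24, 32, 32), channels = 1,
                           fg_radius_range = c(0.3, 0.5),
                           z_extent_range = c(0.5, 0.9),
                           intensity_offset = 2.0, noise_sd = 1.0,
                           wobble = 0.5, spacing = c(1, 1, 1),
                           n_blobs = 1L, seed = 1L) {
  stopifnot(length(shape) == 3, all(shape >= 1), channels >= 1)
  rng_ok <- function(r) length(r) == 2 && r[1] > 0 && r[1] <= r[2] && r[2] <= 1
  if (!rng_ok(fg_radius_range) || !rng_ok(z_extent_range)) {
    stop("fg_radius_range and z_extent_range must satisfy 0 < min <= max <= 1",
         call. = FALSE)
  }
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (wobble < 0) stop("wobble must be >= 0", call. = FALSE)
  if (n_blobs < 1) stop("n_blobs must be >= 1", call. = FALSE)
  structure(
    list(shape = as.integer(shape), channels = as.integer(channels),
         fg_radius_range = fg_radius_range,
         z_extent_range = z_extent_range,
         intensity_offset = intensity_offset, noise_sd = noise_sd,
         wobble = wobble, spacing = as.numeric(spacing),
         n_blobs = as.integer(n_blobs), seed = as.integer(seed)),
    class = "phantom_params"
  )
}

#' Generate one phantom volume
#'
#' @param params A `phantom_params`.
#' @param id Volume identifier.
#' @return A [volume_record()] with exact `gt_masks`. Under the default
#'   single blob the foreground slice set is one contiguous interval
#'   containing the central slice, and the central slice always carries
#'   foreground; `n_blobs > 1` deliberately voids these guarantees.
#' @examples
#' rec <- generate_phantom_volume(phantom_params(seed = 7), "p1")
#' sum(rec$gt_masks[central_slice_index(rec$depth) + 1, , ]) > 0
#' @export
generate_phantom_volume <- function(params, id) {
  stopifnot(inherits(params, "phantom_params"))
  z <- params$shape[1]; ny <- params$shape[2]; nx <- params$shape[3]
  rmax_cap <- min(ny, nx) / 2
  if (params$fg_radius_range[1] * rmax_cap < 1) {
    stop("shape too small to contain the minimal foreground ellipse",
         call. = FALSE)
  }
  with_local_seed(params$seed, {
    zc <- central_slice_index(z)
    rmax <- stats::runif(1, params$fg_radius_range[1],
                         params$fg_radius_range[2]) * rmax_cap
    half_ext <- stats::runif(1, params$z_extent_range[1],
                             params$z_extent_range[2]) * z / 2
    aspect <- stats::runif(2, 0.75, 1.25)       # (y, x) axis stretch
    cy0 <- (ny + 1) / 2 + stats::runif(1, -1, 1)
    cx0 <- (nx + 1) / 2 + stats::runif(1, -1, 1)
    # per-slice centre drift: bounded random-walk steps from the centre out
    step_y <- stats::runif(z, -params$wobble, params$wobble)
    step_x <- stats::runif(z, -params$wobble, params$wobble)
    cy <- cx <- numeric(z)
    cy[zc + 1] <- cy0; cx[zc + 1] <- cx0
    for (i in seq(zc + 2, length.out = z - 1 - zc)) {
      cy[i] <- min(max(cy[i - 1] + step_y[i], 2), ny - 1)
      cx[i] <- min(max(cx[i - 1] + step_x[i], 2), nx - 1)
    }
    for (i in seq(zc, by = -1, length.out = zc)) {
      cy[i] <- min(max(cy[i + 1] + step_y[i], 2), ny - 1)
      cx[i] <- min(max(cx[i + 1] + step_x[i], 2), nx - 1)
    }
    gt <- array(0, c(z, ny, nx))
    yy <- matrix(rep(seq_len(ny), nx), ny)
    xx <- matrix(rep(seq_len(nx), each = ny), ny)
    for (i in seq_len(z)) {
      dz <- (i - 1) - zc
      if (abs(dz) >= half_ext) next
      r <- rmax * sqrt(1 - (dz / half_ext)^2)
      m <- ((yy - cy[i]) / (r * aspect[1]))^2 +
           ((xx - cx[i]) / (r * aspect[2]))^2 <= 1
      if (!any(m)) {
        # slice inside the extent always keeps >= 1 voxel so the
        # foreground interval stays contiguous
        m[round(cy[i]), round(cx[i])] <- TRUE
      }
      gt[i, , ] <- m * 1
    }
    if (!is.null(params$n_blobs) && params$n_blobs > 1) {
      # satellite blobs: half-size ellipsoids anywhere in the volume,
      # deliberately breaking central concentration and z-contiguity
      for (bl in seq_len(params$n_blobs - 1)) {
        bz <- sample.int(z, 1)
        bext <- max(1.5, stats::runif(1, 0.1, 0.25) * z)
        br <- stats::runif(1, 0.4, 0.6) * rmax
        bcy <- stats::runif(1, br + 1, ny - br)
        bcx <- stats::runif(1, br + 1, nx - br)
        for (i in seq_len(z)) {
          dz <- (i - 1) - (bz - 1)
          if (abs(dz) >= bext) next
          r <- br * sqrt(1 - (dz / bext)^2)
          if (r < 0.5) next
          m <- ((yy - bcy) / r)^2 + ((xx - bcx) / r)^2 <= 1
          gt[i, , ] <- pmax(gt[i, , ], m * 1)
        }
      }
    }
    img <- array(stats::rnorm(z * ny * nx * params$channels,
                              sd = params$noise_sd),
                 c(z, ny, nx, params$channels))
    shift <- params$intensity_offset * params$noise_sd
    for (ch in seq_len(params$channels)) {
      img[, , , ch] <- img[, , , ch] + shift * gt
    }
    volume_record(id, img, spacing = params$spacing, gt_masks = gt)
  })
}

#' Generate a phantom dataset with a train/validation/test split
#'
#' Volumes receive per-volume seeds derived deterministically from `seed`;
#' the split is by volume with sizes `floor(n * frac)` and the remainder
#' assigned to training.
#'
#' @param n Number of volumes (>= 3).
#' @param params Shared `phantom_params` (its `seed` field is superseded by
#'   the derived per-volume seeds).
#' @param split_fracs Train/validation/test fractions summing to 1.
#' @param seed Integer seed controlling per-volume seeds and the split.
#' @return List with `volumes` (list of [volume_record()]) and `split`
#'   (a [dataset_split()]).
#' @examples
#' ds <- generate_phantom_dataset(5, phantom_params(shape = c(8, 16, 16)),
#'                                seed = 1)
#' lengths(ds$split)
#' @export
generate_phantom_dataset <- function(n, params = phantom_params(),
                                     split_fracs = c(0.70, 0.15, 0.15),
                                     seed = 1L) {
  if (n < 3) stop("need at least 3 volumes to split", call. = FALSE)
  ids <- sprintf("phantom_%03d", seq_len(n))
  vol_seeds <- with_local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  volumes <- lapply(seq_len(n), function(i) {
    p <- params
    p$seed <- vol_seeds[i]
    generate_phantom_volume(p, ids[i])
  })
  names(volumes) <- ids
  split <- split_dataset(ids, fracs = split_fracs, seed = seed + 1L)
  list(volumes = volumes, split = split)
}
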
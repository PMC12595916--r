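# Shared fixture builders. Everything is generated in code at test time.

tiny_phantom <- function(seed, shape = c(12, 16, 16)) {
  generate_phantom_volume(phantom_params(shape = shape, seed = seed),
                          sprintf("tiny_%d", seed))
}

tiny_spec <- function(channels = 1) {
  model_spec(2, in_channels = channels, base_filters = 2, levels = 2,
             max_filters = 8)
}

# random binary 16^3 masks with guaranteed foreground: a blob plus salt
random_mask_16 <- function(seed) {
  set.seed(seed)
  d <- c(16, 16, 16)
  m <- array(0, d)
  ctr <- runif(3, 5, 12)
  r <- runif(1, 2, 5)
  idx <- as.matrix(expand.grid(z = 1:16, y = 1:16, x = 1:16))
  inside <- colSums((t(idx) - ctr)^2) <= r^2
  m[idx[inside, ]] <- 1
  salt <- sample(length(m), 25)
  m[salt] <- 1
  m
}

# --- independent brute-force HD95 oracle ---------------------------------
# naive 6-neighbour surface scan (triple loop, no shared code with the
# package's surface_mask)
bf_surface_coords <- function(mask) {
  d <- dim(mask)
  out <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask[i, j, k] != 1) next
    nb <- c(
      if (i > 1) mask[i - 1, j, k] else 0,
      if (i < d[1]) mask[i + 1, j, k] else 0,
      if (j > 1) mask[i, j - 1, k] else 0,
      if (j < d[2]) mask[i, j + 1, k] else 0,
      if (k > 1) mask[i, j, k - 1] else 0,
      if (k < d[3]) mask[i, j, k + 1] else 0)
    if (length(nb) < 6 || any(nb == 0)) out <- rbind(out, c(i, j, k))
  }
  out
}

# all-pairs surface distances + identical percentile rule
bf_hd95 <- function(A, B, spacing = c(1, 1, 1)) {
  pa <- sweep(bf_surface_coords(A), 2, spacing, `*`)
  pb <- sweep(bf_surface_coords(B), 2, spacing, `*`)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * pa %*% t(pb)
  d2[d2 < 0] <- 0
  dmat <- sqrt(d2)
  dd <- c(apply(dmat, 1, min), apply(dmat, 2, min))
  quantile(dd, 0.95, type = 7, names = FALSE)
}

# reference slice-selection enumerator: simulates the symmetric budget rule
# step by step with plain interval arithmetic (independent of label_state)
bf_propagation_steps <- function(depth, k) {
  s <- max(1, floor(k * depth / 2 + 0.5))
  lo <- hi <- floor(depth / 2)
  steps <- 0
  while (lo > 0 || hi < depth - 1) {
    below <- min(lo, s + max(0, s - (depth - 1 - hi)))
    above <- min(depth - 1 - hi, s + max(0, s - lo))
    lo <- lo - below
    hi <- hi + above
    steps <- steps + 1
    if (steps > depth + 1) stop("reference enumerator failed to terminate")
  }
  steps
}
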
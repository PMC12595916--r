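# Independent double-precision reference implementation of the 2D U-Net
# forward pass, operating directly on the exported weight vectors. Used to
# cross-check the native forward pass and (via numerical differentiation)
# its analytic gradients.

ref_filters <- function(spec, level) min(spec$base_filters * 2^level, spec$max_filters)

# weight list order: enc conv pairs (2 per level + 2 bottleneck), then per
# decoder level (up, conv1, conv2), then the final 1x1 conv; each layer
# contributes (W, b). Conv W is cout x (9 * cin) with column blocks indexed
# by kernel offset o = (dr + 1) * 3 + (dc + 1); up W is (4 * cout) x cin
# with row blocks indexed by o = a * 2 + b for output pixel (2r + a, 2c + b).
ref_unpack_weights <- function(weights, spec) {
  layers <- list()
  i <- 1
  take <- function(cout, ncol_) {
    W <- matrix(weights[[i]], nrow = cout)
    stopifnot(ncol(W) == ncol_)
    b <- weights[[i + 1]]
    i <<- i + 2
    list(W = W, b = b)
  }
  cin <- spec$in_channels
  for (l in seq_len(spec$levels) - 1L) {
    f <- ref_filters(spec, l)
    layers[[sprintf("enc%d_1", l)]] <- take(f, 9 * cin)
    layers[[sprintf("enc%d_2", l)]] <- take(f, 9 * f)
    cin <- f
  }
  fb <- ref_filters(spec, spec$levels)
  layers[["bott_1"]] <- take(fb, 9 * cin)
  layers[["bott_2"]] <- take(fb, 9 * fb)
  cin <- fb
  for (l in rev(seq_len(spec$levels) - 1L)) {
    f <- ref_filters(spec, l)
    layers[[sprintf("up%d", l)]] <- take(4 * f, cin)
    layers[[sprintf("dec%d_1", l)]] <- take(f, 9 * 2 * f)
    layers[[sprintf("dec%d_2", l)]] <- take(f, 9 * f)
    cin <- f
  }
  layers[["final"]] <- take(1, cin)
  layers
}

# A: channels x npix with pixel p = r + c * H (zero-based)
ref_conv3 <- function(A, W, b, H, Wd) {
  C <- nrow(A)
  npix <- H * Wd
  col <- matrix(0, 9 * C, npix)
  r <- (seq_len(npix) - 1L) %% H
  cc <- (seq_len(npix) - 1L) %/% H
  o <- 0
  for (dr in -1:1) for (dc in -1:1) {
    rr <- r + dr; ccc <- cc + dc
    ok <- rr >= 0 & rr < H & ccc >= 0 & ccc < Wd
    src <- rr + ccc * H + 1L
    block <- matrix(0, C, npix)
    block[, ok] <- A[, src[ok], drop = FALSE]
    col[o * C + seq_len(C), ] <- block
    o <- o + 1
  }
  sweep(W %*% col, 1, b, "+")
}

ref_pool <- function(A, H, Wd) {
  npix <- H * Wd
  Ho <- H %/% 2; Wo <- Wd %/% 2
  out <- matrix(-Inf, nrow(A), Ho * Wo)
  po <- (seq_len(Ho * Wo) - 1L)
  r <- po %% Ho; cc <- po %/% Ho
  for (a in 0:1) for (bq in 0:1) {
    src <- (2 * r + a) + (2 * cc + bq) * H + 1L
    out <- pmax(out, A[, src, drop = FALSE])
  }
  out
}

ref_up <- function(A, W, b, H, Wd) {
  cout <- length(b)
  M <- W %*% A
  out <- matrix(0, cout, 4 * H * Wd)
  p <- (seq_len(H * Wd) - 1L)
  r <- p %% H; cc <- p %/% H
  for (a in 0:1) for (bq in 0:1) {
    o <- a * 2 + bq
    dst <- (2 * r + a) + (2 * cc + bq) * (2 * H) + 1L
    out[, dst] <- M[o * cout + seq_len(cout), , drop = FALSE]
  }
  sweep(out, 1, b, "+")
}

relu_ref <- function(x) pmax(x, 0)

# x: (H, W, C) array -> probability vector of length H * W (pixel order)
ref_forward <- function(x, weights, spec) {
  H <- dim(x)[1]; Wd <- dim(x)[2]
  L <- ref_unpack_weights(weights, spec)
  A <- t(matrix(x, H * Wd, dim(x)[3]))
  h <- H; w <- Wd
  skips <- list()
  for (l in seq_len(spec$levels) - 1L) {
    A <- relu_ref(ref_conv3(A, L[[sprintf("enc%d_1", l)]]$W,
                            L[[sprintf("enc%d_1", l)]]$b, h, w))
    A <- relu_ref(ref_conv3(A, L[[sprintf("enc%d_2", l)]]$W,
                            L[[sprintf("enc%d_2", l)]]$b, h, w))
    skips[[l + 1]] <- A
    A <- ref_pool(A, h, w)
    h <- h %/% 2; w <- w %/% 2
  }
  A <- relu_ref(ref_conv3(A, L$bott_1$W, L$bott_1$b, h, w))
  A <- relu_ref(ref_conv3(A, L$bott_2$W, L$bott_2$b, h, w))
  for (l in rev(seq_len(spec$levels) - 1L)) {
    A <- relu_ref(ref_up(A, L[[sprintf("up%d", l)]]$W,
                         L[[sprintf("up%d", l)]]$b, h, w))
    h <- 2 * h; w <- 2 * w
    A <- rbind(A, skips[[l + 1]])
    A <- relu_ref(ref_conv3(A, L[[sprintf("dec%d_1", l)]]$W,
                            L[[sprintf("dec%d_1", l)]]$b, h, w))
    A <- relu_ref(ref_conv3(A, L[[sprintf("dec%d_2", l)]]$W,
                            L[[sprintf("dec%d_2", l)]]$b, h, w))
  }
  logits <- drop(L$final$W %*% A) + L$final$b
  1 / (1 + exp(-logits))
}

# weight-normalised mean BCE of the reference forward over a slice list
ref_loss <- function(weights, spec, xs, ys, w) {
  num <- 0; den <- 0
  for (i in seq_along(xs)) {
    p <- pmin(pmax(ref_forward(xs[[i]], weights, spec), 1e-7), 1 - 1e-7)
    y <- as.vector(ys[[i]])
    num <- num + w[i] * sum(-(y * log(p) + (1 - y) * log(1 - p)))
    den <- den + w[i] * length(y)
  }
  num / den
}
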
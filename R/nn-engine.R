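# Internal neural-network engine.
#
# All dense linear algebra is delegated to BLAS through R matrix products;
# convolutions are im2col gathers followed by a single GEMM per layer and
# image. Gradients are hand-derived (manual backprop); the input gradient of
# a stride-1 same-padded convolution is computed as another im2col GEMM with
# spatially flipped kernels, which has the same cost as the forward pass.
#
# Activation layout conventions:
#   * one image / feature map  = matrix (H*W) x C (pixels column-major
#     within a channel, channels as columns);
#   * flattened feature vector = as.vector() of that matrix;
#   * a dense batch            = matrix features x N.

# ---- im2col geometry --------------------------------------------------------

# index matrix for stride-1 same-padding k x k convolution over an H x W x C
# input: row = output pixel, col = (dy, dx, c) patch element; entries index
# into c(0, as.vector(x)) so out-of-bounds elements hit the leading zero
build_im2col_idx <- function(h, w, cin, k) {
  pad <- (k - 1L) %/% 2L
  ys <- rep(seq_len(h), w)
  xs <- rep(seq_len(w), each = h)
  idx <- matrix(1L, h * w, k * k * cin)
  col <- 0L
  for (ci in seq_len(cin)) {
    off <- (ci - 1L) * h * w
    for (dx in seq_len(k)) {
      for (dy in seq_len(k)) {
        col <- col + 1L
        yy <- ys + dy - 1L - pad
        xx <- xs + dx - 1L - pad
        ok <- yy >= 1L & yy <= h & xx >= 1L & xx <= w
        v <- rep(1L, h * w)
        v[ok] <- off + (xx[ok] - 1L) * h + yy[ok] + 1L
        idx[, col] <- v
      }
    }
  }
  idx
}

# kernel-flip index pair: W_flip (k*k*cout x cin) built from W (k*k*cin x cout)
# so that dX = im2col(dOut) %*% W_flip
build_flip_map <- function(cin, cout, k) {
  rows <- integer(k * k * cout * cin)
  cols <- integer(k * k * cout * cin)
  p <- 0L
  for (ci in seq_len(cin)) {
    for (co in seq_len(cout)) {
      for (dx in seq_len(k)) {
        for (dy in seq_len(k)) {
          p <- p + 1L
          rows[p] <- ((ci - 1L) * k + (k - dx)) * k + (k + 1L - dy)
          cols[p] <- co
        }
      }
    }
  }
  list(rows = rows, cols = cols, dim = c(k * k * cout, cin))
}

flip_weights <- function(w, flip) {
  matrix(w[cbind(flip$rows, flip$cols)], flip$dim[1], flip$dim[2])
}

conv_geom <- function(h, w, cin, cout, k) {
  list(
    h = h, w = w, cin = cin, cout = cout, k = k,
    idx_in = build_im2col_idx(h, w, cin, k),
    idx_out = build_im2col_idx(h, w, cout, k),
    flip = build_flip_map(cin, cout, k)
  )
}

# gather patches without the matrix() copy: index then set dim in place
im2col <- function(x, idx, nrow) {
  p <- c(0, x)[idx]
  dim(p) <- c(nrow, length(idx) / nrow)
  p
}

conv_forward <- function(x, w, b, geom) {
  z <- im2col(x, geom$idx_in, geom$h * geom$w) %*% w
  z + rep(b, each = geom$h * geom$w)
}

# gradient wrt the conv input, as a flipped-kernel convolution of dz;
# pass wf = flip_weights(w, geom$flip) precomputed when calling in a loop
conv_backward_input <- function(dz, w, geom, wf = NULL) {
  if (is.null(wf)) wf <- flip_weights(w, geom$flip)
  im2col(dz, geom$idx_out, geom$h * geom$w) %*% wf
}

# weight/bias gradients; x is the cached layer input (re-gathered here so
# forward caches stay small)
conv_backward_params <- function(dz, x, geom) {
  p <- im2col(x, geom$idx_in, geom$h * geom$w)
  list(dw = crossprod(p, dz), db = colSums(dz))
}

# ---- 2x2 max pooling (stride 2, truncating odd edges) -----------------------

pool_geom <- function(h, w, channels) {
  h2 <- h %/% 2L
  w2 <- w %/% 2L
  rr <- rep(seq_len(h2) * 2L - 1L, w2)
  cc <- rep(seq_len(w2) * 2L - 1L, each = h2)
  cand <- cbind(
    (cc - 1L) * h + rr,
    (cc - 1L) * h + rr + 1L,
    cc * h + rr,
    cc * h + rr + 1L
  )
  n_out <- h2 * w2
  ch_off <- rep((seq_len(channels) - 1L) * h * w, each = n_out)
  # element indices of the 4 pool candidates over all channels at once
  idx4 <- cbind(
    cand[, 1] + ch_off, cand[, 2] + ch_off,
    cand[, 3] + ch_off, cand[, 4] + ch_off
  )
  el <- seq_len(n_out * channels) - 1L
  list(
    h = h, w = w, h2 = h2, w2 = w2, cand = cand, channels = channels,
    idx4 = idx4, r_out = el %% n_out + 1L, col = el %/% n_out + 1L
  )
}

# x: (h*w) x C -> list(out (h2*w2) x C, win winner candidate index 1..4)
pool_forward <- function(x, geom) {
  flat <- x[geom$idx4]
  dim(flat) <- c(geom$h2 * geom$w2 * geom$channels, 4L)
  win <- max.col(flat, ties.method = "first")
  out <- flat[cbind(seq_len(nrow(flat)), win)]
  dim(out) <- c(geom$h2 * geom$w2, geom$channels)
  list(out = out, win = win)
}

pool_backward <- function(dout, win, geom) {
  in_row <- geom$cand[cbind(geom$r_out, win)]
  dx <- matrix(0, geom$h * geom$w, geom$channels)
  dx[cbind(in_row, geom$col)] <- dout # pool regions are disjoint
  dx
}

# ---- dense / activations / loss --------------------------------------------

dense_forward <- function(x, w, b) crossprod(w, x) + b

dense_backward <- function(dy, x, w) {
  list(dw = x %*% t(dy), db = rowSums(dy), dx = w %*% dy)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# columns of z are observations; y integer labels 1..K
softmax_xent <- function(z, y) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  p <- sweep(e, 2, colSums(e), "/")
  n <- ncol(z)
  loss <- -mean(log(pmax(p[cbind(y, seq_len(n))], 1e-12)))
  dz <- p
  dz[cbind(y, seq_len(n))] <- dz[cbind(y, seq_len(n))] - 1
  list(p = p, loss = loss, dz = dz / n)
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# ---- parameter initialisation and Adam --------------------------------------

# uniform fan-in initialisation: U(-sqrt(6/fan_in), +sqrt(6/fan_in))
init_mat <- function(nr, nc, fan_in) {
  matrix(runif(nr * nc, -sqrt(6 / fan_in), sqrt(6 / fan_in)), nr, nc)
}

adam_state <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

zero_grads <- function(params) lapply(params, function(p) p * 0)
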
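# LSTM and ConvLSTM cells with peephole connections.
#
# Gate equations (sigma = logistic, elementwise products throughout):
#   i_t = sigma(W_xi x_t + W_hi h_{t-1} + w_ci * c_{t-1} + b_i)
#   f_t = sigma(W_xf x_t + W_hf h_{t-1} + w_cf * c_{t-1} + b_f)
#   c_t = f_t * c_{t-1} + i_t * tanh(W_xc x_t + W_hc h_{t-1} + b_c)
#   o_t = sigma(W_xo x_t + W_ho h_{t-1} + w_co * c_{peep} + b_o)
#   h_t = o_t * tanh(c_t)
# The output-gate peephole c_peep is the PREVIOUS cell state by default
# (exactly as the equations above are written); many implementations use the
# freshly computed c_t instead, available via peephole_output = "current".
# Peepholes are elementwise (diagonal) weights. The ConvLSTM replaces the
# affine maps W x by same-padded 2-D convolutions over spatial feature maps
# while the peepholes stay elementwise.

#' One step of a peephole LSTM cell
#'
#' @param x input vector (length `input_dim`).
#' @param h_prev,c_prev previous hidden and cell state vectors (length
#'   `units`).
#' @param weights named list: input maps `W_xi, W_xf, W_xc, W_xo`
#'   (`input_dim x units`), recurrent maps `W_hi, W_hf, W_hc, W_ho`
#'   (`units x units`), elementwise peepholes `w_ci, w_cf, w_co` (length
#'   `units`), biases `b_i, b_f, b_c, b_o` (length `units`).
#' @param peephole_output `"previous"` (default): the output gate peeps at
#'   `c_prev`, as the gate equations are written; `"current"`: at the new
#'   cell state.
#' @return List with elements `h`, `c` (and gate activations `i`, `f`, `o`).
#' @examples
#' w <- init_lstm_weights(2, 3, seed = 1)
#' st <- lstm_step(c(0.5, -1), rep(0, 3), rep(0, 3), w)
#' st$h
#' @export
lstm_step <- function(x, h_prev, c_prev, weights,
                      peephole_output = c("previous", "current")) {
  peephole_output <- match.arg(peephole_output)
  w <- weights
  if (nrow(w$W_xi) != length(x) || ncol(w$W_xi) != length(h_prev) ||
      length(h_prev) != length(c_prev)) {
    ss_abort("lstm_step: weight/state shapes are inconsistent",
      class = "seedstage_shape_error"
    )
  }
  i <- sigmoid(drop(crossprod(w$W_xi, x)) + drop(crossprod(w$W_hi, h_prev)) +
                 w$w_ci * c_prev + w$b_i)
  f <- sigmoid(drop(crossprod(w$W_xf, x)) + drop(crossprod(w$W_hf, h_prev)) +
                 w$w_cf * c_prev + w$b_f)
  g <- tanh(drop(crossprod(w$W_xc, x)) + drop(crossprod(w$W_hc, h_prev)) +
              w$b_c)
  cc <- f * c_prev + i * g
  c_peep <- if (peephole_output == "previous") c_prev else cc
  o <- sigmoid(drop(crossprod(w$W_xo, x)) + drop(crossprod(w$W_ho, h_prev)) +
                 w$w_co * c_peep + w$b_o)
  h <- o * tanh(cc)
  list(h = h, c = cc, i = i, f = f, o = o, g = g)
}

#' Initialise peephole LSTM weights
#'
#' Uniform fan-in initialisation; the forget-gate bias starts at 1 so that
#' early training does not erase the cell state.
#'
#' @param input_dim,units layer dimensions.
#' @param seed optional seed for reproducible initialisation.
#' @return Named weight list in the format [lstm_step()] expects.
#' @export
init_lstm_weights <- function(input_dim, units, seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  wx <- function() init_mat(input_dim, units, input_dim)
  wh <- function() init_mat(units, units, units)
  pe <- function() runif(units, -0.1, 0.1)
  list(
    W_xi = wx(), W_xf = wx(), W_xc = wx(), W_xo = wx(),
    W_hi = wh(), W_hf = wh(), W_hc = wh(), W_ho = wh(),
    w_ci = pe(), w_cf = pe(), w_co = pe(),
    b_i = numeric(units), b_f = rep(1, units), b_c = numeric(units),
    b_o = numeric(units)
  )
}

# full-sequence forward with caches for BPTT; x_seq: input_dim x T matrix;
# h0/c0 carry state across truncated-BPTT chunks (constants wrt gradients)
lstm_forward <- function(x_seq, weights, peephole_output = "previous",
                         h0 = NULL, c0 = NULL) {
  u <- ncol(weights$W_xi)
  tt <- ncol(x_seq)
  h <- h0 %||% numeric(u)
  cc <- c0 %||% numeric(u)
  hs <- matrix(0, u, tt)
  cache <- vector("list", tt)
  for (t in seq_len(tt)) {
    st <- lstm_step(x_seq[, t], h, cc, weights, peephole_output)
    cache[[t]] <- list(h_prev = h, c_prev = cc, st = st)
    h <- st$h
    cc <- st$c
    hs[, t] <- h
  }
  list(h = hs, cache = cache)
}

# BPTT through the whole sequence; dh_seq: units x T gradient on the hidden
# outputs. Returns weight grads and dx (input_dim x T).
lstm_backward <- function(dh_seq, x_seq, weights, cache,
                          peephole_output = "previous") {
  w <- weights
  u <- ncol(w$W_xi)
  tt <- ncol(x_seq)
  g <- lapply(w, function(p) p * 0)
  dh_next <- numeric(u)
  dc_next <- numeric(u)
  # gate pre-activation gradients collected over time; the (large)
  # input-side weight and dx products are then single GEMMs over the
  # whole sequence instead of per-step outer products
  da_is <- matrix(0, u, tt)
  da_fs <- matrix(0, u, tt)
  da_cs <- matrix(0, u, tt)
  da_os <- matrix(0, u, tt)
  h_prevs <- matrix(0, u, tt)
  for (t in rev(seq_len(tt))) {
    ca <- cache[[t]]
    st <- ca$st
    tc <- tanh(st$c)
    dh <- dh_seq[, t] + dh_next
    do_ <- dh * tc
    da_o <- do_ * st$o * (1 - st$o)
    dc <- dh * st$o * (1 - tc^2) + dc_next
    if (peephole_output == "current") {
      dc <- dc + da_o * w$w_co
    }
    di <- dc * st$g
    df <- dc * ca$c_prev
    dg <- dc * st$i
    da_i <- di * st$i * (1 - st$i)
    da_f <- df * st$f * (1 - st$f)
    da_c <- dg * (1 - st$g^2)
    dc_prev <- dc * st$f + da_i * w$w_ci + da_f * w$w_cf
    if (peephole_output == "previous") {
      dc_prev <- dc_prev + da_o * w$w_co
    }
    g$w_ci <- g$w_ci + da_i * ca$c_prev
    g$w_cf <- g$w_cf + da_f * ca$c_prev
    g$w_co <- g$w_co +
      da_o * (if (peephole_output == "previous") ca$c_prev else st$c)
    da_is[, t] <- da_i
    da_fs[, t] <- da_f
    da_cs[, t] <- da_c
    da_os[, t] <- da_o
    h_prevs[, t] <- ca$h_prev
    dh_next <- drop(
      w$W_hi %*% da_i + w$W_hf %*% da_f + w$W_hc %*% da_c + w$W_ho %*% da_o
    )
    dc_next <- dc_prev
  }
  g$W_xi <- tcrossprod(x_seq, da_is)
  g$W_xf <- tcrossprod(x_seq, da_fs)
  g$W_xc <- tcrossprod(x_seq, da_cs)
  g$W_xo <- tcrossprod(x_seq, da_os)
  g$W_hi <- tcrossprod(h_prevs, da_is)
  g$W_hf <- tcrossprod(h_prevs, da_fs)
  g$W_hc <- tcrossprod(h_prevs, da_cs)
  g$W_ho <- tcrossprod(h_prevs, da_os)
  g$b_i <- rowSums(da_is)
  g$b_f <- rowSums(da_fs)
  g$b_c <- rowSums(da_cs)
  g$b_o <- rowSums(da_os)
  dx <- w$W_xi %*% da_is + w$W_xf %*% da_fs + w$W_xc %*% da_cs +
    w$W_xo %*% da_os
  list(grads = g, dx = dx)
}

# ---- ConvLSTM ---------------------------------------------------------------

#' One step of a peephole ConvLSTM cell
#'
#' Identical gate structure to [lstm_step()] with the input and recurrent
#' affine maps replaced by same-padded 2-D convolutions over spatial feature
#' maps; peephole terms stay elementwise. States preserve the spatial size
#' of the input. At 1 x 1 spatial extent with 1 x 1 kernels the cell reduces
#' exactly to the LSTM cell with the same weights.
#'
#' @param x input array `h x w x cin` (or an `(h*w) x cin` matrix).
#' @param h_prev,c_prev state arrays `h x w x units` (or `(h*w) x units`
#'   matrices).
#' @param weights named list: convolution kernels `W_xi, W_xf, W_xc, W_xo`
#'   (`(k*k*cin) x units`), `W_hi, W_hf, W_hc, W_ho` (`(k*k*units) x units`),
#'   elementwise peepholes `w_ci, w_cf, w_co` (`(h*w) x units` matrices, or
#'   vectors recycled over space), per-channel biases `b_i, b_f, b_c, b_o`.
#' @param geom optional precomputed geometry (internal use).
#' @inheritParams lstm_step
#' @return List with `h`, `c` as `(h*w) x units` matrices plus the spatial
#'   dims in `dim_hw`.
#' @export
convlstm_step <- function(x, h_prev, c_prev, weights,
                          peephole_output = c("previous", "current"),
                          geom = NULL) {
  peephole_output <- match.arg(peephole_output)
  w <- weights
  if (length(dim(x)) == 3) {
    dhw <- dim(x)[1:2]
    x <- matrix(x, prod(dhw))
  } else {
    dhw <- attr(x, "dim_hw") %||% c(nrow(x), 1L)
  }
  if (length(dim(h_prev)) == 3) h_prev <- matrix(h_prev, prod(dhw))
  if (length(dim(c_prev)) == 3) c_prev <- matrix(c_prev, prod(dhw))
  units <- ncol(w$W_xi)
  cin <- ncol(x)
  k <- as.integer(sqrt(nrow(w$W_xi) / cin))
  if (k * k * cin != nrow(w$W_xi)) {
    ss_abort("convlstm_step: kernel size inconsistent with input channels",
      class = "seedstage_shape_error"
    )
  }
  if (min(dhw) > 1 && k > 2 * min(dhw) - 1) {
    ss_abort("convlstm_step: kernel larger than the input extent",
      class = "seedstage_shape_error"
    )
  }
  if (is.null(geom)) {
    geom <- list(
      x = conv_geom(dhw[1], dhw[2], cin, units, k),
      h = conv_geom(dhw[1], dhw[2], units, units, k)
    )
  }
  cx <- function(wm) conv_forward(as.vector(x), wm, numeric(units), geom$x)
  ch <- function(wm) conv_forward(as.vector(h_prev), wm, numeric(units),
                                  geom$h)
  pe <- function(v) if (is.matrix(v)) v else matrix(v, prod(dhw), units,
                                                    byrow = TRUE)
  bb <- function(b) rep(b, each = prod(dhw))
  i <- sigmoid(cx(w$W_xi) + ch(w$W_hi) + pe(w$w_ci) * c_prev + bb(w$b_i))
  f <- sigmoid(cx(w$W_xf) + ch(w$W_hf) + pe(w$w_cf) * c_prev + bb(w$b_f))
  g <- tanh(cx(w$W_xc) + ch(w$W_hc) + bb(w$b_c))
  cc <- f * c_prev + i * g
  c_peep <- if (peephole_output == "previous") c_prev else cc
  o <- sigmoid(cx(w$W_xo) + ch(w$W_ho) + pe(w$w_co) * c_peep + bb(w$b_o))
  h <- o * tanh(cc)
  list(h = h, c = cc, i = i, f = f, o = o, g = g, dim_hw = dhw)
}

#' Initialise ConvLSTM weights
#'
#' @param spatial `c(h, w)` spatial extent of the feature maps.
#' @param cin input channels.
#' @param units number of ConvLSTM filters (state channels).
#' @param k kernel size (odd).
#' @param seed optional seed.
#' @return Named weight list in the format [convlstm_step()] expects.
#' @export
init_convlstm_weights <- function(spatial, cin, units, k = 3, seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  np <- prod(spatial)
  wx <- function() init_mat(k * k * cin, units, k * k * cin)
  wh <- function() init_mat(k * k * units, units, k * k * units)
  pe <- function() matrix(runif(np * units, -0.1, 0.1), np, units)
  list(
    W_xi = wx(), W_xf = wx(), W_xc = wx(), W_xo = wx(),
    W_hi = wh(), W_hf = wh(), W_hc = wh(), W_ho = wh(),
    w_ci = pe(), w_cf = pe(), w_co = pe(),
    b_i = numeric(units), b_f = rep(1, units), b_c = numeric(units),
    b_o = numeric(units)
  )
}

# sequence forward; x_seq: list of (h*w) x cin matrices (or one 4-D array)
convlstm_forward <- function(x_seq, weights, geom, dhw,
                             peephole_output = "previous",
                             h0 = NULL, c0 = NULL) {
  units <- ncol(weights$W_xi)
  np <- prod(dhw)
  tt <- length(x_seq)
  h <- h0 %||% matrix(0, np, units)
  cc <- c0 %||% matrix(0, np, units)
  hs <- vector("list", tt)
  cache <- vector("list", tt)
  for (t in seq_len(tt)) {
    xt <- x_seq[[t]]
    attr(xt, "dim_hw") <- dhw
    st <- convlstm_step(xt, h, cc, weights, peephole_output, geom = geom)
    cache[[t]] <- list(h_prev = h, c_prev = cc, st = st)
    h <- st$h
    cc <- st$c
    hs[[t]] <- h
  }
  list(h = hs, cache = cache)
}

convlstm_backward <- function(dh_seq, x_seq, weights, cache, geom, dhw,
                              peephole_output = "previous") {
  w <- weights
  units <- ncol(w$W_xi)
  np <- prod(dhw)
  tt <- length(x_seq)
  g <- lapply(w, function(p) p * 0)
  dx <- vector("list", tt)
  dh_next <- matrix(0, np, units)
  dc_next <- matrix(0, np, units)
  pe <- function(v) if (is.matrix(v)) v else matrix(v, np, units, byrow = TRUE)
  # kernel flips are weight-only: compute once, reuse every timestep
  wfx <- lapply(c("W_xi", "W_xf", "W_xc", "W_xo"), function(nm) {
    flip_weights(w[[nm]], geom$x$flip)
  })
  wfh <- lapply(c("W_hi", "W_hf", "W_hc", "W_ho"), function(nm) {
    flip_weights(w[[nm]], geom$h$flip)
  })
  for (t in rev(seq_len(tt))) {
    ca <- cache[[t]]
    st <- ca$st
    x <- x_seq[[t]]
    tc <- tanh(st$c)
    dh <- dh_seq[[t]] + dh_next
    do_ <- dh * tc
    da_o <- do_ * st$o * (1 - st$o)
    dc <- dh * st$o * (1 - tc^2) + dc_next
    if (peephole_output == "current") dc <- dc + da_o * pe(w$w_co)
    di <- dc * st$g
    df <- dc * ca$c_prev
    dg <- dc * st$i
    da_i <- di * st$i * (1 - st$i)
    da_f <- df * st$f * (1 - st$f)
    da_c <- dg * (1 - st$g^2)
    dc_prev <- dc * st$f + da_i * pe(w$w_ci) + da_f * pe(w$w_cf)
    if (peephole_output == "previous") dc_prev <- dc_prev + da_o * pe(w$w_co)

    px <- matrix(c(0, as.vector(x))[geom$x$idx_in], np)
    ph <- matrix(c(0, as.vector(ca$h_prev))[geom$h$idx_in], np)
    g$W_xi <- g$W_xi + crossprod(px, da_i)
    g$W_xf <- g$W_xf + crossprod(px, da_f)
    g$W_xc <- g$W_xc + crossprod(px, da_c)
    g$W_xo <- g$W_xo + crossprod(px, da_o)
    g$W_hi <- g$W_hi + crossprod(ph, da_i)
    g$W_hf <- g$W_hf + crossprod(ph, da_f)
    g$W_hc <- g$W_hc + crossprod(ph, da_c)
    g$W_ho <- g$W_ho + crossprod(ph, da_o)
    g$w_ci <- g$w_ci + da_i * ca$c_prev
    g$w_cf <- g$w_cf + da_f * ca$c_prev
    g$w_co <- g$w_co +
      da_o * (if (peephole_output == "previous") ca$c_prev else st$c)
    g$b_i <- g$b_i + colSums(da_i)
    g$b_f <- g$b_f + colSums(da_f)
    g$b_c <- g$b_c + colSums(da_c)
    g$b_o <- g$b_o + colSums(da_o)

    dx[[t]] <- conv_backward_input(da_i, w$W_xi, geom$x, wfx[[1]]) +
      conv_backward_input(da_f, w$W_xf, geom$x, wfx[[2]]) +
      conv_backward_input(da_c, w$W_xc, geom$x, wfx[[3]]) +
      conv_backward_input(da_o, w$W_xo, geom$x, wfx[[4]])
    dh_next <- conv_backward_input(da_i, w$W_hi, geom$h, wfh[[1]]) +
      conv_backward_input(da_f, w$W_hf, geom$h, wfh[[2]]) +
      conv_backward_input(da_c, w$W_hc, geom$h, wfh[[3]]) +
      conv_backward_input(da_o, w$W_ho, geom$h, wfh[[4]])
    dc_next <- dc_prev
  }
  list(grads = g, dx = dx)
}
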
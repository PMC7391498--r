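# Frame-classification networks: the memoryless multi-class CNN baseline,
# two-class chained CNNs, CNN-LSTM and ConvLSTM, all sharing one
# convolutional feature-extraction stack.

#' Specify a stage-classification network
#'
#' The default ("reference") architecture is a small AlexNet-like
#' stack: four 3x3 convolution layers with 64, 128, 256 and 256 filters,
#' each followed by ReLU and 2x2 max-pooling; then a 512-unit fully
#' connected layer with ReLU and dropout (p = 0.5) and a softmax output
#' layer. `arch` selects how temporal context is added:
#' `"cnn"` scores frames independently; `"cnn_lstm"` inserts a 128-unit
#' peephole LSTM between the flattened conv features and the classification
#' head; `"convlstm"` inserts a convolutional LSTM operating on the final
#' feature maps. For binary chained models set `n_classes = 2` and
#' `class_labels` to the pair of consecutive stages.
#'
#' @param arch `"cnn"`, `"cnn_lstm"` or `"convlstm"`.
#' @param input_size side of the square input crop in pixels (default 89).
#' @param channels input channels (RGB = 3).
#' @param conv_filters filter counts of the conv stack.
#' @param kernel conv kernel size (square).
#' @param fc_units width of the fully connected head layer.
#' @param dropout dropout probability in the head.
#' @param lstm_units LSTM width for `"cnn_lstm"` (default 128).
#' @param convlstm_filters,convlstm_kernel ConvLSTM state channels and
#'   kernel for `"convlstm"`.
#' @param n_classes 4 (full ontology) or 2 (chained binary models).
#' @param class_labels stage names the output units correspond to, in
#'   ontological order.
#' @param peephole_output output-gate peephole convention, see
#'   [lstm_step()].
#' @return A list of class `network_spec`.
#' @examples
#' network_spec("cnn")          # the reference memoryless CNN
#' network_spec("cnn_lstm")     # + 128-unit LSTM
#' @export
network_spec <- function(arch = c("cnn", "cnn_lstm", "convlstm"),
                         input_size = 89,
                         channels = 3,
                         conv_filters = c(64, 128, 256, 256),
                         kernel = 3,
                         fc_units = 512,
                         dropout = 0.5,
                         lstm_units = 128,
                         convlstm_filters = 64,
                         convlstm_kernel = 3,
                         n_classes = 4,
                         class_labels = NULL,
                         peephole_output = c("previous", "current")) {
  arch <- match.arg(arch)
  peephole_output <- match.arg(peephole_output)
  if (!n_classes %in% c(2, 4)) {
    ss_abort("n_classes must be 2 or 4", class = "seedstage_config_error")
  }
  class_labels <- class_labels %||%
    if (n_classes == 4) stage_levels() else c("Soil", "FA")
  if (length(class_labels) != n_classes ||
      !all(class_labels %in% stage_levels())) {
    ss_abort("class_labels must name n_classes developmental stages",
      class = "seedstage_config_error"
    )
  }
  size <- input_size
  for (i in seq_along(conv_filters)) size <- size %/% 2L
  if (size < 1) {
    ss_abort(
      "input_size too small for the conv stack (each layer halves the map)",
      class = "seedstage_config_error"
    )
  }
  structure(
    list(
      arch = arch, input_size = as.integer(input_size),
      channels = as.integer(channels),
      conv_filters = as.integer(conv_filters), kernel = as.integer(kernel),
      fc_units = as.integer(fc_units), dropout = dropout,
      lstm_units = as.integer(lstm_units),
      convlstm_filters = as.integer(convlstm_filters),
      convlstm_kernel = as.integer(convlstm_kernel),
      n_classes = as.integer(n_classes), class_labels = class_labels,
      peephole_output = peephole_output,
      final_map = as.integer(size)
    ),
    class = "network_spec"
  )
}

#' Build an initialised network from a specification
#'
#' Allocates all weights (uniform fan-in initialisation, seed-controlled)
#' and precomputes the im2col geometry of every convolution, so that
#' [train_model()] and [predict_frames()] are pure functions of the model
#' object.
#'
#' @param spec a [network_spec()].
#' @param seed integer seed fixing the initialisation.
#' @return An object of class `stage_model`.
#' @examples
#' m <- build_network(network_spec("cnn", input_size = 32,
#'                                 conv_filters = c(8, 8),
#'                                 fc_units = 16), seed = 1)
#' n_parameters(m)
#' @export
build_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  k <- spec$kernel
  geoms <- list()
  params <- list()
  h <- spec$input_size
  cin <- spec$channels
  for (l in seq_along(spec$conv_filters)) {
    cout <- spec$conv_filters[l]
    cg <- conv_geom(h, h, cin, cout, k)
    pg <- pool_geom(h, h, cout)
    geoms[[l]] <- list(conv = cg, pool = pg)
    params[[paste0("conv", l, "_w")]] <-
      init_mat(k * k * cin, cout, k * k * cin)
    params[[paste0("conv", l, "_b")]] <- numeric(cout)
    h <- h %/% 2L
    cin <- cout
  }
  map_ch <- cin
  feat <- h * h * map_ch

  head_in <- feat
  if (spec$arch == "cnn_lstm") {
    params <- c(params, prefix_names(
      init_lstm_weights(feat, spec$lstm_units), "lstm_"
    ))
    head_in <- spec$lstm_units
  } else if (spec$arch == "convlstm") {
    params <- c(params, prefix_names(
      init_convlstm_weights(c(h, h), map_ch, spec$convlstm_filters,
                            spec$convlstm_kernel), "clstm_"
    ))
    geoms$clstm <- list(
      x = conv_geom(h, h, map_ch, spec$convlstm_filters,
                    spec$convlstm_kernel),
      h = conv_geom(h, h, spec$convlstm_filters, spec$convlstm_filters,
                    spec$convlstm_kernel),
      dhw = c(h, h)
    )
    head_in <- h * h * spec$convlstm_filters
  }
  params$fc1_w <- init_mat(head_in, spec$fc_units, head_in)
  params$fc1_b <- numeric(spec$fc_units)
  params$out_w <- init_mat(spec$fc_units, spec$n_classes, spec$fc_units)
  params$out_b <- numeric(spec$n_classes)

  structure(
    list(
      spec = spec, params = params, geoms = geoms,
      feat_dim = feat, map_dim = c(h, h, map_ch), head_in = head_in,
      classes = spec$class_labels, seed = seed, history = NULL
    ),
    class = "stage_model"
  )
}

prefix_names <- function(x, prefix) setNames(x, paste0(prefix, names(x)))
strip_prefix <- function(params, prefix) {
  sel <- startsWith(names(params), prefix)
  setNames(params[sel], sub(prefix, "", names(params)[sel], fixed = TRUE))
}

#' @export
print.stage_model <- function(x, ...) {
  cat(sprintf(
    "<stage_model> arch=%s input=%dx%dx%d classes=[%s] parameters=%s\n",
    x$spec$arch, x$spec$input_size, x$spec$input_size, x$spec$channels,
    paste(x$classes, collapse = ","), format(n_parameters(x), big.mark = ",")
  ))
  invisible(x)
}

#' Total number of trainable parameters
#' @param model a `stage_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) sum(vapply(model$params, length, 1L))

# ---- shared forward pieces --------------------------------------------------

# one image through the conv stack; x: vector (h*w*channels)
conv_stack_fwd <- function(x, params, geoms, keep_cache = FALSE) {
  n_layers <- sum(startsWith(names(params), "conv") &
                    endsWith(names(params), "_w"))
  cache <- if (keep_cache) vector("list", n_layers) else NULL
  for (l in seq_len(n_layers)) {
    g <- geoms[[l]]
    z <- conv_forward(x, params[[paste0("conv", l, "_w")]],
                      params[[paste0("conv", l, "_b")]], g$conv)
    mask <- z > 0
    a <- z * mask
    pl <- pool_forward(a, g$pool)
    if (keep_cache) cache[[l]] <- list(x = x, mask = mask, win = pl$win)
    x <- as.vector(pl$out)
  }
  list(out = x, cache = cache)
}

# backward through the conv stack, accumulating into `grads` (an env-free
# list returned updated); dflat: gradient on the flattened final output.
# `wf` holds per-layer flipped kernels (precompute once per mini-batch with
# conv_stack_flips() — flipping is weight-only work shared by all images).
conv_stack_bwd <- function(dflat, cache, params, geoms, grads, wf = NULL) {
  n_layers <- length(cache)
  d <- dflat
  for (l in rev(seq_len(n_layers))) {
    g <- geoms[[l]]
    dmat <- d
    dim(dmat) <- c(g$pool$h2 * g$pool$w2, g$pool$channels)
    da <- pool_backward(dmat, cache[[l]]$win, g$pool)
    dz <- da * cache[[l]]$mask
    pg <- conv_backward_params(dz, cache[[l]]$x, g$conv)
    wn <- paste0("conv", l, "_w")
    bn <- paste0("conv", l, "_b")
    grads[[wn]] <- grads[[wn]] + pg$dw
    grads[[bn]] <- grads[[bn]] + pg$db
    if (l > 1) {
      d <- as.vector(conv_backward_input(dz, params[[wn]], g$conv,
                                         wf = wf[[l]]))
    }
  }
  grads
}

conv_stack_flips <- function(params, geoms) {
  n_layers <- sum(startsWith(names(params), "conv") &
                    endsWith(names(params), "_w"))
  wf <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    if (l > 1) {
      wf[[l]] <- flip_weights(params[[paste0("conv", l, "_w")]],
                              geoms[[l]]$conv$flip)
    }
  }
  wf
}

# classification head: fc1 -> relu -> (dropout) -> out; x: head_in x N
head_fwd <- function(x, params, dropout = 0, training = FALSE) {
  z1 <- dense_forward(x, params$fc1_w, params$fc1_b)
  mask1 <- z1 > 0
  a1 <- z1 * mask1
  dmask <- NULL
  if (training && dropout > 0) {
    dmask <- matrix(
      rbinom(length(a1), 1, 1 - dropout) / (1 - dropout),
      nrow(a1), ncol(a1)
    )
    a1 <- a1 * dmask
  }
  z2 <- dense_forward(a1, params$out_w, params$out_b)
  list(z = z2, cache = list(x = x, mask1 = mask1, a1 = a1, dmask = dmask))
}

head_bwd <- function(dz, cache, params, grads) {
  d2 <- dense_backward(dz, cache$a1, params$out_w)
  grads$out_w <- grads$out_w + d2$dw
  grads$out_b <- grads$out_b + d2$db
  da1 <- d2$dx
  if (!is.null(cache$dmask)) da1 <- da1 * cache$dmask
  dz1 <- da1 * cache$mask1
  d1 <- dense_backward(dz1, cache$x, params$fc1_w)
  grads$fc1_w <- grads$fc1_w + d1$dw
  grads$fc1_b <- grads$fc1_b + d1$db
  list(grads = grads, dx = d1$dx)
}

# ---- training ---------------------------------------------------------------

#' Training configuration
#'
#' @param epochs passes over the training data (0 = no-op training).
#' @param batch_size mini-batch size for memoryless CNNs.
#' @param learning_rate Adam learning rate (default 0.001).
#' @param seq_len chunk length for temporal models: sequences are cut into
#'   chunks of this many frames for backpropagation through time, each
#'   starting from a zero state. Inference always runs full sequences.
#' @param clip_norm gradient clipping: per-update global L2 norm ceiling
#'   (the standard stabiliser for backpropagation through time; also
#'   applied, harmlessly, to memoryless models). `Inf` disables.
#' @param carry_state truncated-BPTT state carryover: when `TRUE`, the
#'   chunks of one sequence are visited in order and the recurrent state is
#'   carried (as a constant) from chunk to chunk, matching the
#'   full-sequence inference state distribution; when `FALSE` (default)
#'   every chunk starts from a zero state and chunks are shuffled freely.
#' @param seed seed fixing shuffling and dropout.
#' @param verbose print per-epoch losses.
#' @return List of class `training_config`.
#' @export
training_config <- function(epochs = 5, batch_size = 32,
                            learning_rate = 0.001, seq_len = 32,
                            clip_norm = 5, carry_state = FALSE,
                            seed = 1L, verbose = FALSE) {
  if (learning_rate <= 0) {
    ss_abort("learning_rate must be positive",
      class = "seedstage_config_error"
    )
  }
  structure(
    list(
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      learning_rate = learning_rate, seq_len = as.integer(seq_len),
      clip_norm = clip_norm, carry_state = isTRUE(carry_state),
      seed = as.integer(seed), verbose = isTRUE(verbose)
    ),
    class = "training_config"
  )
}

clip_gradients <- function(grads, clip_norm) {
  if (!is.finite(clip_norm)) {
    return(grads)
  }
  total <- sqrt(sum(vapply(grads, function(g) sum(g * g), 1)))
  if (total > clip_norm) {
    grads <- lapply(grads, function(g) g * (clip_norm / total))
  }
  grads
}

#' Train a stage-classification model
#'
#' Minimises the empirical cross-entropy risk over the labelled crops with
#' the Adam optimiser. Memoryless CNNs are trained on shuffled mini-batches
#' of independent frames; temporal models (CNN-LSTM, ConvLSTM) are trained
#' by backpropagation through time on fixed-length chunks of per-pot frame
#' sequences, each chunk starting from a zero state. Fully reproducible
#' given `config$seed`.
#'
#' @param data tibble with columns `image` (list of `s x s x 3` arrays in
#'   \[0, 1\]) and `stage` (labels among the model's classes); temporal
#'   architectures additionally need `pot` (sequence id) and `frame`
#'   (ordering within the sequence).
#' @param model a `stage_model` from [build_network()].
#' @param config a [training_config()].
#' @return The trained model; `$history` holds a tibble of per-epoch mean
#'   losses.
#' @export
train_model <- function(data, model, config = training_config()) {
  stopifnot(inherits(model, "stage_model"))
  if (nrow(data) == 0) {
    ss_abort("training data is empty", class = "seedstage_config_error")
  }
  labels <- as.character(data$stage)
  bad <- setdiff(unique(labels), model$classes)
  if (length(bad)) {
    ss_abort(
      paste0("labels outside the model's classes: ",
             paste(bad, collapse = ", ")),
      class = "seedstage_config_error"
    )
  }
  missing_cls <- setdiff(model$classes, unique(labels))
  if (length(missing_cls)) {
    warn(paste0("class(es) absent from training labels: ",
                paste(missing_cls, collapse = ", ")))
  }
  y <- match(labels, model$classes)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  state <- adam_state(model$params)
  history <- numeric(config$epochs)
  temporal <- model$spec$arch %in% c("cnn_lstm", "convlstm")

  if (!temporal) {
    n <- nrow(data)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        res <- cnn_batch_grad(model, data$image[idx], y[idx], config)
        if (!is.finite(res$loss)) {
          ss_abort(sprintf("loss is not finite (epoch %d); try a lower %s",
                           ep, "learning rate"),
            class = "seedstage_numeric_error"
          )
        }
        up <- adam_step(model$params,
                        clip_gradients(res$grads, config$clip_norm), state,
                        config$learning_rate)
        model$params <- up$params
        state <- up$state
        losses <- c(losses, res$loss)
      }
      history[ep] <- mean(losses)
      if (config$verbose) {
        message(sprintf("epoch %d: loss %.4f", ep, history[ep]))
      }
    }
  } else {
    if (!all(c("pot", "frame") %in% names(data))) {
      ss_abort("temporal models need `pot` and `frame` columns",
        class = "seedstage_config_error"
      )
    }
    data <- dplyr::arrange(data, .data$pot, .data$frame)
    y <- match(as.character(data$stage), model$classes)
    pots <- unique(data$pot)
    pot_chunks <- lapply(pots, function(p) {
      make_chunks(data$pot[data$pot == p], config$seq_len) |>
        lapply(function(i) which(data$pot == p)[i])
    })
    all_chunks <- unlist(pot_chunks, recursive = FALSE)
    for (ep in seq_len(config$epochs)) {
      losses <- c()
      step <- function(idx, rstate) {
        res <- seq_chunk_grad(model, data$image[idx], y[idx], config,
                              state = rstate)
        if (!is.finite(res$loss)) {
          ss_abort(sprintf("loss is not finite (epoch %d)", ep),
            class = "seedstage_numeric_error"
          )
        }
        up <- adam_step(model$params,
                        clip_gradients(res$grads, config$clip_norm), state,
                        config$learning_rate)
        model$params <<- up$params
        state <<- up$state
        losses <<- c(losses, res$loss)
        res$state
      }
      if (config$carry_state) {
        # visit each sequence's chunks in order, carrying the recurrent
        # state across chunk boundaries; sequences in random order
        for (pi in sample.int(length(pot_chunks))) {
          rstate <- NULL
          for (idx in pot_chunks[[pi]]) {
            rstate <- step(idx, rstate)
          }
        }
      } else {
        for (ci in sample.int(length(all_chunks))) {
          step(all_chunks[[ci]], NULL)
        }
      }
      history[ep] <- mean(losses)
      if (config$verbose) {
        message(sprintf("epoch %d: loss %.4f", ep, history[ep]))
      }
    }
  }
  model$history <- tibble(epoch = seq_len(config$epochs), loss = history)
  model
}

make_chunks <- function(pot, seq_len) {
  chunks <- list()
  for (p in unique(pot)) {
    rows <- which(pot == p)
    starts <- seq(1, length(rows), by = seq_len)
    for (s in starts) {
      chunks[[length(chunks) + 1]] <- rows[s:min(s + seq_len - 1,
                                                 length(rows))]
    }
  }
  chunks
}

# loss + gradients for one mini-batch of independent frames (memoryless CNN)
cnn_batch_grad <- function(model, images, y, config) {
  nb <- length(images)
  feats <- matrix(0, model$feat_dim, nb)
  caches <- vector("list", nb)
  for (i in seq_len(nb)) {
    fw <- conv_stack_fwd(as.vector(images[[i]]), model$params, model$geoms,
                         keep_cache = TRUE)
    feats[, i] <- fw$out
    caches[[i]] <- fw$cache
  }
  hd <- head_fwd(feats, model$params, model$spec$dropout, training = TRUE)
  sm <- softmax_xent(hd$z, y)
  grads <- zero_grads(model$params)
  hb <- head_bwd(sm$dz, hd$cache, model$params, grads)
  grads <- hb$grads
  wf <- conv_stack_flips(model$params, model$geoms)
  for (i in seq_len(nb)) {
    grads <- conv_stack_bwd(hb$dx[, i], caches[[i]], model$params,
                            model$geoms, grads, wf = wf)
  }
  list(loss = sm$loss, grads = grads)
}

# loss + gradients for one BPTT chunk (CNN-LSTM / ConvLSTM); `state` is the
# recurrent state carried from the previous chunk of the same sequence
# (treated as a constant for the gradient), NULL for a zero start
seq_chunk_grad <- function(model, images, y, config, state = NULL) {
  tt <- length(images)
  feats <- matrix(0, model$feat_dim, tt)
  caches <- vector("list", tt)
  for (t in seq_len(tt)) {
    fw <- conv_stack_fwd(as.vector(images[[t]]), model$params, model$geoms,
                         keep_cache = TRUE)
    feats[, t] <- fw$out
    caches[[t]] <- fw$cache
  }
  grads <- zero_grads(model$params)
  peep <- model$spec$peephole_output

  if (model$spec$arch == "cnn_lstm") {
    lw <- strip_prefix(model$params, "lstm_")
    lf <- lstm_forward(feats, lw, peep, h0 = state$h, c0 = state$c)
    hd <- head_fwd(lf$h, model$params, model$spec$dropout, training = TRUE)
    sm <- softmax_xent(hd$z, y)
    hb <- head_bwd(sm$dz, hd$cache, model$params, grads)
    grads <- hb$grads
    lb <- lstm_backward(hb$dx, feats, lw, lf$cache, peep)
    for (nm in names(lb$grads)) {
      grads[[paste0("lstm_", nm)]] <- grads[[paste0("lstm_", nm)]] +
        lb$grads[[nm]]
    }
    dfeats <- lb$dx
    out_state <- list(h = lf$h[, tt], c = lf$cache[[tt]]$st$c)
  } else {
    cw <- strip_prefix(model$params, "clstm_")
    gg <- model$geoms$clstm
    np <- prod(gg$dhw)
    ch <- model$map_dim[3]
    xs <- lapply(seq_len(tt), function(t) matrix(feats[, t], np, ch))
    cf <- convlstm_forward(xs, cw, gg, gg$dhw, peep,
                           h0 = state$h, c0 = state$c)
    hmat <- vapply(cf$h, as.vector, numeric(model$head_in))
    hd <- head_fwd(hmat, model$params, model$spec$dropout, training = TRUE)
    sm <- softmax_xent(hd$z, y)
    hb <- head_bwd(sm$dz, hd$cache, model$params, grads)
    grads <- hb$grads
    dh <- lapply(seq_len(tt), function(t) {
      matrix(hb$dx[, t], np, ncol(cw$W_xi))
    })
    cb <- convlstm_backward(dh, xs, cw, cf$cache, gg, gg$dhw, peep)
    for (nm in names(cb$grads)) {
      grads[[paste0("clstm_", nm)]] <- grads[[paste0("clstm_", nm)]] +
        cb$grads[[nm]]
    }
    dfeats <- vapply(cb$dx, as.vector, numeric(model$feat_dim))
    out_state <- list(h = cf$h[[tt]], c = cf$cache[[tt]]$st$c)
  }
  wf <- conv_stack_flips(model$params, model$geoms)
  for (t in seq_len(tt)) {
    grads <- conv_stack_bwd(dfeats[, t], caches[[t]], model$params,
                            model$geoms, grads, wf = wf)
  }
  list(loss = sm$loss, grads = grads, state = out_state)
}

# ---- prediction -------------------------------------------------------------

#' Score a sequence of pot crops
#'
#' Memoryless CNNs score every frame independently; temporal models consume
#' the frames in order with the recurrent state initialised to zero at the
#' start of the sequence. Dropout is disabled at inference.
#'
#' @param model a trained `stage_model`.
#' @param images list of `s x s x 3` arrays (one pot's frame sequence, in
#'   temporal order) or a tibble with an `image` list-column ordered by
#'   frame.
#' @return A `prediction_trace` tibble: `frame`, one probability column
#'   `p_<class>` per model class (each row sums to 1), and `label`
#'   (ordered stage factor of the argmax class).
#' @export
predict_frames <- function(model, images) {
  stopifnot(inherits(model, "stage_model"))
  if (is.data.frame(images)) images <- images$image
  tt <- length(images)
  if (tt == 0) {
    ss_abort("empty frame sequence", class = "seedstage_config_error")
  }
  feats <- matrix(0, model$feat_dim, tt)
  for (t in seq_len(tt)) {
    feats[, t] <- conv_stack_fwd(as.vector(images[[t]]), model$params,
                                 model$geoms)$out
  }
  peep <- model$spec$peephole_output
  if (model$spec$arch == "cnn_lstm") {
    lw <- strip_prefix(model$params, "lstm_")
    feats <- lstm_forward(feats, lw, peep)$h
  } else if (model$spec$arch == "convlstm") {
    cw <- strip_prefix(model$params, "clstm_")
    gg <- model$geoms$clstm
    np <- prod(gg$dhw)
    xs <- lapply(seq_len(tt), function(t) {
      matrix(feats[, t], np, model$map_dim[3])
    })
    cf <- convlstm_forward(xs, cw, gg, gg$dhw, peep)
    feats <- vapply(cf$h, as.vector, numeric(model$head_in))
  }
  z <- head_fwd(feats, model$params)$z
  p <- softmax_cols(z)
  new_trace(t(p), model$classes)
}

new_trace <- function(probs, classes, frame = seq_len(nrow(probs))) {
  colnames(probs) <- paste0("p_", tolower(classes))
  out <- as_tibble(probs)
  out <- dplyr::mutate(out,
    frame = frame,
    label = stage_factor(classes[max.col(probs, ties.method = "first")])
  )
  out <- dplyr::relocate(out, "frame")
  class(out) <- c("prediction_trace", class(out))
  out
}

#' Chained prediction with three binary CNNs
#'
#' Implements the ontology-aware chained scheme: scanning a pot's frame
#' sequence, model `m1` (Soil vs FA) is applied until it first detects FA;
#' from that frame on `m2` (FA vs OC) takes over, then `m3` (OC vs FL)
#' after the first OC; after `m3` first detects FL all remaining frames are
#' labelled FL. At a hand-over frame the incoming model re-scores that
#' frame (detections may cascade within a single frame). Already-emitted
#' labels are never revised, and the emitted sequence is non-decreasing in
#' the stage order by construction.
#'
#' @param m1,m2,m3 binary `stage_model`s with class pairs (Soil, FA),
#'   (FA, OC) and (OC, FL).
#' @param images list of crop arrays in temporal order.
#' @return A `prediction_trace` tibble with 4-class probability columns
#'   (the active binary model's probabilities in its two slots, zero
#'   elsewhere; 1 on FL once the chain has terminated).
#' @export
chained_predict <- function(m1, m2, m3, images) {
  models <- list(m1, m2, m3)
  pairs <- list(c("Soil", "FA"), c("FA", "OC"), c("OC", "FL"))
  for (i in 1:3) {
    if (!identical(models[[i]]$classes, pairs[[i]])) {
      ss_abort(sprintf(
        "model %d must have classes (%s)", i,
        paste(pairs[[i]], collapse = ", ")
      ), class = "seedstage_config_error")
    }
  }
  if (is.data.frame(images)) images <- images$image
  tt <- length(images)
  if (tt == 0) {
    ss_abort("empty frame sequence", class = "seedstage_config_error")
  }
  probs <- matrix(0, tt, 4, dimnames = list(NULL, stage_levels()))
  active <- 1L # 1..3 = model index, 4 = terminal FL
  for (t in seq_len(tt)) {
    repeat {
      if (active == 4L) {
        probs[t, "FL"] <- 1
        break
      }
      mdl <- models[[active]]
      tr <- predict_frames(mdl, images[t])
      p2 <- as.numeric(tr[1, paste0("p_", tolower(mdl$classes))])
      probs[t, ] <- 0
      probs[t, mdl$classes] <- p2
      later <- p2[2] >= p2[1]
      if (later) {
        active <- active + 1L
        if (active < 4L) next # cascade: re-score this frame with the next model
        if (active == 4L) {
          # m3 detected FL: this frame keeps m3's probabilities
          break
        }
      }
      break
    }
  }
  new_trace(probs, stage_levels())
}
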
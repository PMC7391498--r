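# Temporal post-processing of predicted stage sequences: ordinal median
# smoothing over a sliding window plus enforcement of the developmental
# ontology (stages never regress).

#' Smoothing configuration
#'
#' @param window_n sliding window length in frames (default 4; at the
#'   15-minute cadence 4 frames correspond to one hour of observation).
#' @param enforce_ontology clamp the smoothed sequence to be non-decreasing
#'   (default `TRUE`).
#' @param align `"centered"` (default): the window is centred on the
#'   current frame — the standard median-denoising placement, which leaves
#'   clean monotone transitions where they are and makes post-processing
#'   idempotent; `"trailing"`: the window ends at the current frame (the
#'   label is revised from its recent history only), at the cost of a
#'   systematic floor(n/2)-frame detection delay.
#' @return List of class `smoothing_config`.
#' @export
smoothing_config <- function(window_n = 4, enforce_ontology = TRUE,
                             align = c("centered", "trailing")) {
  align <- match.arg(align)
  if (window_n < 1) {
    ss_abort("window_n must be >= 1", class = "seedstage_config_error")
  }
  structure(
    list(window_n = as.integer(window_n),
         enforce_ontology = isTRUE(enforce_ontology), align = align),
    class = "smoothing_config"
  )
}

#' Ordinal median smoothing of a stage-label sequence
#'
#' Majority voting by the median of classes: each position is replaced by
#' the `floor((n+1)/2)`-th smallest ordinal label in its window of `n`
#' consecutive labels (the lower median — no averaging of ordinal codes,
#' so the output is always a valid stage). Windows are centred by default
#' and truncated at the sequence boundaries; output length equals input
#' length.
#'
#' @param labels stage labels (factor, names or ordinal codes 0..3).
#' @param n window length in frames.
#' @param align `"centered"` or `"trailing"` window placement.
#' @return Ordered stage factor of the same length.
#' @examples
#' median_smooth(c("FA", "FA", "OC", "FA"), n = 4, align = "trailing")
#' @export
median_smooth <- function(labels, n = 4, align = c("centered", "trailing")) {
  align <- match.arg(align)
  if (n < 1) {
    ss_abort("window length n must be >= 1", class = "seedstage_config_error")
  }
  code <- stage_code(labels)
  tt <- length(code)
  if (tt == 0) {
    ss_abort("label sequence is empty", class = "seedstage_config_error")
  }
  out <- integer(tt)
  for (t in seq_len(tt)) {
    if (align == "trailing") {
      lo <- max(1L, t - n + 1L)
      win <- code[lo:t]
    } else {
      half <- (n - 1L) %/% 2L
      lo <- max(1L, t - half)
      hi <- min(tt, t - half + n - 1L)
      win <- code[lo:hi]
    }
    m <- length(win)
    out[t] <- sort(win)[(m + 1L) %/% 2L]
  }
  stage_factor(out)
}

#' Clamp a stage sequence to the developmental ontology
#'
#' Stages occur in a fixed order and never regress; apparent regressions
#' (for instance OC predicted after the first leaf has grown out of the
#' crop frame, leaving only cotyledons visible) are clamped by taking the
#' running maximum of the ordinal codes, so the stage is kept at the
#' highest level reached.
#'
#' @param labels stage labels (factor, names or ordinal codes).
#' @return Ordered stage factor, non-decreasing, pointwise >= the input.
#' @examples
#' enforce_monotone(c("Soil", "FA", "Soil", "OC", "FA"))
#' @export
enforce_monotone <- function(labels) {
  code <- stage_code(labels)
  if (length(code) == 0) {
    ss_abort("label sequence is empty", class = "seedstage_config_error")
  }
  stage_factor(cummax(code))
}

#' Post-process a prediction trace
#'
#' Applies [median_smooth()] and then (if enabled) [enforce_monotone()] to
#' the trace's hard labels; the per-frame probability columns are carried
#' through unchanged. Idempotent: post-processing an already post-processed
#' trace changes nothing.
#'
#' @param trace a `prediction_trace` tibble from [predict_frames()] (any
#'   tibble with `frame` and `label` columns works).
#' @param config a [smoothing_config()].
#' @return The trace with smoothed labels.
#' @export
postprocess <- function(trace, config = smoothing_config()) {
  stopifnot(inherits(config, "smoothing_config"))
  lab <- median_smooth(trace$label, config$window_n, config$align)
  if (config$enforce_ontology) lab <- enforce_monotone(lab)
  trace$label <- lab
  trace
}

#' Sweep the smoothing window size against ground truth
#'
#' For each candidate window length, post-processes every trace and scores
#' frame accuracy against the aligned truth labels; returns the accuracy
#' curve and the smallest window attaining the maximum.
#'
#' @param traces list of `prediction_trace` tibbles (one per pot).
#' @param truth list of matching ground-truth label vectors (same lengths,
#'   same order).
#' @param n_range window lengths to evaluate (default 1..10).
#' @param config base [smoothing_config()] whose `window_n` is swept.
#' @return List of class `window_sweep`: `curve` (tibble `window_n,
#'   accuracy`) and `best_n`.
#' @export
sweep_window_size <- function(traces, truth, n_range = 1:10,
                              config = smoothing_config()) {
  if (length(traces) != length(truth)) {
    ss_abort("traces and truth must have the same length",
      class = "seedstage_config_error"
    )
  }
  for (i in seq_along(traces)) {
    if (nrow(traces[[i]]) != length(truth[[i]])) {
      ss_abort(sprintf("trace %d and its truth are misaligned", i),
        class = "seedstage_config_error"
      )
    }
  }
  acc <- vapply(n_range, function(n) {
    cfg <- config
    cfg$window_n <- as.integer(n)
    hits <- 0L
    total <- 0L
    for (i in seq_along(traces)) {
      sm <- postprocess(traces[[i]], cfg)
      hits <- hits + sum(stage_code(sm$label) == stage_code(truth[[i]]))
      total <- total + length(truth[[i]])
    }
    hits / total
  }, numeric(1))
  curve <- tibble(window_n = as.integer(n_range), accuracy = acc)
  best_n <- curve$window_n[which.max(curve$accuracy)] # smallest tie wins
  structure(list(curve = curve, best_n = best_n), class = "window_sweep")
}

#' @export
print.window_sweep <- function(x, ...) {
  cat(sprintf("<window_sweep> best window = %d frames (accuracy %.4f)\n",
              x$best_n, max(x$curve$accuracy)))
  invisible(x)
}
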
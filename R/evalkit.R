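# Evaluation: confusion matrices and the standard one-vs-rest metrics
# (accuracy, error, sensitivity, specificity, precision, false positive
# rate) plus per-class F1.

#' Confusion matrix of predicted vs true stage labels
#'
#' @param truth,pred equal-length stage label vectors (factors, names or
#'   ordinal codes).
#' @return A `stage_confusion` object: 4 x 4 integer matrix with rows =
#'   true classes and columns = predicted classes, in stage order.
#' @examples
#' cm <- confusion_matrix(c("Soil", "FA", "FA"), c("Soil", "FA", "OC"))
#' cm
#' @export
confusion_matrix <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    ss_abort("truth and pred must have equal length",
      class = "seedstage_config_error"
    )
  }
  t_f <- stage_factor(truth)
  p_f <- stage_factor(pred)
  m <- table(truth = t_f, pred = p_f)
  m <- matrix(as.integer(m), 4, 4,
              dimnames = list(truth = stage_levels(),
                              pred = stage_levels()))
  structure(m, class = c("stage_confusion", "matrix"))
}

#' Wrap printed confusion-matrix counts
#'
#' For evaluating published 4 x 4 confusion tables without re-running a
#' model: counts are row-major with rows = true classes.
#'
#' @param counts 4 x 4 matrix (or 16 values, row-major) of counts.
#' @return A `stage_confusion` object.
#' @export
as_stage_confusion <- function(counts) {
  m <- if (is.matrix(counts)) {
    counts
  } else {
    matrix(as.numeric(counts), 4, 4, byrow = TRUE)
  }
  storage.mode(m) <- "integer"
  dimnames(m) <- list(truth = stage_levels(), pred = stage_levels())
  if (any(m < 0)) {
    ss_abort("confusion counts must be non-negative",
      class = "seedstage_config_error"
    )
  }
  structure(m, class = c("stage_confusion", "matrix"))
}

#' @export
print.stage_confusion <- function(x, ...) {
  cat("<stage_confusion> rows = true, cols = predicted\n")
  print(unclass(x))
  invisible(x)
}

# one-vs-rest counts per class
ovr_counts <- function(cm) {
  total <- sum(cm)
  purrr::map_dfr(seq_len(4), function(i) {
    tp <- cm[i, i]
    fp <- sum(cm[-i, i])
    fn <- sum(cm[i, -i])
    tn <- total - tp - fp - fn
    tibble(stage = stage_levels()[i], tp = tp, fp = fp, fn = fn, tn = tn)
  })
}

#' Per-class F1 scores
#'
#' One-vs-rest F1 per stage, the harmonic mean of precision and recall,
#' computed in the count form `2 TP / (2 TP + FP + FN)`; 0 by convention
#' when the denominator vanishes.
#'
#' @param cm a `stage_confusion` from [confusion_matrix()] or
#'   [as_stage_confusion()].
#' @return Named numeric vector of four F1 scores in stage order.
#' @export
per_class_f1 <- function(cm) {
  stopifnot(inherits(cm, "stage_confusion"))
  ct <- ovr_counts(unclass(cm))
  denom <- 2 * ct$tp + ct$fp + ct$fn
  f1 <- ifelse(denom == 0, 0, 2 * ct$tp / denom)
  setNames(f1, ct$stage)
}

#' Summary metrics report
#'
#' Per-class one-vs-rest metrics: sensitivity (recall) `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, precision `TP/(TP+FP)`, false positive rate
#' `FP/(FP+TN)`, accuracy `(TP+TN)/total`, error `1 - accuracy`, and F1.
#' Undefined ratios (zero denominators) are reported as 0.
#'
#' @param cm a `stage_confusion`.
#' @return A `stage_metrics` tibble with one row per class; the macro
#'   summary (mean and sd across the four classes) is available via
#'   [glance.stage_metrics()].
#' @export
summary_metrics <- function(cm) {
  stopifnot(inherits(cm, "stage_confusion"))
  if (sum(cm) == 0) {
    ss_abort("confusion matrix is empty", class = "seedstage_config_error")
  }
  ct <- ovr_counts(unclass(cm))
  total <- sum(cm)
  safe <- function(num, den) ifelse(den == 0, 0, num / den)
  out <- dplyr::mutate(ct,
    accuracy = (tp + tn) / total,
    error = 1 - (tp + tn) / total,
    sensitivity = safe(tp, tp + fn),
    specificity = safe(tn, tn + fp),
    precision = safe(tp, tp + fp),
    false_positive_rate = safe(fp, fp + tn),
    f1 = safe(2 * tp, 2 * tp + fp + fn)
  )
  class(out) <- c("stage_metrics", class(out))
  attr(out, "confusion") <- cm
  out
}

#' @describeIn summary_metrics tidy() returns the per-class metrics in long
#'   form (`stage`, `metric`, `value`).
#' @param x a `stage_metrics` tibble.
#' @param ... unused.
#' @method tidy stage_metrics
#' @export
tidy.stage_metrics <- function(x, ...) {
  out <- tidyr::pivot_longer(
    dplyr::select(as_tibble(x), -"tp", -"fp", -"fn", -"tn"),
    -"stage", names_to = "metric", values_to = "value"
  )
  out
}

#' @describeIn summary_metrics glance() returns one row of macro metrics:
#'   overall frame accuracy plus mean and sd across classes of each
#'   one-vs-rest metric.
#' @method glance stage_metrics
#' @export
glance.stage_metrics <- function(x, ...) {
  cm <- attr(x, "confusion")
  metrics <- c("accuracy", "error", "sensitivity", "specificity",
               "precision", "false_positive_rate", "f1")
  means <- lapply(metrics, function(m) mean(x[[m]]))
  sds <- lapply(metrics, function(m) sd(x[[m]]))
  names(means) <- paste0("mean_", metrics)
  names(sds) <- paste0("sd_", metrics)
  dplyr::bind_cols(
    tibble(frame_accuracy = sum(diag(unclass(cm))) / sum(cm)),
    as_tibble(means), as_tibble(sds)
  )
}

#' @method tidy stage_confusion
#' @export
tidy.stage_confusion <- function(x, ...) {
  out <- expand.grid(truth = stage_levels(), pred = stage_levels(),
                     stringsAsFactors = FALSE)
  out$n <- as.vector(unclass(x)) # column-major: truth varies fastest
  as_tibble(out)
}

#' Frame accuracy of predictions against truth
#' @param truth,pred equal-length label vectors.
#' @return Proportion of frames labelled correctly.
#' @export
frame_accuracy <- function(truth, pred) {
  mean(stage_code(truth) == stage_code(pred))
}
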
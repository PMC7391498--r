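# ggplot2 methods for the package's result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   geom_text geom_step labs scale_fill_gradient theme_minimal
#'   scale_y_continuous facet_wrap geom_abline
NULL

#' @export
ggplot2::autoplot

#' Plot a prediction trace
#'
#' Class probabilities per frame as lines with the hard label overlaid as a
#' step function (on the ordinal 0..3 scale, rescaled to \[0, 1\] for
#' display).
#'
#' @param object a `prediction_trace`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot prediction_trace
#' @export
autoplot.prediction_trace <- function(object, ...) {
  probs <- tidyr::pivot_longer(
    dplyr::select(object, "frame", dplyr::starts_with("p_")),
    -"frame", names_to = "class", values_to = "probability"
  )
  probs$class <- toupper(sub("p_", "", probs$class))
  probs$class <- factor(probs$class,
                        levels = toupper(tolower(stage_levels())))
  lab <- tibble(frame = object$frame,
                ordinal = stage_code(object$label) / 3)
  ggplot(probs, aes(x = .data$frame, y = .data$probability,
                    colour = .data$class)) +
    geom_line() +
    geom_step(data = lab,
              aes(x = .data$frame, y = .data$ordinal),
              inherit.aes = FALSE, linetype = 2) +
    labs(x = "frame", y = "class probability",
         colour = "stage",
         subtitle = "dashed: hard label (Soil=0 .. FL=1 on this scale)") +
    theme_minimal()
}

#' Plot a window-size sweep
#'
#' Frame accuracy of the post-processed predictions as a function of the
#' smoothing window length, with the selected optimum marked.
#'
#' @param object a `window_sweep` from [sweep_window_size()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot window_sweep
#' @export
autoplot.window_sweep <- function(object, ...) {
  best <- object$curve[object$curve$window_n == object$best_n, ]
  ggplot(object$curve, aes(x = .data$window_n, y = .data$accuracy)) +
    geom_line() +
    geom_point() +
    geom_point(data = best, colour = "red", size = 3) +
    labs(x = "smoothing window (frames)", y = "frame accuracy") +
    theme_minimal()
}

#' Plot a confusion matrix
#'
#' @param object a `stage_confusion`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot stage_confusion
#' @export
autoplot.stage_confusion <- function(object, ...) {
  d <- tidy(object)
  d$truth <- factor(d$truth, levels = rev(stage_levels()))
  d$pred <- factor(d$pred, levels = stage_levels())
  ggplot(d, aes(x = .data$pred, y = .data$truth, fill = .data$n)) +
    geom_tile() +
    geom_text(aes(label = .data$n)) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(x = "predicted", y = "true") +
    theme_minimal()
}

#' Plot recovered vs true event frames of a pipeline run
#'
#' @param object a `pipeline_run`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot pipeline_run
#' @export
autoplot.pipeline_run <- function(object, ...) {
  d <- event_errors(object)
  d <- d[!is.na(d$predicted) & !is.na(d$true), ]
  ggplot(d, aes(x = .data$true, y = .data$predicted)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    geom_point(alpha = 0.6) +
    facet_wrap(~event) +
    labs(x = "true transition frame", y = "recovered transition frame") +
    theme_minimal()
}

# ---- broom-style methods for fitted models and runs -------------------------

#' @describeIn train_model tidy() on a trained model returns the loss
#'   history (`epoch`, `loss`).
#' @param x a `stage_model`.
#' @param ... unused.
#' @method tidy stage_model
#' @export
tidy.stage_model <- function(x, ...) {
  x$history %||% tibble(epoch = integer(), loss = numeric())
}

#' @describeIn train_model glance() returns a one-row model summary.
#' @method glance stage_model
#' @export
glance.stage_model <- function(x, ...) {
  tibble(
    arch = x$spec$arch,
    input_size = x$spec$input_size,
    n_classes = x$spec$n_classes,
    n_parameters = n_parameters(x),
    epochs_trained = if (is.null(x$history)) 0L else nrow(x$history),
    final_loss = if (is.null(x$history) || nrow(x$history) == 0) {
      NA_real_
    } else {
      x$history$loss[nrow(x$history)]
    }
  )
}

#' @describeIn run_pipeline tidy() returns the long table of per-pot event
#'   frames and errors.
#' @param x a `pipeline_run`.
#' @param ... unused.
#' @method tidy pipeline_run
#' @export
tidy.pipeline_run <- function(x, ...) event_errors(x)

#' @describeIn run_pipeline glance() returns a one-row run summary.
#' @method glance pipeline_run
#' @export
glance.pipeline_run <- function(x, ...) {
  err <- event_errors(x)
  ok <- !is.na(err$error)
  dplyr::bind_cols(
    tibble(
      arch = x$config$arch,
      pots_scored = nrow(x$timings),
      event_mae = stats::median(abs(err$error[ok]))
    ),
    glance(x$metrics)
  )
}
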
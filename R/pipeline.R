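# End-to-end orchestration: synthetic scene -> preprocessing -> model
# training -> per-frame prediction -> temporal post-processing -> metrics
# and the biological deliverable, per-pot stage-transition timings.

#' Derive per-pot event timings from a monotone label sequence
#'
#' The transition into each stage is the first frame at which the
#' (smoothed, ontology-clamped) label equals that stage; stages never
#' observed are reported as not reached (`NA`). Sequences must be
#' non-decreasing — post-process predictions first.
#'
#' @param labels stage labels, non-decreasing in the stage order.
#' @param timestamps optional POSIXct per frame; if given, wall-clock event
#'   times are reported as well (an overnight transition is timed at the
#'   first morning frame).
#' @param gap_adjacent optional logical per frame marking frames that
#'   directly follow a night gap; events on such frames may actually have
#'   happened overnight and are flagged.
#' @return One-row tibble: `frame_fa`, `frame_oc`, `frame_fl` (NA = not
#'   reached), plus `time_*` and `gap_*` columns when the optional inputs
#'   are supplied.
#' @examples
#' derive_event_times(c("Soil", "Soil", "FA", "OC", "OC", "FL"))
#' @export
derive_event_times <- function(labels, timestamps = NULL,
                               gap_adjacent = NULL) {
  code <- stage_code(labels)
  if (length(code) == 0) {
    ss_abort("label sequence is empty", class = "seedstage_config_error")
  }
  if (any(diff(code) < 0)) {
    ss_abort(
      "label sequence regresses in the stage order; run postprocess() first",
      class = "seedstage_ontology_violation"
    )
  }
  first_of <- function(s) {
    i <- which(code >= s)[1]
    if (is.na(i)) NA_integer_ else as.integer(i)
  }
  out <- tibble(
    frame_fa = first_of(1L), frame_oc = first_of(2L), frame_fl = first_of(3L)
  )
  if (!is.null(timestamps)) {
    at <- function(i) if (is.na(i)) as.POSIXct(NA) else timestamps[i]
    out$time_fa <- at(out$frame_fa)
    out$time_oc <- at(out$frame_oc)
    out$time_fl <- at(out$frame_fl)
  }
  if (!is.null(gap_adjacent)) {
    at <- function(i) if (is.na(i)) NA else gap_adjacent[i]
    out$gap_fa <- at(out$frame_fa)
    out$gap_oc <- at(out$frame_oc)
    out$gap_fl <- at(out$frame_fl)
  }
  out
}

#' Preprocess one tray frame into per-pot crops
#'
#' The full rectification workflow on a single tray image: landmark
#' detection, Fourier orientation estimation, rotation + projective
#' rectification onto the pot grid, tiling into pot crops and (optionally)
#' HSV background removal.
#'
#' @param image RGB array of the tray.
#' @param config a [scene_config()] describing the tray geometry.
#' @param remove_bg apply [remove_background()] to every crop.
#' @param angle optionally a precomputed orientation (skips estimation).
#' @return Tibble `row`, `col`, `image` (list of pot crops).
#' @export
preprocess_tray_frame <- function(image, config, remove_bg = TRUE,
                                  angle = NULL) {
  lm <- detect_landmarks(image)
  if (is.null(angle)) {
    angle <- tryCatch(
      as.numeric(estimate_tray_orientation(image)),
      seedstage_orientation_undefined = function(e) {
        warn("tray spectrum is isotropic; assuming 0 degree rotation")
        0
      }
    )
  }
  rect <- rectify_tray(image, lm, angle,
    grid_rows = config$grid_rows, grid_cols = config$grid_cols,
    pot_size_px = config$pot_size_px, margin_px = config$margin_px
  )
  pots <- extract_pots(rect, config$grid_rows, config$grid_cols,
                       config$pot_size_px)
  if (remove_bg) {
    pots$image <- purrr::map(pots$image, remove_background)
  }
  pots
}

#' Pipeline run configuration
#'
#' Bundles everything one reproducible run needs. The train/validation/test
#' split is by tray, never by pot, to avoid cross-sampling between splits:
#' with three or more trays the last tray is the test set and the
#' second-to-last the validation set; with two trays the second is the test
#' set; a single-tray scene is evaluated by resubstitution (train = test,
#' flagged in the result).
#'
#' @param scene a [scene_config()].
#' @param arch `"cnn"`, `"cnn2"` (chained binary CNNs), `"cnn_lstm"` or
#'   `"convlstm"`.
#' @param germination_prob,delay_params forwarded to the generator.
#' @param network named list of overrides for [network_spec()]
#'   (e.g. smaller `conv_filters` for quick experiments).
#' @param training a [training_config()].
#' @param smoothing a [smoothing_config()].
#' @param remove_bg apply HSV background removal before classification.
#' @param out_dir optional run directory for artifacts.
#' @param seed master seed; sub-seeds for generation, initialisation and
#'   training are derived from it.
#' @return List of class `run_config`.
#' @export
run_config <- function(scene,
                       arch = c("cnn_lstm", "cnn", "cnn2", "convlstm"),
                       germination_prob = 0.9,
                       delay_params = default_delay_params(scene),
                       network = list(),
                       training = training_config(),
                       smoothing = smoothing_config(),
                       remove_bg = TRUE,
                       out_dir = NULL,
                       seed = 1L) {
  arch <- match.arg(arch)
  stopifnot(inherits(scene, "scene_config"),
            inherits(training, "training_config"),
            inherits(smoothing, "smoothing_config"))
  structure(
    list(
      scene = scene, arch = arch, germination_prob = germination_prob,
      delay_params = delay_params, network = network, training = training,
      smoothing = smoothing, remove_bg = isTRUE(remove_bg),
      out_dir = out_dir, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

tray_split <- function(n_trays) {
  if (n_trays >= 3) {
    tibble(tray = seq_len(n_trays),
           role = c(rep("train", n_trays - 2), "validation", "test"))
  } else if (n_trays == 2) {
    tibble(tray = 1:2, role = c("train", "test"))
  } else {
    tibble(tray = 1L, role = "resubstitution")
  }
}

#' Run the full pipeline on a synthetic scene
#'
#' Generates the scene, preprocesses every tray frame into background-free
#' pot crops, trains the requested architecture on the training trays,
#' predicts every test-pot sequence, post-processes the label sequences,
#' scores them against the ground truth and derives per-pot event timings.
#'
#' @param config a [run_config()].
#' @return List of class `pipeline_run`: `split`, `dataset_summary`,
#'   `model` (or binary model list), `traces`, `confusion`, `metrics`,
#'   `timings` (per-pot predicted vs true event frames), `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  scene <- config$scene
  split <- tray_split(scene$n_trays)
  if (scene$n_trays == 1) {
    warn(paste("single-tray scene: training and evaluation share the tray",
               "(resubstitution)"))
  }

  schedule <- sample_stage_schedule(scene, config$germination_prob,
                                    config$delay_params)
  truth <- schedule_to_labels(schedule, scene)
  summary <- tibble(
    trays = scene$n_trays,
    pots_per_tray = scene$grid_rows * scene$grid_cols,
    frames = scene$frames_total,
    images = scene$n_trays * scene$grid_rows * scene$grid_cols *
      scene$frames_total
  )

  # preprocess every tray frame into crops; orientation estimated once per
  # tray (the tray does not move during the time-lapse)
  crops <- vector("list", scene$n_trays)
  for (tr in seq_len(scene$n_trays)) {
    first <- render_tray_frame(scene, schedule, 1, tray = tr)
    angle <- tryCatch(
      as.numeric(estimate_tray_orientation(first)),
      seedstage_orientation_undefined = function(e) {
        warn("tray spectrum is isotropic; assuming 0 degree rotation")
        0
      }
    )
    frames <- vector("list", scene$frames_total)
    for (fr in seq_len(scene$frames_total)) {
      img <- if (fr == 1) first else {
        render_tray_frame(scene, schedule, fr, tray = tr)
      }
      pots <- preprocess_tray_frame(img, scene, remove_bg = config$remove_bg,
                                    angle = angle)
      pots$tray <- tr
      pots$frame <- fr
      frames[[fr]] <- pots
    }
    crops[[tr]] <- dplyr::bind_rows(frames)
  }
  crops <- dplyr::bind_rows(crops)
  crops <- dplyr::left_join(crops, truth,
                            by = c("tray", "row", "col", "frame"))
  crops$pot <- paste(crops$tray, crops$row, crops$col, sep = "_")

  train_trays <- split$tray[split$role %in% c("train", "resubstitution")]
  test_trays <- split$tray[split$role %in% c("test", "resubstitution")]
  train_dat <- dplyr::filter(crops, .data$tray %in% train_trays)
  test_dat <- dplyr::filter(crops, .data$tray %in% test_trays)

  net_args <- utils::modifyList(
    list(input_size = scene$pot_size_px, n_classes = 4),
    config$network
  )
  build <- function(arch, n_classes = 4, class_labels = NULL) {
    args <- utils::modifyList(net_args, list(
      arch = arch, n_classes = n_classes, class_labels = class_labels
    ))
    do.call(network_spec, args)
  }

  if (config$arch == "cnn2") {
    pairs <- list(c("Soil", "FA"), c("FA", "OC"), c("OC", "FL"))
    models <- purrr::imap(pairs, function(pr, i) {
      dat <- dplyr::filter(train_dat, as.character(.data$stage) %in% pr)
      m <- build_network(build("cnn", 2, pr), seed = config$seed + i)
      train_model(dat, m, config$training)
    })
    model <- models
  } else {
    arch <- config$arch
    m <- build_network(build(arch), seed = config$seed)
    model <- train_model(train_dat, m, config$training)
  }

  # per-pot prediction on the evaluation tray(s)
  ts <- frame_timestamps(scene)
  gaps <- first_frame_of_day(scene)
  by_pot <- dplyr::group_split(dplyr::arrange(test_dat, .data$pot,
                                              .data$frame),
                               .data$pot)
  traces <- list()
  timings <- list()
  all_true <- c()
  all_pred <- c()
  for (dat in by_pot) {
    trace <- if (config$arch == "cnn2") {
      chained_predict(model[[1]], model[[2]], model[[3]], dat$image)
    } else {
      predict_frames(model, dat$image)
    }
    trace$frame <- dat$frame
    smooth <- postprocess(trace, config$smoothing)
    pot_id <- dat$pot[1]
    traces[[pot_id]] <- smooth
    all_true <- c(all_true, stage_code(dat$stage))
    all_pred <- c(all_pred, stage_code(smooth$label))
    ev_labels <- if (config$smoothing$enforce_ontology) {
      smooth$label
    } else {
      enforce_monotone(smooth$label) # event timing always needs monotonicity
    }
    ev <- derive_event_times(ev_labels, ts[dat$frame], gaps[dat$frame])
    true_sched <- schedule[schedule$tray == dat$tray[1] &
                             schedule$row == dat$row[1] &
                             schedule$col == dat$col[1], ]
    timings[[pot_id]] <- dplyr::bind_cols(
      tibble(tray = dat$tray[1], row = dat$row[1], col = dat$col[1]),
      ev,
      tibble(true_fa = true_sched$t_fa, true_oc = true_sched$t_oc,
             true_fl = true_sched$t_fl)
    )
  }
  timings <- dplyr::bind_rows(timings)
  cm <- confusion_matrix(all_true, all_pred)
  metrics <- summary_metrics(cm)

  result <- structure(
    list(
      split = split, dataset_summary = summary, model = model,
      schedule = schedule, traces = traces, confusion = cm,
      metrics = metrics, timings = timings, config = config
    ),
    class = "pipeline_run"
  )
  if (!is.null(config$out_dir)) write_run(result, config$out_dir)
  result
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(as.data.frame(run$timings), file.path(out_dir, "timings.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(
      confusion = unclass(run$confusion),
      per_class = as.data.frame(run$metrics),
      macro = as.data.frame(glance(run$metrics))
    ),
    file.path(out_dir, "metrics.json"),
    auto_unbox = TRUE, digits = NA
  )
  tr_dir <- file.path(out_dir, "trace")
  dir.create(tr_dir, showWarnings = FALSE)
  for (pot in names(run$traces)) {
    write.csv(as.data.frame(run$traces[[pot]]),
              file.path(tr_dir, paste0(pot, ".csv")), row.names = FALSE)
  }
  saveRDS(run$model, file.path(out_dir, "model.rds"))
  invisible(out_dir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  g <- glance(x$metrics)
  cat(sprintf(
    "<pipeline_run> arch=%s  frame accuracy %.3f  (%d pots scored)\n",
    x$config$arch, g$frame_accuracy, nrow(x$timings)
  ))
  invisible(x)
}

#' Event-frame errors of a pipeline run
#'
#' Differences between recovered and true transition frames for every pot
#' and event, long format; the basis for the parameter-recovery check.
#'
#' @param run a `pipeline_run`.
#' @return Tibble `tray, row, col, event, predicted, true, error`
#'   (`error = predicted - true`; rows with either side missing are kept
#'   with `NA`).
#' @export
event_errors <- function(run) {
  t <- run$timings
  long <- dplyr::bind_rows(
    tibble(tray = t$tray, row = t$row, col = t$col, event = "FA",
           predicted = t$frame_fa, true = t$true_fa),
    tibble(tray = t$tray, row = t$row, col = t$col, event = "OC",
           predicted = t$frame_oc, true = t$true_oc),
    tibble(tray = t$tray, row = t$row, col = t$col, event = "FL",
           predicted = t$frame_fl, true = t$true_fl)
  )
  dplyr::mutate(long, error = .data$predicted - .data$true)
}
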
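#' Generate a complete synthetic time-lapse dataset
#'
#' Samples a per-pot stage schedule, expands it into the per-frame
#' ground-truth label table, optionally renders and writes every tray frame
#' as PNG, and writes the truth table as CSV. Two runs with the same
#' configuration (same seed) produce byte-identical truth files and frames.
#'
#' Directory layout under `out_dir`:
#' \preformatted{
#'   frames/tray{T}_frame{FFFF}.png   8-bit RGB tray frames (if rendered)
#'   truth.csv                        tray,row,col,frame,timestamp_iso,stage
#'   schedule.csv                     tray,row,col,t_fa,t_oc,t_fl
#' }
#'
#' @param config a [scene_config()].
#' @param out_dir output directory; created if missing. `NULL` keeps the
#'   dataset in memory only.
#' @param germination_prob,delay_params forwarded to
#'   [sample_stage_schedule()].
#' @param write_frames render and write the PNG frames. Sizing/accounting
#'   work only needs the truth table, which is pure schedule arithmetic;
#'   set to `FALSE` to skip the (much slower) rendering.
#' @return List of class `synthetic_dataset`: `config`, `schedule`, `truth`
#'   (tibble), `frame_files` (tibble of written paths, if any).
#' @examples
#' cfg <- scene_config(grid_rows = 2, grid_cols = 2, frames_total = 10,
#'                     pot_size_px = 24, landmark_radius_px = 3)
#' ds <- generate_dataset(cfg, out_dir = NULL, write_frames = FALSE)
#' nrow(ds$truth) # 4 pots x 10 frames
#' @export
generate_dataset <- function(config,
                             out_dir = NULL,
                             germination_prob = 0.9,
                             delay_params = default_delay_params(config),
                             write_frames = TRUE) {
  schedule <- sample_stage_schedule(config, germination_prob, delay_params)
  truth <- schedule_to_labels(schedule, config)

  frame_files <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) {
      ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      if (!ok) {
        ss_abort(paste("cannot create output directory:", out_dir),
          class = "seedstage_io_error"
        )
      }
    }
    truth_out <- dplyr::mutate(truth,
      timestamp_iso = format(.data$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                             tz = "UTC"),
      stage = as.character(.data$stage)
    )
    truth_out <- dplyr::select(truth_out, "tray", "row", "col", "frame",
                               "timestamp_iso", "stage")
    write.csv(truth_out, file.path(out_dir, "truth.csv"), row.names = FALSE)
    write.csv(as.data.frame(schedule), file.path(out_dir, "schedule.csv"),
              row.names = FALSE)
    if (write_frames) {
      dir.create(file.path(out_dir, "frames"), showWarnings = FALSE)
      frame_files <- tidyr::expand_grid(
        tray = seq_len(config$n_trays),
        frame = seq_len(config$frames_total)
      )
      paths <- character(nrow(frame_files))
      for (i in seq_len(nrow(frame_files))) {
        tr <- frame_files$tray[i]
        fr <- frame_files$frame[i]
        img <- render_tray_frame(config, schedule, fr, tray = tr)
        paths[i] <- file.path(out_dir, "frames",
                              sprintf("tray%d_frame%04d.png", tr, fr))
        png::writePNG(img, paths[i])
      }
      frame_files$path <- paths
    }
  }
  structure(
    list(config = config, schedule = schedule, truth = truth,
         frame_files = frame_files),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<synthetic_dataset> %d tray(s), %d x %d pots, %d frames (%d truth rows)\n",
    cfg$n_trays, cfg$grid_rows, cfg$grid_cols, cfg$frames_total,
    nrow(x$truth)
  ))
  invisible(x)
}
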
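#' Sample per-pot stage transition schedules
#'
#' Draws, for every pot of the scene, the frame indices at which the seedling
#' enters each developmental stage: `t_fa` (emergence, Soil to FA), `t_oc`
#' (cotyledon opening) and `t_fl` (first leaf). A pot germinates with
#' probability `germination_prob`; non-germinating pots stay Soil for the
#' whole sequence (`NA` transition frames). Emergence time and the durations
#' of the FA and OC periods are drawn from gamma distributions, which is the
#' usual right-skewed model for germination/emergence delays. Transitions
#' falling beyond the end of the sequence are censored to `NA` ("never
#' reached within the time-lapse").
#'
#' @param config a [scene_config()].
#' @param germination_prob probability a pot germinates at all.
#' @param delay_params list with means and sds (in frames) of the three
#'   delays: `fa_mean`, `fa_sd` (sowing to emergence), `oc_mean`, `oc_sd`
#'   (duration of the FA period), `fl_mean`, `fl_sd` (duration of the OC
#'   period). Defaults scale with `frames_total` via
#'   [default_delay_params()].
#' @return A tibble of class `stage_schedule` with columns
#'   `tray, row, col, t_fa, t_oc, t_fl` (1-based frame indices or `NA`).
#' @examples
#' cfg <- scene_config(grid_rows = 2, grid_cols = 2, frames_total = 64,
#'                     pot_size_px = 32)
#' sample_stage_schedule(cfg)
#' @export
sample_stage_schedule <- function(config,
                                  germination_prob = 0.9,
                                  delay_params = default_delay_params(config)) {
  stopifnot(inherits(config, "scene_config"))
  if (germination_prob < 0 || germination_prob > 1) {
    ss_abort("germination_prob must lie in [0, 1]",
      class = "seedstage_config_error"
    )
  }
  p <- delay_params
  needed <- c("fa_mean", "fa_sd", "oc_mean", "oc_sd", "fl_mean", "fl_sd")
  if (!all(needed %in% names(p))) {
    ss_abort(paste("delay_params must contain", paste(needed, collapse = ", ")),
      class = "seedstage_config_error"
    )
  }
  if (any(unlist(p[c("fa_mean", "oc_mean", "fl_mean")]) <= 0)) {
    ss_abort("delay means must be positive (positive support)",
      class = "seedstage_config_error"
    )
  }
  if (any(unlist(p[c("fa_sd", "oc_sd", "fl_sd")]) < 0)) {
    ss_abort("delay sds must be non-negative",
      class = "seedstage_config_error"
    )
  }

  n_pots <- config$n_trays * config$grid_rows * config$grid_cols
  grid <- tidyr::expand_grid(
    tray = seq_len(config$n_trays),
    row = seq_len(config$grid_rows),
    col = seq_len(config$grid_cols)
  )

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  germinated <- runif(n_pots) < germination_prob
  d_fa <- rgamma_frames(n_pots, p$fa_mean, p$fa_sd)
  d_oc <- rgamma_frames(n_pots, p$oc_mean, p$oc_sd)
  d_fl <- rgamma_frames(n_pots, p$fl_mean, p$fl_sd)

  t_fa <- ifelse(germinated, d_fa, NA_integer_)
  t_oc <- t_fa + d_oc
  t_fl <- t_oc + d_fl
  censor <- function(t) ifelse(!is.na(t) & t <= config$frames_total,
                               as.integer(t), NA_integer_)
  sched <- dplyr::mutate(grid,
    t_fa = censor(t_fa), t_oc = censor(t_oc), t_fl = censor(t_fl)
  )
  structure(sched, class = c("stage_schedule", class(sched)))
}

# gamma draw rounded to whole frames, kept >= 1; sd = 0 degenerates to the
# (rounded) mean so fixed-delay schedules are expressible
rgamma_frames <- function(n, mean, sd) {
  if (sd == 0) {
    return(rep(max(1L, as.integer(round(mean))), n))
  }
  shape <- (mean / sd)^2
  pmax(1L, as.integer(round(rgamma(n, shape = shape, scale = mean / shape))))
}

#' Default delay distribution parameters, scaled to the sequence length
#'
#' Emergence around 20% of the time-lapse, cotyledons opening about 12% of
#' the sequence later and the first leaf after a further 25%, with sds of
#' roughly a quarter of each mean — so that on a 768-frame (12 day, 16 h
#' photoperiod) sequence emergence falls near day 2-3 and most pots reach FL
#' well before the end.
#'
#' @param config a [scene_config()].
#' @return Named list of gamma means and sds in frames.
#' @export
default_delay_params <- function(config) {
  t <- config$frames_total
  list(
    fa_mean = 0.20 * t, fa_sd = 0.05 * t,
    oc_mean = 0.12 * t, oc_sd = 0.03 * t,
    fl_mean = 0.25 * t, fl_sd = 0.06 * t
  )
}

#' Expand a schedule into the per-frame ground-truth label table
#'
#' The stage at frame `f` is the latest stage whose transition frame is
#' `<= f`; labels are therefore non-decreasing in time by construction.
#'
#' @param schedule a `stage_schedule` tibble from [sample_stage_schedule()].
#' @param config the [scene_config()] the schedule was sampled under.
#' @return Tibble with one row per pot x frame: `tray, row, col, frame,
#'   timestamp, stage` (ordered factor).
#' @examples
#' cfg <- scene_config(grid_rows = 1, grid_cols = 2, frames_total = 8,
#'                     pot_size_px = 32)
#' truth <- schedule_to_labels(sample_stage_schedule(cfg), cfg)
#' nrow(truth) # 2 pots x 8 frames
#' @export
schedule_to_labels <- function(schedule, config) {
  ts <- frame_timestamps(config)
  frames <- seq_len(config$frames_total)
  truth <- tidyr::expand_grid(
    dplyr::select(schedule, "tray", "row", "col", "t_fa", "t_oc", "t_fl"),
    frame = frames
  )
  truth <- dplyr::mutate(truth,
    code = stage_at(.data$frame, .data$t_fa, .data$t_oc, .data$t_fl),
    stage = stage_factor(.data$code),
    timestamp = ts[.data$frame]
  )
  dplyr::select(truth, "tray", "row", "col", "frame", "timestamp", "stage")
}

# vectorised stage lookup used by both truth expansion and the renderer
stage_at <- function(frame, t_fa, t_oc, t_fl) {
  code <- integer(length(frame))
  code[!is.na(t_fa) & frame >= t_fa] <- 1L
  code[!is.na(t_oc) & frame >= t_oc] <- 2L
  code[!is.na(t_fl) & frame >= t_fl] <- 3L
  code
}

# save/restore the global RNG state so generator calls are deterministic
# given their own seed but do not disturb the caller's RNG stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
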
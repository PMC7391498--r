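#' Noise and difficulty settings for the synthetic generator
#'
#' Controls the nuisance processes the generator emulates from real tray
#' time-lapses: circadian movement of cotyledons/leaves (periodic day/night
#' displacement and partial lobe closure that blurs the FA/OC boundary on
#' single frames), occasional overlap of a plant into a neighbouring pot,
#' rare degenerate renderings (a germinated pot drawn with a tiny plant),
#' and additive RGB pixel noise.
#'
#' The `difficulty` presets bundle these into three regimes: `"easy"`
#' (clearly separable stage shapes, negligible noise), `"medium"` (circadian
#' lobe closure and within-stage growth, so adjacent stages overlap in
#' appearance on some frames and temporal context genuinely helps) and
#' `"hard"` (stronger versions of both plus overlap between pots).
#'
#' @param difficulty one of `"easy"`, `"medium"`, `"hard"`; preset selector.
#' @param circadian_jitter_px amplitude (pixels) of the periodic plant-lobe
#'   displacement over the 24 h cycle. Also drives relative lobe closure.
#' @param overlap_prob probability that a plant lobe extends into a
#'   neighbouring pot on a given frame.
#' @param flip_prob probability that a germinated pot is rendered degenerate
#'   (tiny plant) on a given frame.
#' @param pixel_noise_sd standard deviation of additive RGB noise, on the
#'   \[0, 1\] intensity scale.
#' @param growth_within_stage fraction of final stage size a plant starts at
#'   when entering a stage (1 = full size immediately, sharpest transitions).
#' @param size_spread half-width of the per-pot size factor around 1
#'   (plants of different pots differ in overall size, so stage-wise sizes
#'   of different pots overlap — the realistic cause of boundary confusion
#'   that single frames cannot resolve).
#' @return A list of class `noise_spec`.
#' @examples
#' noise_spec("easy")
#' noise_spec("medium")$circadian_jitter_px
#' @export
noise_spec <- function(difficulty = c("easy", "medium", "hard"),
                       circadian_jitter_px = NULL,
                       overlap_prob = NULL,
                       flip_prob = NULL,
                       pixel_noise_sd = NULL,
                       growth_within_stage = NULL,
                       size_spread = NULL) {
  difficulty <- match.arg(difficulty)
  preset <- switch(difficulty,
    easy = list(
      circadian_jitter_px = 0.5, overlap_prob = 0, flip_prob = 0,
      pixel_noise_sd = 0.005, growth_within_stage = 1, size_spread = 0.05
    ),
    medium = list(
      circadian_jitter_px = 2.5, overlap_prob = 0.01, flip_prob = 0.005,
      pixel_noise_sd = 0.015, growth_within_stage = 0.7, size_spread = 0.25
    ),
    hard = list(
      circadian_jitter_px = 4, overlap_prob = 0.04, flip_prob = 0.02,
      pixel_noise_sd = 0.03, growth_within_stage = 0.5, size_spread = 0.35
    )
  )
  spec <- list(
    difficulty = difficulty,
    circadian_jitter_px = circadian_jitter_px %||% preset$circadian_jitter_px,
    overlap_prob = overlap_prob %||% preset$overlap_prob,
    flip_prob = flip_prob %||% preset$flip_prob,
    pixel_noise_sd = pixel_noise_sd %||% preset$pixel_noise_sd,
    growth_within_stage = growth_within_stage %||% preset$growth_within_stage,
    size_spread = size_spread %||% preset$size_spread
  )
  probs <- c(spec$overlap_prob, spec$flip_prob)
  if (any(probs < 0 | probs > 1)) {
    ss_abort("probabilities in a noise_spec must lie in [0, 1]",
      class = "seedstage_config_error"
    )
  }
  if (spec$circadian_jitter_px < 0 || spec$pixel_noise_sd < 0) {
    ss_abort("noise amplitudes must be non-negative",
      class = "seedstage_config_error"
    )
  }
  if (spec$growth_within_stage <= 0 || spec$growth_within_stage > 1) {
    ss_abort("growth_within_stage must lie in (0, 1]",
      class = "seedstage_config_error"
    )
  }
  if (spec$size_spread < 0 || spec$size_spread >= 1) {
    ss_abort("size_spread must lie in [0, 1)",
      class = "seedstage_config_error"
    )
  }
  structure(spec, class = "noise_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scene configuration for the synthetic tray generator
#'
#' Describes one imaging scene: how many trays, the pot grid, crop size,
#' temporal cadence and the geometry of the rendered tray. The defaults
#' mirror the acquisition the package targets: 89-pixel square pot crops,
#' 15-minute frame cadence with a 16 h photoperiod (night frames are not
#' rendered; frame indices are contiguous over the kept day frames and the
#' wall-clock timestamps carry the overnight gaps), and a tray carrying five
#' white circular landmarks (centre plus four corners) used downstream for
#' rectification.
#'
#' @param n_trays number of trays in the scene.
#' @param grid_rows,grid_cols pot grid dimensions per tray (default 10 x 20,
#'   i.e. 200 pots).
#' @param pot_size_px side of the square pot crop in pixels (default 89).
#' @param frames_total number of (day) frames per tray (default 768).
#' @param interval_min minutes between consecutive frames (default 15).
#' @param photoperiod_h hours of light per day (default 16); frames are only
#'   captured during the photoperiod.
#' @param landmark_radius_px radius of the five white landmark discs.
#' @param tray_rotation_deg in-plane rotation of the tray on the bench,
#'   degrees counter-clockwise, in (-45, 45].
#' @param margin_px width of the tray border around the pot grid; the corner
#'   landmarks sit in this border.
#' @param noise a [noise_spec()].
#' @param seed integer seed fixing every stochastic choice of the generator.
#' @param start_time POSIXct of the first frame (first light of day one).
#' @return A list of class `scene_config`.
#' @examples
#' cfg <- scene_config(n_trays = 1, grid_rows = 3, grid_cols = 4,
#'                     pot_size_px = 40, frames_total = 16)
#' cfg$grid_rows * cfg$grid_cols
#' @export
scene_config <- function(n_trays = 1,
                         grid_rows = 10,
                         grid_cols = 20,
                         pot_size_px = 89,
                         frames_total = 768,
                         interval_min = 15,
                         photoperiod_h = 16,
                         landmark_radius_px = 8,
                         tray_rotation_deg = 0,
                         margin_px = NULL,
                         noise = noise_spec("easy"),
                         seed = 1L,
                         start_time = as.POSIXct("2024-03-01 06:00:00",
                                                 tz = "UTC")) {
  margin_px <- margin_px %||% max(24L, ceiling(4 * landmark_radius_px))
  cfg <- list(
    n_trays = as.integer(n_trays),
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    pot_size_px = as.integer(pot_size_px),
    frames_total = as.integer(frames_total),
    interval_min = interval_min, photoperiod_h = photoperiod_h,
    landmark_radius_px = landmark_radius_px,
    tray_rotation_deg = tray_rotation_deg,
    margin_px = as.integer(margin_px),
    noise = noise, seed = as.integer(seed), start_time = start_time
  )
  if (cfg$n_trays < 1 || cfg$grid_rows < 1 || cfg$grid_cols < 1) {
    ss_abort("n_trays and the pot grid must be at least 1",
      class = "seedstage_config_error"
    )
  }
  if (cfg$frames_total < 1 || cfg$interval_min <= 0) {
    ss_abort("frames_total must be >= 1 and interval_min > 0",
      class = "seedstage_config_error"
    )
  }
  if (cfg$tray_rotation_deg <= -45 || cfg$tray_rotation_deg > 45) {
    ss_abort("tray_rotation_deg must lie in (-45, 45]",
      class = "seedstage_config_error"
    )
  }
  if (cfg$pot_size_px < 8) {
    ss_abort("pot_size_px is too small to render a pot",
      class = "seedstage_config_error"
    )
  }
  if (!inherits(noise, "noise_spec")) {
    ss_abort("noise must be created with noise_spec()",
      class = "seedstage_config_error"
    )
  }
  structure(cfg, class = "scene_config")
}

#' Wall-clock timestamps of the kept frames
#'
#' Night frames are discarded at acquisition, so consecutive frame indices
#' can be separated by an overnight gap; timestamps make the gap explicit.
#'
#' @param config a [scene_config()].
#' @return POSIXct vector of length `frames_total`.
#' @export
frame_timestamps <- function(config) {
  per_day <- max(1L, as.integer(floor(config$photoperiod_h * 60 /
                                        config$interval_min)))
  f <- seq_len(config$frames_total) - 1L
  day <- f %/% per_day
  within <- f %% per_day
  config$start_time + day * 86400 + within * config$interval_min * 60
}

# frames falling on the first frame of a day (event there may have happened
# overnight); frame 1 excluded since nothing precedes it
first_frame_of_day <- function(config) {
  per_day <- max(1L, as.integer(floor(config$photoperiod_h * 60 /
                                        config$interval_min)))
  f <- seq_len(config$frames_total)
  (f - 1L) %% per_day == 0L & f > 1L
}
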
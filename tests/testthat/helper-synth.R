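# shared fixtures: small scenes and schedules built in code

tiny_scene <- function(rows = 4, cols = 6, pot = 40, frames = 64,
                       rotation = 0, seed = 3,
                       noise = noise_spec("easy"), ...) {
  scene_config(
    n_trays = 1, grid_rows = rows, grid_cols = cols, pot_size_px = pot,
    frames_total = frames, landmark_radius_px = 6,
    tray_rotation_deg = rotation, noise = noise, seed = seed, ...
  )
}

tiny_schedule <- function(cfg, germination_prob = 1) {
  sample_stage_schedule(
    cfg, germination_prob,
    delay_params = list(
      fa_mean = 10, fa_sd = 3, oc_mean = 15, oc_sd = 4,
      fl_mean = 20, fl_sd = 5
    )
  )
}

# soil/plant style crop for classifier tests: green disc of radius r on a
# noisy brown background
blob_crop <- function(size = 24, r = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  img <- array(runif(size * size * 3, 0.3, 0.5), c(size, size, 3))
  if (r > 0) {
    ctr <- size / 2
    for (i in seq_len(size)) {
      for (j in seq_len(size)) {
        if ((i - ctr)^2 + (j - ctr)^2 < r^2) img[i, j, ] <- c(0.1, 0.7, 0.15)
      }
    }
  }
  img
}
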
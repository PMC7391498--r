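# Synthetic tray rendering.
#
# A tray is modelled in its own "tray frame": a rectangle of
# (grid_rows*s + 2*margin) x (grid_cols*s + 2*margin) pixels holding the pot
# grid centred with a margin border, five white landmark discs (tray centre
# plus the four margin corners) and per-pot plants drawn as green ellipse
# lobes on brown soil. The rendered canvas is the axis-aligned bounding box
# of the tray rotated by tray_rotation_deg; every pixel is mapped back into
# the tray frame (inverse rotation), where all geometry tests are cheap.

# tray-frame geometry shared by the renderer and the rectifier
tray_geometry <- function(config) {
  s <- config$pot_size_px
  m <- config$margin_px
  h_t <- config$grid_rows * s + 2 * m
  w_t <- config$grid_cols * s + 2 * m
  corners <- rbind( # tray-frame landmark centres, (x, y), continuous coords
    TL = c(m / 2, m / 2),
    TR = c(w_t - m / 2, m / 2),
    BL = c(m / 2, h_t - m / 2),
    BR = c(w_t - m / 2, h_t - m / 2)
  )
  list(
    h_t = h_t, w_t = w_t, margin = m, pot = s,
    central = c(w_t / 2, h_t / 2), corners = corners
  )
}

rotmat <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2) # CCW, y down
}

# colour constants (HSV, hue in degrees): soil brown ~20 deg, plant green
# ~110 deg; the default background-filter band [70, 160] separates them
.soil_hsv <- c(h = 20, s = 0.55, v = 0.42)
.plant_hsv <- c(h = 110, s = 0.75, v = 0.65)

hsv_rgb <- function(h_deg, s, v) {
  grDevices::col2rgb(grDevices::hsv(h_deg / 360, s, v))[, 1] / 255
}

# static per-pot attributes (plant axis angle, hue jitter, circadian phase),
# a pure function of the scene seed and tray id
pot_attributes <- function(config, tray) {
  n <- config$grid_rows * config$grid_cols
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed((config$seed * 1009 + tray * 97) %% .Machine$integer.max)
  tibble(
    row = rep(seq_len(config$grid_rows), each = config$grid_cols),
    col = rep(seq_len(config$grid_cols), config$grid_rows),
    axis_deg = runif(n, 0, 180),
    hue_jitter = runif(n, -10, 10),
    # nyctinastic rhythm is day/night-locked; pots differ by a small phase
    phase = runif(n, -0.6, 0.6),
    # per-pot plant size factor: individuals differ in overall size, so
    # stage-wise sizes of different pots overlap between adjacent stages
    size = runif(n, 1 - config$noise$size_spread,
                 1 + config$noise$size_spread)
  )
}

#' Render one synthetic tray frame
#'
#' Draws the tray at `frame_index`: brown textured soil with a visible pot
#' grid, five white landmark discs (centre + four corners), and each pot's
#' plant at its current developmental stage — nothing for Soil, one small
#' closed green blob for FA, two separated cotyledon lobes for OC, and two
#' larger lobes plus a central third lobe for FL. Circadian movement
#' displaces and partially closes the lobes as a periodic function of the
#' wall-clock hour. The whole tray is rotated by `tray_rotation_deg`.
#' Rendering is deterministic given the scene seed and the frame index.
#'
#' @param config a [scene_config()].
#' @param schedule a `stage_schedule` from [sample_stage_schedule()].
#' @param frame_index frame to render, `1..frames_total`.
#' @param tray tray id to render (schedules may cover several trays).
#' @return Numeric array `H x W x 3` (RGB in \[0, 1\]) with attributes
#'   `plant_mask` (logical `H x W`, true plant pixels),
#'   `landmarks` (tibble of true landmark centres in image coordinates) and
#'   `rotation_deg`.
#' @examples
#' cfg <- scene_config(grid_rows = 2, grid_cols = 2, pot_size_px = 24,
#'                     frames_total = 4, landmark_radius_px = 3)
#' img <- render_tray_frame(cfg, sample_stage_schedule(cfg), 1)
#' dim(img)
#' @export
render_tray_frame <- function(config, schedule, frame_index, tray = 1L) {
  stopifnot(inherits(config, "scene_config"))
  if (frame_index < 1 || frame_index > config$frames_total) {
    ss_abort("frame_index must lie in 1..frames_total",
      class = "seedstage_config_error"
    )
  }
  geom <- tray_geometry(config)
  s <- geom$pot
  m <- geom$margin
  theta <- config$tray_rotation_deg
  rot <- rotmat(theta)

  # canvas: bounding box of the rotated tray, plus a small border
  half <- abs(rot) %*% c(geom$w_t / 2, geom$h_t / 2)
  border <- 6
  wc <- 2 * ceiling(half[1]) + 2 * border
  hc <- 2 * ceiling(half[2]) + 2 * border
  if (hc * wc > 4e7) {
    ss_abort("pot grid larger than a renderable canvas",
      class = "seedstage_geometry_error"
    )
  }
  cx <- wc / 2
  cy <- hc / 2

  # inverse map every canvas pixel centre into the tray frame
  xs <- matrix(seq_len(wc) - 0.5, hc, wc, byrow = TRUE) - cx
  ys <- matrix(seq_len(hc) - 0.5, hc, wc) - cy
  inv <- rotmat(-theta)
  xt <- inv[1, 1] * xs + inv[1, 2] * ys + geom$w_t / 2
  yt <- inv[2, 1] * xs + inv[2, 2] * ys + geom$h_t / 2

  inside <- xt >= 0 & xt < geom$w_t & yt >= 0 & yt < geom$h_t

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  # static soil texture (scene-seeded, constant across frames)
  set.seed((config$seed * 2111 + tray * 13) %% .Machine$integer.max)
  texture <- matrix(runif(hc * wc, -0.04, 0.04), hc, wc)

  soil <- hsv_rgb(.soil_hsv["h"], .soil_hsv["s"], .soil_hsv["v"])
  val <- matrix(0.25, hc, wc) # bench background
  rmat <- val
  gmat <- val
  bmat <- val
  scale <- 1 + texture
  rmat[inside] <- (soil[1] * scale)[inside]
  gmat[inside] <- (soil[2] * scale)[inside]
  bmat[inside] <- (soil[3] * scale)[inside]

  # pot grid lines and tray edge (darkened); these rotate with the tray and
  # carry the spectral anisotropy the orientation estimator relies on
  in_grid <- xt >= m & xt <= m + config$grid_cols * s &
    yt >= m & yt <= m + config$grid_rows * s
  dx <- (xt - m) %% s
  dy <- (yt - m) %% s
  line <- in_grid & (pmin(dx, s - dx) < 0.8 | pmin(dy, s - dy) < 0.8)
  edge <- inside & (xt < 2 | xt > geom$w_t - 2 | yt < 2 | yt > geom$h_t - 2)
  dark <- line | edge
  rmat[dark] <- rmat[dark] * 0.55
  gmat[dark] <- gmat[dark] * 0.55
  bmat[dark] <- bmat[dark] * 0.55

  # plants: per-frame stochastic effects reseeded so the frame is a pure
  # function of (seed, tray, frame_index)
  set.seed((config$seed * 7907 + tray * 131 + frame_index) %%
             .Machine$integer.max)
  attrs <- pot_attributes(config, tray)
  sched <- dplyr::filter(schedule, .data$tray == !!tray)
  sched <- dplyr::left_join(sched, attrs, by = c("row", "col"))
  per_day <- max(1L, as.integer(floor(config$photoperiod_h * 60 /
                                        config$interval_min)))
  hour <- 6 + ((frame_index - 1L) %% per_day) * config$interval_min / 60

  plant_mask <- matrix(FALSE, hc, wc)
  noise <- config$noise
  ramp <- 0.04 * config$frames_total + 2 # frames to reach full stage size

  for (k in seq_len(nrow(sched))) {
    pot <- sched[k, ]
    stage <- stage_at(frame_index, pot$t_fa, pot$t_oc, pot$t_fl)
    if (stage == 0L) next
    t_stage <- c(pot$t_fa, pot$t_oc, pot$t_fl)[stage]
    grow <- noise$growth_within_stage +
      (1 - noise$growth_within_stage) *
        min(1, (frame_index - t_stage + 1) / ramp)
    if (noise$flip_prob > 0 && runif(1) < noise$flip_prob) grow <- grow * 0.3

    pc <- c(
      m + (pot$col - 0.5) * s, # x
      m + (pot$row - 0.5) * s # y
    )
    phi <- pot$axis_deg * pi / 180
    # cotyledons/leaves are closed around dawn and reopen over the morning;
    # the sqrt widens the closed shoulder so, at the harder settings, a
    # sizeable share of day frames shows partially folded plants
    drive <- cos(2 * pi * (hour - 7) / 24 + pot$phase)
    jit <- noise$circadian_jitter_px * drive
    closure <- min(1, noise$circadian_jitter_px / 3) * sqrt(pmax(0, drive))
    jx <- jit * cos(phi + pi / 4)
    jy <- jit * sin(phi + pi / 4)
    sep_mult <- 1 - closure
    # closing cotyledons fold up: separation shrinks and so does the
    # apparent lobe size, so a strongly closed OC/FL pot approaches the FA
    # silhouette on a single frame — resolvable only from temporal context
    lobe_scale <- 1 - 0.55 * closure

    lobes <- switch(stage,
      # FA: one small closed blob
      list(c(0, 0, 0.11, 0.085, phi)),
      # OC: two separated cotyledon lobes
      {
        d <- 0.16 * sep_mult
        list(
          c(d * cos(phi), d * sin(phi), 0.15, 0.10, phi + pi / 2),
          c(-d * cos(phi), -d * sin(phi), 0.15, 0.10, phi + pi / 2)
        )
      },
      # FL: two larger lobes plus a central third lobe
      {
        d <- 0.20 * sep_mult
        list(
          c(d * cos(phi), d * sin(phi), 0.19, 0.12, phi + pi / 2),
          c(-d * cos(phi), -d * sin(phi), 0.19, 0.12, phi + pi / 2),
          c(0.06 * cos(phi + pi / 2), 0.06 * sin(phi + pi / 2),
            0.13, 0.07, phi + pi / 2)
        )
      }
    )
    if (noise$overlap_prob > 0 && runif(1) < noise$overlap_prob) {
      l1 <- lobes[[1]]
      l1[1:2] <- l1[1:2] + 0.6 * c(cos(phi), sin(phi)) # offsets in pot units
      lobes <- c(lobes, list(l1))
    }
    col_p <- hsv_rgb(.plant_hsv["h"] + pot$hue_jitter, .plant_hsv["s"],
                     .plant_hsv["v"])
    shape_scale <- pot$size * grow * (if (stage >= 2L) lobe_scale else 1)
    for (lb in lobes) {
      mask <- ellipse_mask(
        hc, wc, xt, yt, rot, cx, cy, geom,
        xc = pc[1] + lb[1] * s + jx, yc = pc[2] + lb[2] * s + jy,
        a = max(1.2, lb[3] * s * shape_scale),
        b = max(1, lb[4] * s * shape_scale),
        ang = lb[5]
      )
      if (is.null(mask)) next
      plant_mask[mask] <- TRUE
      rmat[mask] <- col_p[1] * (1 + texture[mask])
      gmat[mask] <- col_p[2] * (1 + texture[mask])
      bmat[mask] <- col_p[3] * (1 + texture[mask])
    }
  }

  # landmarks drawn last so nothing overwrites them
  lm_xy <- rbind(center = geom$central, geom$corners)
  for (k in seq_len(nrow(lm_xy))) {
    mask <- ellipse_mask(hc, wc, xt, yt, rot, cx, cy, geom,
      xc = lm_xy[k, 1], yc = lm_xy[k, 2],
      a = config$landmark_radius_px, b = config$landmark_radius_px, ang = 0
    )
    if (is.null(mask)) next
    rmat[mask] <- 1
    gmat[mask] <- 1
    bmat[mask] <- 1
  }

  img <- array(c(rmat, gmat, bmat), dim = c(hc, wc, 3))
  if (noise$pixel_noise_sd > 0) {
    img <- img + rnorm(length(img), 0, noise$pixel_noise_sd)
  }
  img[img < 0] <- 0
  img[img > 1] <- 1

  # true landmark centres in image coordinates (for validation downstream)
  fwd <- rot %*% t(cbind(lm_xy[, 1] - geom$w_t / 2, lm_xy[, 2] - geom$h_t / 2))
  landmarks <- tibble(
    role = c("center", rownames(geom$corners)),
    x = fwd[1, ] + cx, y = fwd[2, ] + cy
  )
  attr(img, "plant_mask") <- plant_mask
  attr(img, "landmarks") <- landmarks
  attr(img, "rotation_deg") <- theta
  img
}

# logical index of pixels inside a tray-frame ellipse, evaluated only on the
# canvas bounding box of the (rotated) ellipse for speed; NULL if off-canvas
ellipse_mask <- function(hc, wc, xt, yt, rot, cx, cy, geom,
                         xc, yc, a, b, ang) {
  ctr <- rot %*% c(xc - geom$w_t / 2, yc - geom$h_t / 2)
  x0 <- ctr[1] + cx
  y0 <- ctr[2] + cy
  r <- max(a, b) + 1.5
  rows <- max(1, floor(y0 - r)):min(hc, ceiling(y0 + r))
  cols <- max(1, floor(x0 - r)):min(wc, ceiling(x0 + r))
  if (y0 + r < 1 || y0 - r > hc || x0 + r < 1 || x0 - r > wc) return(NULL)
  sx <- xt[rows, cols, drop = FALSE] - xc
  sy <- yt[rows, cols, drop = FALSE] - yc
  u <- sx * cos(ang) + sy * sin(ang)
  v <- -sx * sin(ang) + sy * cos(ang)
  hit <- (u / a)^2 + (v / b)^2 <= 1
  idx <- which(hit, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  cbind(rows[idx[, 1]], cols[idx[, 2]])
}
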
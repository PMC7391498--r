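# landmark detection, role assignment, orientation, rectification,
# pot extraction, background removal

test_that("landmarks are recovered within 2 px of the rendered centres", {
  cfg <- tiny_scene(rotation = 7)
  sch <- tiny_schedule(cfg)
  img <- render_tray_frame(cfg, sch, 40)
  lm <- detect_landmarks(img)
  expect_equal(nrow(lm), 5)
  expect_setequal(lm$role, c("center", "TL", "TR", "BL", "BR"))
  truth <- attr(img, "landmarks")
  m <- dplyr::left_join(lm, truth, by = "role", suffix = c("", "_true"))
  err <- sqrt((m$x - m$x_true)^2 + (m$y - m$y_true)^2)
  expect_lt(max(err), 2)
})

test_that("landmark recall holds across random scenes", {
  errs <- c()
  for (seed in 1:12) {
    cfg <- tiny_scene(
      rows = 3, cols = 4, pot = 24, frames = 8,
      rotation = runif(1, -12, 12), seed = seed
    )
    img <- render_tray_frame(cfg, tiny_schedule(cfg), sample(8, 1))
    lm <- detect_landmarks(img)
    truth <- attr(img, "landmarks")
    m <- dplyr::left_join(lm, truth, by = "role", suffix = c("", "_true"))
    errs <- c(errs, sqrt((m$x - m$x_true)^2 + (m$y - m$y_true)^2))
  }
  expect_lt(max(errs), 2)
})

test_that("degenerate landmark inputs raise typed errors", {
  black <- array(0, c(80, 80, 3))
  err <- expect_error(detect_landmarks(black),
                      class = "seedstage_landmarks_not_found")
  expect_equal(err$n_found, 0L)
  # five big discs plus three sub-threshold specks: specks ignored
  img <- array(0, c(120, 120, 3))
  disc <- function(y, x, r) {
    for (i in max(1, y - r):min(120, y + r)) {
      for (j in max(1, x - r):min(120, x + r)) {
        if ((i - y)^2 + (j - x)^2 <= r^2) img[i, j, ] <<- 1
      }
    }
  }
  centers <- list(c(60, 60), c(15, 15), c(15, 105), c(105, 15), c(105, 105))
  for (p in centers) disc(p[1], p[2], 6)
  for (p in list(c(40, 80), c(80, 40), c(90, 90))) disc(p[1], p[2], 2)
  lm <- detect_landmarks(img, min_area_px = 20)
  expect_equal(nrow(lm), 5)
  ctr <- lm[lm$role == "center", ]
  expect_equal(round(ctr$x), 60)
  expect_equal(round(ctr$y), 60)
})

test_that("role assignment matches quadrants and tolerates rotation", {
  pts <- tibble::tibble(
    x = c(50, 10, 90, 10, 90),
    y = c(50, 10, 10, 90, 90)
  )
  lm <- assign_landmark_roles(pts, c(50, 50))
  expect_equal(lm$role[lm$x == 10 & lm$y == 10], "TL")
  expect_equal(lm$role[lm$x == 10 & lm$y == 90], "BL")
  expect_equal(lm$role[lm$x == 90 & lm$y == 10], "TR")
  expect_equal(lm$role[lm$x == 50], "center")
  # rotate the same configuration by 10 degrees about the centre
  th <- 10 * pi / 180
  rot <- function(x, y) {
    list(
      x = cos(th) * (x - 50) - sin(th) * (y - 50) + 50,
      y = sin(th) * (x - 50) + cos(th) * (y - 50) + 50
    )
  }
  r <- rot(pts$x, pts$y)
  lm2 <- assign_landmark_roles(tibble::tibble(x = r$x, y = r$y), c(50, 50))
  expect_equal(sort(lm2$role), sort(lm$role))
  # all four corner candidates left of centre: ambiguous
  bad <- tibble::tibble(x = c(50, 10, 20, 10, 20), y = c(50, 10, 20, 80, 70))
  expect_error(assign_landmark_roles(bad, c(50, 50)),
               class = "seedstage_role_assignment_ambiguous")
})

test_that("orientation is recovered within 1 degree over +/-30 degrees", {
  cfg0 <- tiny_scene()
  sch <- tiny_schedule(cfg0)
  for (theta in c(-30, -20, -10, -3, 0, 3, 10, 20, 30)) {
    cfg <- tiny_scene(rotation = theta)
    img <- render_tray_frame(cfg, sch, 40)
    est <- estimate_tray_orientation(img)
    expect_lt(abs(as.numeric(est) - theta), 1)
  }
})

test_that("orientation folds with the 90-degree grid symmetry", {
  cfg <- tiny_scene(rows = 4, cols = 4)
  sch <- tiny_schedule(cfg)
  img <- render_tray_frame(cfg, sch, 10)
  a0 <- as.numeric(estimate_tray_orientation(img))
  rot90 <- aperm(img[, rev(seq_len(ncol(img[, , 1]))), ], c(2, 1, 3))
  a90 <- as.numeric(estimate_tray_orientation(rot90))
  expect_lt(abs(a90 - a0), 1)
  expect_error(estimate_tray_orientation(matrix(0.5, 32, 32)),
               class = "seedstage_geometry_error")
  flat <- matrix(0.5, 128, 128)
  expect_error(estimate_tray_orientation(flat),
               class = "seedstage_orientation_undefined")
})

test_that("rectification brings corner landmarks within 2 px of targets", {
  cfg <- tiny_scene(rotation = 7)
  sch <- tiny_schedule(cfg)
  img <- render_tray_frame(cfg, sch, 40)
  lm <- detect_landmarks(img)
  ang <- as.numeric(estimate_tray_orientation(img))
  rect <- rectify_tray(img, lm, ang, cfg$grid_rows, cfg$grid_cols,
                       cfg$pot_size_px, margin_px = cfg$margin_px)
  expect_equal(dim(rect), c(cfg$grid_rows * cfg$pot_size_px,
                            cfg$grid_cols * cfg$pot_size_px, 3))
  # the rectified tray must match the same scene rendered unrotated
  cfg0 <- tiny_scene(rotation = 0)
  img0 <- render_tray_frame(cfg0, sch, 40)
  lm0 <- detect_landmarks(img0)
  rect0 <- rectify_tray(img0, lm0, 0, cfg$grid_rows, cfg$grid_cols,
                        cfg$pot_size_px, margin_px = cfg$margin_px)
  # interiors of pots (avoid grid lines): compare a central block per pot
  s <- cfg$pot_size_px
  diffs <- c()
  for (r in seq_len(cfg$grid_rows)) {
    for (c in seq_len(cfg$grid_cols)) {
      rows <- ((r - 1) * s + 8):(r * s - 8)
      cols <- ((c - 1) * s + 8):(c * s - 8)
      diffs <- c(diffs, mean(abs(rect[rows, cols, ] - rect0[rows, cols, ])))
    }
  }
  expect_lt(max(diffs), 5 / 255)
  # forward-map the true corner landmarks through the same transform:
  # their targets are half a margin outside the grid corners
  expect_error(
    rectify_tray(img, lm[c(1, 2, 2, 3, 4), ], ang, 4, 6, 40),
    class = "seedstage_geometry_error"
  )
})

test_that("a straight tray rectifies to itself", {
  cfg <- tiny_scene(rotation = 0, rows = 3, cols = 3)
  sch <- tiny_schedule(cfg)
  img <- render_tray_frame(cfg, sch, 20)
  lm <- attr(img, "landmarks") # exact centres: identity transform
  class(lm) <- c("landmark_set", class(lm))
  rect <- rectify_tray(img, lm, 0, 3, 3, cfg$pot_size_px,
                       margin_px = cfg$margin_px)
  # the grid region of the source image, cropped directly
  m <- cfg$margin_px
  y0 <- round((nrow(img[, , 1]) - (3 * cfg$pot_size_px + 2 * m)) / 2)
  x0 <- round((ncol(img[, , 1]) - (3 * cfg$pot_size_px + 2 * m)) / 2)
  crop <- img[(y0 + m + 1):(y0 + m + 3 * cfg$pot_size_px),
              (x0 + m + 1):(x0 + m + 3 * cfg$pot_size_px), ]
  expect_lt(mean(abs(rect - crop)), 1 / 255)
})

test_that("pot extraction partitions the grid exactly", {
  cfg <- tiny_scene(rows = 3, cols = 4, pot = 20, frames = 4)
  img <- array(runif(60 * 80 * 3), c(60, 80, 3))
  pots <- extract_pots(img, 3, 4, 20)
  expect_equal(nrow(pots), 12)
  # coverage counting: every pixel of the grid appears in exactly one crop
  cover <- matrix(0, 60, 80)
  for (i in seq_len(nrow(pots))) {
    r <- pots$row[i]
    c <- pots$col[i]
    cover[((r - 1) * 20 + 1):(r * 20), ((c - 1) * 20 + 1):(c * 20)] <-
      cover[((r - 1) * 20 + 1):(r * 20), ((c - 1) * 20 + 1):(c * 20)] + 1
  }
  expect_true(all(cover == 1))
  # crops carry the right pixels
  expect_equal(pots$image[[1]], img[1:20, 1:20, , drop = FALSE])
  single <- extract_pots(img, 1, 1, 20)
  expect_equal(single$image[[1]], img[1:20, 1:20, , drop = FALSE])
  expect_error(extract_pots(img, 4, 4, 20),
               class = "seedstage_geometry_error")
})

test_that("HSV background filter keeps green and zeroes soil", {
  # single-pixel checks: pure green kept, brown removed
  px <- function(h, s, v) {
    array(grDevices::col2rgb(grDevices::hsv(h / 360, s, v))[, 1] / 255,
          c(1, 1, 3))
  }
  green <- remove_background(px(120, 1, 1))
  expect_equal(as.vector(attr(green, "mask")), TRUE)
  brown <- remove_background(px(20, 0.6, 0.5))
  expect_equal(as.vector(brown), c(0, 0, 0))
  expect_error(remove_background(px(120, 1, 1), hue_band = c(160, 70)),
               class = "seedstage_config_error")
})

test_that("background filter recovers the generator's plant mask", {
  cfg <- tiny_scene(rows = 2, cols = 3, pot = 40, frames = 60)
  sch <- tiny_schedule(cfg)
  img <- render_tray_frame(cfg, sch, 50)
  mask_true <- attr(img, "plant_mask")
  filt <- remove_background(img)
  mask_est <- attr(filt, "mask")
  jacc <- sum(mask_true & mask_est) / sum(mask_true | mask_est)
  expect_gte(jacc, 0.9)
  # all-soil crop comes back black
  cfg2 <- tiny_scene(rows = 1, cols = 1, pot = 30, frames = 4)
  soil <- render_tray_frame(cfg2, sample_stage_schedule(cfg2, 0), 1)
  pots <- preprocess_tray_frame(soil, cfg2, remove_bg = TRUE, angle = 0)
  crop <- pots$image[[1]]
  expect_lt(sum(attr(crop, "mask")), 10) # tolerate isolated noise pixels
  # idempotence
  twice <- remove_background(remove_background(img))
  expect_equal(as.vector(twice), as.vector(filt))
})
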
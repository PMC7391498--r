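# synthetic generator: schedules, truth expansion, rendering

test_that("stage labels form the expected ordinal scale", {
  expect_equal(stage_levels(), c("Soil", "FA", "OC", "FL"))
  f <- stage_factor(c("OC", "Soil"))
  expect_true(is.ordered(f))
  expect_true(f[1] > f[2])
  expect_equal(stage_code(c("Soil", "FA", "OC", "FL")), 0:3)
  expect_error(stage_factor("seedling"), class = "seedstage_bad_stage")
})

test_that("schedule transitions are strictly ordered for germinated pots", {
  cfg <- scene_config(
    n_trays = 1, grid_rows = 100, grid_cols = 100,
    pot_size_px = 16, frames_total = 768, seed = 9
  )
  sch <- sample_stage_schedule(cfg, germination_prob = 0.9)
  expect_equal(nrow(sch), 1e4)
  g <- dplyr::filter(sch, !is.na(t_fa))
  ok_oc <- is.na(g$t_oc) | g$t_fa < g$t_oc
  ok_fl <- is.na(g$t_fl) | (g$t_oc < g$t_fl)
  expect_true(all(ok_oc))
  expect_true(all(ok_fl, na.rm = TRUE))
  # about 10% of pots never germinate
  expect_gt(mean(is.na(sch$t_fa)), 0.05)
  expect_lt(mean(is.na(sch$t_fa)), 0.15)
})

test_that("fixed delays expand to label counts equal to window lengths", {
  cfg <- scene_config(
    n_trays = 1, grid_rows = 1, grid_cols = 1, pot_size_px = 16,
    frames_total = 768, seed = 1
  )
  sch <- sample_stage_schedule(
    cfg, 1,
    delay_params = list(
      fa_mean = 100, fa_sd = 0, oc_mean = 50, oc_sd = 0,
      fl_mean = 200, fl_sd = 0
    )
  )
  expect_equal(sch$t_fa, 100L)
  expect_equal(sch$t_oc, 150L)
  expect_equal(sch$t_fl, 350L)
  truth <- schedule_to_labels(sch, cfg)
  counts <- table(truth$stage)
  # brute-force expansion: Soil frames 1..99, FA 100..149, OC 150..349
  expect_equal(as.integer(counts), c(99L, 50L, 200L, 768L - 349L))
})

test_that("non-germinating scenes stay Soil and labels never regress", {
  cfg <- tiny_scene(rows = 2, cols = 2, pot = 16, frames = 30)
  none <- schedule_to_labels(sample_stage_schedule(cfg, 0), cfg)
  expect_true(all(none$stage == "Soil"))
  truth <- schedule_to_labels(tiny_schedule(cfg), cfg)
  for (d in dplyr::group_split(truth, row, col)) {
    expect_true(all(diff(stage_code(d$stage[order(d$frame)])) >= 0))
  }
})

test_that("dataset sizing follows trays x pots x frames exactly", {
  cfg <- tiny_scene(rows = 2, cols = 2, pot = 24, frames = 10)
  ds <- generate_dataset(cfg, out_dir = NULL, write_frames = FALSE)
  expect_equal(nrow(ds$truth), 2 * 2 * 10)
  tmp <- withr::local_tempdir()
  ds2 <- generate_dataset(cfg, out_dir = tmp, write_frames = TRUE)
  expect_length(list.files(file.path(tmp, "frames")), 10)
  expect_true(file.exists(file.path(tmp, "truth.csv")))
})

test_that("identical seeds give byte-identical truth files and renders", {
  cfg <- tiny_scene(rows = 2, cols = 3, pot = 20, frames = 6, seed = 12)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_dataset(cfg, d1, write_frames = FALSE)
  generate_dataset(cfg, d2, write_frames = FALSE)
  expect_identical(
    readBin(file.path(d1, "truth.csv"), "raw", 1e6),
    readBin(file.path(d2, "truth.csv"), "raw", 1e6)
  )
  sch <- tiny_schedule(cfg)
  expect_identical(
    render_tray_frame(cfg, sch, 3),
    render_tray_frame(cfg, sch, 3)
  )
})

test_that("rendered frames honour the stage geometry", {
  cfg <- tiny_scene(rows = 2, cols = 3, pot = 40, frames = 60, seed = 5)
  sch <- sample_stage_schedule(
    cfg, 1,
    delay_params = list(
      fa_mean = 20, fa_sd = 0, oc_mean = 15, oc_sd = 0,
      fl_mean = 15, fl_sd = 0
    )
  )
  # before any emergence: no plant pixels at all
  img0 <- render_tray_frame(cfg, sch, 5)
  expect_equal(sum(attr(img0, "plant_mask")), 0)
  # OC rendering strictly larger than FA for the same pot
  img_fa <- render_tray_frame(cfg, sch, 25) # all pots FA
  img_oc <- render_tray_frame(cfg, sch, 40) # all pots OC
  expect_gt(sum(attr(img_oc, "plant_mask")), sum(attr(img_fa, "plant_mask")))
  # exactly five bright connected components in any frame
  for (img in list(img0, img_oc)) {
    bw <- pmax(img[, , 1], img[, , 2], img[, , 3]) > 200 / 255
    lab <- EBImage::bwlabel(EBImage::Image(t(bw)))
    expect_equal(max(lab), 5)
  }
})
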
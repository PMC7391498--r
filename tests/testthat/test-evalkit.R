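# confusion matrices and derived metrics

test_that("confusion counting matches a brute-force oracle", {
  set.seed(21)
  truth <- sample(0:3, 500, replace = TRUE)
  pred <- sample(0:3, 500, replace = TRUE)
  cm <- confusion_matrix(truth, pred)
  expect_equal(sum(cm), 500)
  for (i in 0:3) {
    for (j in 0:3) {
      expect_equal(cm[i + 1, j + 1], sum(truth == i & pred == j))
    }
  }
  perfect <- confusion_matrix(truth, truth)
  expect_equal(sum(diag(unclass(perfect))), 500)
  expect_equal(sum(unclass(perfect)) - sum(diag(unclass(perfect))), 0)
  expect_error(confusion_matrix(0:1, 0:2),
               class = "seedstage_config_error")
})

test_that("F1 agrees between count and harmonic-mean forms", {
  set.seed(4)
  for (rep in 1:25) {
    m <- as_stage_confusion(matrix(rpois(16, 40), 4, 4))
    f1 <- per_class_f1(m)
    met <- summary_metrics(m)
    harm <- ifelse(met$precision + met$sensitivity == 0, 0,
                   2 * met$precision * met$sensitivity /
                     (met$precision + met$sensitivity))
    expect_equal(unname(f1), harm, tolerance = 1e-12)
  }
  ident <- as_stage_confusion(diag(4) * 10)
  expect_equal(unname(per_class_f1(ident)), rep(1, 4))
})

test_that("summary metrics match hand calculations", {
  # 4-class matrix with known one-vs-rest counts for the first class
  m <- as_stage_confusion(rbind(
    c(8, 2, 0, 0),
    c(1, 9, 0, 0),
    c(0, 0, 5, 0),
    c(0, 0, 0, 5)
  ))
  met <- summary_metrics(m)
  expect_equal(met$sensitivity[1], 8 / 10)
  expect_equal(met$sensitivity[2], 9 / 10)
  expect_equal(met$precision[1], 8 / 9)
  expect_equal(met$false_positive_rate[1], 1 / 20)
  expect_equal(met$accuracy + met$error, rep(1, 4))
  expect_true(all(dplyr::select(
    as.data.frame(met), accuracy:f1
  ) >= 0))
  g <- glance(met)
  expect_equal(g$frame_accuracy, 27 / 30)
  expect_error(summary_metrics(as_stage_confusion(matrix(0, 4, 4))),
               class = "seedstage_config_error")
})

test_that("metrics are equivariant under class relabelling", {
  set.seed(11)
  counts <- matrix(rpois(16, 30), 4, 4)
  perm <- c(3, 1, 4, 2)
  f1 <- unname(per_class_f1(as_stage_confusion(counts)))
  f1p <- unname(per_class_f1(as_stage_confusion(counts[perm, perm])))
  expect_equal(f1p, f1[perm])
})

test_that("tidiers return well-formed tables", {
  cm <- confusion_matrix(c(0, 1, 2, 3, 1), c(0, 1, 2, 3, 2))
  td <- tidy(cm)
  expect_equal(nrow(td), 16)
  expect_equal(sum(td$n), 5)
  met <- summary_metrics(cm)
  long <- tidy(met)
  expect_setequal(unique(long$stage), stage_levels())
  expect_true(all(c("metric", "value") %in% names(long)))
})
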
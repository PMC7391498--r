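# ordinal median smoothing and ontology enforcement

test_that("the window median picks the lower order statistic", {
  expect_equal(as.character(median_smooth(c("OC", "OC", "OC", "OC"), 4)),
               rep("OC", 4))
  # trailing window [FA, FA, OC, FA]: sorted codes 1,1,1,2 -> 2nd = FA
  out <- median_smooth(c("FA", "FA", "OC", "FA"), 4, align = "trailing")
  expect_equal(as.character(out[4]), "FA")
  expect_error(median_smooth(c("FA"), 0), class = "seedstage_config_error")
})

test_that("median smoothing matches sort oracles for n = 1..9", {
  set.seed(31)
  for (n in 1:9) {
    for (rep in 1:10) {
      labs <- sample(0:3, 25, replace = TRUE)
      got_tr <- stage_code(median_smooth(labs, n, align = "trailing"))
      want_tr <- vapply(seq_along(labs), function(t) {
        win <- labs[max(1, t - n + 1):t]
        sort(win)[(length(win) + 1) %/% 2] # lower median by sorting
      }, 0L)
      expect_equal(got_tr, want_tr)
      got_ce <- stage_code(median_smooth(labs, n, align = "centered"))
      half <- (n - 1) %/% 2
      want_ce <- vapply(seq_along(labs), function(t) {
        win <- labs[max(1, t - half):min(length(labs), t - half + n - 1)]
        sort(win)[(length(win) + 1) %/% 2]
      }, 0L)
      expect_equal(got_ce, want_ce)
    }
  }
  # the centred lower median leaves clean monotone sequences unchanged
  mono <- seedstage:::stage_at(1:30, 8, 15, 23)
  expect_equal(stage_code(median_smooth(mono, 4)), mono)
})

test_that("a single-frame flip is removed at every interior position", {
  base <- rep(1L, 20)
  for (pos in 3:18) {
    noisy <- base
    noisy[pos] <- 2L
    sm <- stage_code(median_smooth(noisy, 4))
    expect_equal(sm, base)
  }
})

test_that("ontology enforcement is the running maximum", {
  expect_equal(
    as.character(enforce_monotone(c("Soil", "FA", "OC", "FL"))),
    c("Soil", "FA", "OC", "FL")
  )
  out <- enforce_monotone(c("Soil", "FL", "FL", "OC", "OC"))
  expect_equal(as.character(out), c("Soil", "FL", "FL", "FL", "FL"))
  set.seed(17)
  for (rep in 1:200) {
    labs <- sample(0:3, 40, replace = TRUE)
    got <- stage_code(enforce_monotone(labs))
    expect_equal(got, cummax(labs)) # brute-force cumulative max
    expect_true(all(diff(got) >= 0))
    expect_true(all(got >= labs))
  }
})

test_that("postprocess smooths then clamps, preserving trace shape", {
  probs <- matrix(0.25, 12, 4)
  trace <- seedstage:::new_trace(probs, stage_levels())
  trace$label <- stage_factor(c(0, 0, 1, 0, 1, 1, 2, 2, 3, 2, 2, 3))
  out <- postprocess(trace, smoothing_config(4, TRUE))
  expect_equal(nrow(out), 12)
  expect_true(all(diff(stage_code(out$label)) >= 0))
  expect_equal(out$p_soil, trace$p_soil) # probabilities untouched
  # n = 1 with ontology off is the identity
  id <- postprocess(trace, smoothing_config(1, FALSE))
  expect_equal(stage_code(id$label), stage_code(trace$label))
  # idempotence
  twice <- postprocess(out, smoothing_config(4, TRUE))
  expect_equal(stage_code(twice$label), stage_code(out$label))
})

test_that("postprocess is idempotent on random sequences", {
  set.seed(5)
  for (rep in 1:50) {
    probs <- matrix(0.25, 30, 4)
    trace <- seedstage:::new_trace(probs, stage_levels())
    trace$label <- stage_factor(sample(0:3, 30, replace = TRUE))
    once <- postprocess(trace)
    twice <- postprocess(once)
    expect_equal(stage_code(twice$label), stage_code(once$label))
  }
})

# --- window sweep ------------------------------------------------------------

simulate_flip_traces <- function(n_seq, len, flip_p, seed) {
  set.seed(seed)
  lapply(seq_len(n_seq), function(i) {
    t1 <- sample(5:(len / 2), 1)
    t2 <- sample((t1 + 3):(len - 10), 1)
    t3 <- sample((t2 + 3):(len - 1), 1)
    code <- seedstage:::stage_at(seq_len(len), t1, t2, t3)
    noisy <- code
    flips <- runif(len) < flip_p
    noisy[flips] <- sample(0:3, sum(flips), replace = TRUE)
    probs <- matrix(0.25, len, 4)
    trace <- seedstage:::new_trace(probs, stage_levels())
    trace$label <- stage_factor(noisy)
    list(trace = trace, truth = code)
  })
}

test_that("noise-free traces keep accuracy flat and pick n = 1", {
  sims <- simulate_flip_traces(10, 40, 0, seed = 8)
  sweep <- sweep_window_size(
    lapply(sims, `[[`, "trace"), lapply(sims, `[[`, "truth"),
    n_range = 1:6, config = smoothing_config(enforce_ontology = FALSE)
  )
  expect_equal(sweep$best_n, 1L)
  expect_equal(sweep$curve$accuracy, rep(1, 6))
})

test_that("under isolated flips the sweep peaks at a small window", {
  sims <- simulate_flip_traces(200, 60, 0.05, seed = 13)
  sweep <- sweep_window_size(
    lapply(sims, `[[`, "trace"), lapply(sims, `[[`, "truth"),
    n_range = 1:12
  )
  expect_gte(sweep$best_n, 3)
  expect_lte(sweep$best_n, 6)
  acc <- sweep$curve$accuracy
  expect_gt(max(acc), acc[1]) # smoothing helps
  expect_gt(max(acc), acc[12]) # over-smoothing hurts
  expect_error(
    sweep_window_size(list(sims[[1]]$trace), list(c(0, 1))),
    class = "seedstage_config_error"
  )
})
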
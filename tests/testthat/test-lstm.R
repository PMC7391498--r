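# recurrent cells against independent small-instance oracles

# scalar oracle: the gate equations written out in plain arithmetic for a
# single-unit cell, independent of the vectorised implementation
scalar_lstm_oracle <- function(x, h, c, w, peep_prev = TRUE) {
  sg <- function(z) 1 / (1 + exp(-z))
  i <- sg(w$W_xi * x + w$W_hi * h + w$w_ci * c + w$b_i)
  f <- sg(w$W_xf * x + w$W_hf * h + w$w_cf * c + w$b_f)
  cc <- f * c + i * tanh(w$W_xc * x + w$W_hc * h + w$b_c)
  o <- sg(w$W_xo * x + w$W_ho * h + w$w_co * (if (peep_prev) c else cc) +
            w$b_o)
  hh <- o * tanh(cc)
  list(h = hh, c = cc)
}

test_that("lstm_step matches the scalar oracle to 1e-10", {
  w <- list(
    W_xi = 0.3, W_xf = -0.2, W_xc = 0.7, W_xo = 0.15,
    W_hi = -0.4, W_hf = 0.5, W_hc = -0.3, W_ho = 0.6,
    w_ci = 0.12, w_cf = -0.08, w_co = 0.2,
    b_i = 0.05, b_f = 1, b_c = -0.1, b_o = 0.02
  )
  wmat <- w
  for (nm in c("W_xi", "W_xf", "W_xc", "W_xo", "W_hi", "W_hf", "W_hc",
               "W_ho")) {
    wmat[[nm]] <- matrix(w[[nm]], 1, 1)
  }
  for (case in list(c(0.8, -0.3, 0.5), c(-1.2, 0.9, -0.4))) {
    got <- lstm_step(case[1], case[2], case[3], wmat)
    want <- scalar_lstm_oracle(case[1], case[2], case[3], w)
    expect_equal(got$h, want$h, tolerance = 1e-10)
    expect_equal(got$c, want$c, tolerance = 1e-10)
    gotc <- lstm_step(case[1], case[2], case[3], wmat, "current")
    wantc <- scalar_lstm_oracle(case[1], case[2], case[3], w, FALSE)
    expect_equal(gotc$h, wantc$h, tolerance = 1e-10)
  }
})

test_that("lstm_step degenerate and range properties hold", {
  u <- 4
  w <- init_lstm_weights(3, u, seed = 1)
  wz <- lapply(w, function(p) p * 0)
  st <- lstm_step(rep(0, 3), rep(0, u), rep(0, u), wz)
  expect_equal(st$h, rep(0, u)) # sigma(0)=0.5 but tanh(0)=0
  expect_equal(st$c, rep(0, u))
  st2 <- lstm_step(rnorm(3), rnorm(u), rnorm(u), w)
  expect_true(all(st2$i > 0 & st2$i < 1))
  expect_true(all(st2$f > 0 & st2$f < 1))
  expect_true(all(st2$o > 0 & st2$o < 1))
  expect_error(lstm_step(rnorm(5), rnorm(u), rnorm(u), w),
               class = "seedstage_shape_error")
})

test_that("convlstm_step reduces exactly to lstm_step at 1x1 extent", {
  w <- init_lstm_weights(2, 3, seed = 5)
  x <- rnorm(2)
  h0 <- rnorm(3)
  c0 <- rnorm(3)
  sl <- lstm_step(x, h0, c0, w)
  sc <- convlstm_step(matrix(x, 1, 2), matrix(h0, 1, 3), matrix(c0, 1, 3),
                      w)
  expect_lt(max(abs(sl$h - as.vector(sc$h))), 1e-6)
  expect_lt(max(abs(sl$c - as.vector(sc$c))), 1e-6)
  # zero weights: H identically zero
  wz <- lapply(init_convlstm_weights(c(4, 4), 2, 3, 3, seed = 1),
               function(p) p * 0)
  sz <- convlstm_step(array(rnorm(4 * 4 * 2), c(4, 4, 2)),
                      matrix(0, 16, 3), matrix(0, 16, 3), wz)
  expect_true(all(sz$h == 0))
})

test_that("convlstm response shifts with a shifted input (interior)", {
  # an impulse away from the borders: shifting the input by one pixel
  # shifts the hidden response by one pixel (zero padding only disturbs
  # the borders, which are excluded)
  set.seed(3)
  hh <- 9; ww <- 9
  w <- init_convlstm_weights(c(hh, ww), 1, 2, 3, seed = 7)
  w$w_ci[] <- 0; w$w_cf[] <- 0; w$w_co[] <- 0 # spatially uniform cell
  impulse <- function(y, x) {
    m <- matrix(0, hh, ww)
    m[y, x] <- 1
    array(m, c(hh, ww, 1))
  }
  zero <- matrix(0, hh * ww, 2)
  s1 <- convlstm_step(impulse(4, 4), zero, zero, w)
  s2 <- convlstm_step(impulse(5, 5), zero, zero, w)
  h1 <- array(s1$h, c(hh, ww, 2))
  h2 <- array(s2$h, c(hh, ww, 2))
  expect_lt(max(abs(h1[2:7, 2:7, ] - h2[3:8, 3:8, ])), 1e-10)
})

test_that("lstm BPTT gradients agree with finite differences", {
  set.seed(7)
  ind <- 3; u <- 3; tt <- 4
  w <- init_lstm_weights(ind, u, seed = 2)
  x <- matrix(rnorm(ind * tt), ind, tt)
  loss <- function(w) sum(seedstage:::lstm_forward(x, w)$h^2)
  fw <- seedstage:::lstm_forward(x, w)
  bw <- seedstage:::lstm_backward(2 * fw$h, x, w, fw$cache)
  eps <- 1e-6
  for (nm in c("W_xi", "W_hf", "w_co", "b_c")) {
    g <- w[[nm]] * 0
    for (i in seq_along(w[[nm]])) {
      w1 <- w; w1[[nm]][i] <- w1[[nm]][i] + eps
      w2 <- w; w2[[nm]][i] <- w2[[nm]][i] - eps
      g[i] <- (loss(w1) - loss(w2)) / (2 * eps)
    }
    expect_lt(max(abs(g - bw$grads[[nm]])), 1e-6)
  }
})
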
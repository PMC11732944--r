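test_that("recurrent matrix is rescaled exactly to the target spectral radius", {
  w1 <- build_reservoir(reservoir_spec(M = 1, k = 1, rho = 0.5, seed = 3))
  expect_equal(abs(w1$W_res[1, 1]), 0.5)

  w <- build_reservoir(reservoir_spec(M = 50, k = 1, rho = 0.95, seed = 5))
  sr <- max(Mod(eigen(w$W_res, only.values = TRUE)$values))
  expect_lt(abs(sr - 0.95), 1e-8)

  wd <- build_reservoir(reservoir_spec(M = 40, k = 2, rho = 0.8, seed = 9,
                                       density = 0.2))
  expect_gt(mean(wd$W_res == 0), 0.5)
  srd <- max(Mod(eigen(wd$W_res, only.values = TRUE)$values))
  expect_lt(abs(srd - 0.8), 1e-8)
})

test_that("identical specifications reproduce bit-identical weights", {
  s <- reservoir_spec(M = 17, k = 3, seed = 42)
  expect_identical(build_reservoir(s)$W_in, build_reservoir(s)$W_in)
  expect_identical(build_reservoir(s)$W_res, build_reservoir(s)$W_res)
  # and a different seed gives different weights
  s2 <- reservoir_spec(M = 17, k = 3, seed = 43)
  expect_false(identical(build_reservoir(s)$W_res,
                         build_reservoir(s2)$W_res))
})

test_that("spec validation rejects out-of-range hyperparameters", {
  expect_error(reservoir_spec(M = 0), "M")
  expect_error(reservoir_spec(a = 1.2), "a")
  expect_error(reservoir_spec(rho = 0), "rho")
  expect_error(reservoir_spec(k = 0.5), "k")
})

test_that("single state update honours the leaky-integrator limits", {
  w <- build_reservoir(reservoir_spec(M = 4, k = 2, seed = 1))
  x <- c(0.3, -0.2, 0.1, 0.4); u <- c(1, -1)
  # a = 0: state unchanged
  expect_identical(update_state(x, u, w, a = 0), x)
  # a = 1 from the zero state: pure tanh of the input drive
  expect_equal(update_state(rep(0, 4), u, w, a = 1),
               drop(tanh(w$W_in %*% u)))
  # zero state, zero input: stays at zero
  expect_identical(update_state(rep(0, 4), c(0, 0), w), rep(0, 4))
  expect_error(update_state(c(1, 2), u, w), "length")
  expect_error(update_state(x, c(1, 2, 3), w), "length")
})

test_that("run_sequence iterates the update from the zero state", {
  w <- build_reservoir(reservoir_spec(M = 6, k = 1, seed = 2))
  expect_identical(run_sequence(matrix(0, 10, 1), w),
                   matrix(0, 10, 6))
  u1 <- matrix(0.7)
  expect_equal(run_sequence(u1, w)[1, ],
               update_state(rep(0, 6), 0.7, w))
  useq <- matrix(rnorm(20), 20, 1)
  expect_identical(run_sequence(useq, w), run_sequence(useq, w))
  expect_error(run_sequence(matrix(0, 0, 1), w), "non-empty")
  expect_error(run_sequence(matrix(0, 3, 2), w), "columns")
})

test_that("states match a hand-unrolled scalar recurrence to 1e-12", {
  for (M in 1:3) {
    for (n in c(1, 3, 5)) {
      spec <- reservoir_spec(M = M, k = 2, a = 0.85, rho = 0.7,
                             seed = 100 + M)
      w <- build_reservoir(spec)
      useq <- matrix(seq_len(n * 2) / 7 - 0.5, n, 2)
      expect_equal(run_sequence(useq, w),
                   scalar_unroll(useq, w$W_in, w$W_res, spec$a),
                   tolerance = 1e-12)
    }
  }
})

test_that("states started at zero stay strictly inside (-1, 1)", {
  for (s in 1:5) {
    spec <- reservoir_spec(M = 20, k = 1, a = 0.9, rho = 0.95, seed = s)
    w <- build_reservoir(spec)
    useq <- matrix(withr::with_seed(s, rnorm(100, 0, 3)), ncol = 1)
    st <- run_sequence(useq, w)
    expect_lt(max(abs(st)), 1)
  }
})

test_that("initial-state influence fades under the echo state property", {
  for (s in 1:5) {
    d <- esp_profile(reservoir_spec(M = 30, a = 0.9, rho = 0.95, seed = s),
                     n = 200)
    expect_lt(d[200], 1e-6)
    # eventually monotone decreasing, checked above the double-precision
    # floor where rounding noise would dominate
    win <- d[d > 1e-12]
    win <- win[-seq_len(min(60, length(win) - 2))]   # past the transient
    expect_true(all(diff(win) <= 0))
  }
})
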
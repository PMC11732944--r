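test_that("monthly interpolation reproduces knots and linear midpoints", {
  ip <- interpolate_monthly(c(0, 2), matrix(c(1, 3)))
  expect_equal(ip$months, 0:2)
  expect_equal(drop(ip$values), c(1, 2, 3))

  # visits already on consecutive months are reproduced exactly
  v <- matrix(c(0.3, -1.2, 4.5, 0.9), 4, 1)
  ip2 <- interpolate_monthly(0:3, v)
  expect_identical(drop(ip2$values), drop(v))

  # per-marker independence: a constant second marker stays constant
  ip3 <- interpolate_monthly(c(0, 3), cbind(c(0, 3), c(5, 5)))
  expect_equal(ip3$values[, 1], 0:3)
  expect_equal(ip3$values[, 2], rep(5, 4))

  # a fractional last visit is appended exactly, after the month grid
  ip4 <- interpolate_monthly(c(10, 12.5), matrix(c(0, 5)))
  expect_equal(ip4$months, c(0, 1, 2, 2.5))
  expect_equal(drop(ip4$values), c(0, 2, 4, 5))

  expect_error(interpolate_monthly(c(0, 0, 2), matrix(1:3)),
               "strictly increasing")
  expect_error(interpolate_monthly(3, matrix(1)), "two visits")
})

test_that("skip sampling matches the backward-enumeration oracle", {
  expect_identical(skip_select(10, 4), c(2L, 6L, 10L))
  expect_identical(skip_select(7, 1), 1:7)
  expect_identical(skip_select(1, 5), 1L)
  expect_error(skip_select(5, 0), "tau")

  oracle <- function(n, tau) {
    idx <- integer(0); j <- n
    while (j >= 1) { idx <- c(j, idx); j <- j - tau }
    idx
  }
  set.seed(31)
  for (rep in 1:200) {
    n <- sample(1:100, 1); tau <- sample(1:n, 1)
    got <- skip_select(n, tau)
    expect_identical(got, oracle(n, tau))
    expect_true(n %in% got)
    expect_length(got, ceiling(n / tau))
  }
})

test_that("stacked design matrix has one block per participant with replicated labels", {
  ch <- tiny_cohort()
  m_i <- vapply(ch$participants, function(p)
    length(interpolate_monthly(p$times, p$values)$months), 0L)

  fit1 <- interp_esn(ch, tau = 1, M = 6, seed = 1)
  expect_equal(fit1$n_rows, sum(m_i))

  fit4 <- interp_esn(ch, tau = 2, M = 6, seed = 1)
  expect_equal(fit4$n_rows, sum(ceiling(m_i / 2)))

  # provenance: per-participant row counts and outcome replication
  counts <- table(fit4$row_index$id)
  expect_equal(unname(c(counts[vapply(ch$participants, function(p)
    as.character(p$id), "")])), ceiling(m_i / 2))
})

test_that("well-separated classes yield confident calibrated probabilities", {
  ch <- tiny_cohort(n_ctrl = 10, n_case = 10, shift = 6)
  fit <- interp_esn(ch, tau = 2, M = 10, seed = 1)
  pr <- predict(fit, ch, per_row = TRUE)
  expect_true(all(pr$prob > 0 & pr$prob < 1))
  truth <- cohort_outcomes(ch)[as.character(pr$id)]
  correct <- ifelse(truth == "case", pr$prob, 1 - pr$prob)
  expect_true(all(correct >= 0.9))
})

test_that("the participant prediction is the last retained row's probability", {
  ch <- tiny_cohort()
  fit <- interp_esn(ch, tau = 2, M = 8, seed = 2)
  p <- predict(fit, ch)
  rows <- predict(fit, ch, per_row = TRUE)
  last_of <- vapply(split(rows, rows$id), function(g)
    g$prob[which.max(g$month)], numeric(1))
  expect_equal(p[names(last_of)], last_of[names(last_of)])
})

test_that("identical series with opposite labels get identical predictions", {
  df <- tiny_cohort_df(n_ctrl = 4, n_case = 4)
  twin <- df[df$id == "C01", ]
  twin$id <- "K99"; twin$outcome <- "case"
  ch <- cohort(rbind(df, twin), outcome_levels = c("control", "case"))
  fit <- interp_esn(ch, tau = 2, M = 8, seed = 3)
  p <- predict(fit, ch)
  expect_equal(unname(p["C01"]), unname(p["K99"]))
})

test_that("forecast truncation drops the last gamma months on the test side only", {
  df <- data.frame(id = rep(c("A", "B"), c(2, 2)),
                   time = c(0, 11, 0, 4),
                   marker_1 = c(0, 1, 0.5, 0.2),
                   outcome = rep(c("control", "case"), c(2, 2)))
  ch <- cohort(df, outcome_levels = c("control", "case"))
  train <- tiny_cohort(n_ctrl = 5, n_case = 5)
  # single-marker fit so shapes match the one-marker test cohort
  fit <- interp_esn(train, markers = "marker_1", tau = 1, M = 6, seed = 1)

  # A has months 0..11 (m = 12); gamma = 6 keeps rows 1..6 (months 0..5)
  rows <- predict(fit, ch, gamma = 6, per_row = TRUE)
  expect_equal(max(rows$month[rows$id == "A"]), 5)
  # B has m = 5 monthly rows; gamma = 6 excludes it
  p <- predict(fit, ch, gamma = 6)
  expect_identical(attr(p, "excluded"), "B")
  expect_identical(names(p), "A")
  # gamma too large for everyone: error
  expect_error(predict(fit, ch, gamma = 50), "no usable participants")
})

test_that("tau larger than the shortest monthly series is rejected", {
  df <- data.frame(id = rep(c("A", "B"), each = 2),
                   time = c(0, 2, 0, 30),
                   marker_1 = c(0, 1, 0, 1),
                   outcome = rep(c("control", "case"), each = 2))
  ch <- cohort(df, outcome_levels = c("control", "case"))
  expect_error(interp_esn(ch, tau = 10, M = 5, seed = 1),
               "shortest monthly sequence")
})

test_that("refitting with the same cohort and seed is bit-identical", {
  ch <- tiny_cohort()
  p1 <- predict(interp_esn(ch, M = 8, seed = 5, tau = 2), ch)
  p2 <- predict(interp_esn(ch, M = 8, seed = 5, tau = 2), ch)
  expect_identical(p1, p2)
})
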
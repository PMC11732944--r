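test_that("differential encoding takes adjacent pairwise differences", {
  expect_equal(diff_transform(c(2, 5, 4)), matrix(c(3, -1)))
  expect_equal(diff_transform(rep(3.7, 6)), matrix(0, 5, 1))
  m <- matrix(rnorm(12), 4, 3)
  expect_equal(diff_transform(m + 2.5), diff_transform(m))
  expect_equal(nrow(diff_transform(m)), 3)
  expect_error(diff_transform(1), "too short")
})

test_that("variance hallmark is the per-neuron population variance", {
  expect_equal(variance_hallmark(matrix(1.3, 5, 2)), c(0, 0))
  expect_equal(variance_hallmark(cbind(c(0, 1))), 0.25)
  traj <- matrix(rnorm(40), 10, 4)
  perm <- traj[sample(10), , drop = FALSE]
  expect_equal(variance_hallmark(perm), variance_hallmark(traj))
  expect_true(all(variance_hallmark(traj) >= 0))
  expect_error(variance_hallmark(matrix(1, 1, 3)), "at least 2")
})

test_that("variance features have the contracted shape and zero rows for constants", {
  w <- build_reservoir(reservoir_spec(M = 8, k = 1, seed = 4))
  x1 <- matrix(rnorm(20), 1, 20)
  expect_equal(dim(variance_features(x1, w)), c(1, 8))
  xconst <- matrix(5, 3, 20)   # constant samples: zero differences
  expect_equal(variance_features(xconst, w), matrix(0, 3, 8))
  # constant offset leaves features unchanged (static suppression)
  x <- matrix(rnorm(60), 3, 20)
  expect_equal(variance_features(x + 7, w), variance_features(x, w))
})

test_that("a separable variance geometry is fit with zero training error", {
  d <- flat_vs_zigzag(n_per_class = 8, len = 30)
  fit <- diff_esn(d$x, d$y, M = 10, seed = 1)
  expect_identical(predict(fit, d$x), d$y)
  # prediction is deterministic across repeated calls
  expect_identical(predict(fit, d$x), predict(fit, d$x))
})

test_that("duplicating every training sample leaves the decision rule unchanged", {
  d <- flat_vs_zigzag(n_per_class = 8, len = 30, noise = 0.2)
  fit1 <- diff_esn(d$x, d$y, M = 10, seed = 1)
  dup <- list(x = d$x[rep(seq_len(nrow(d$x)), 2), ],
              y = d$y[rep(seq_along(d$y), 2)])
  fit2 <- diff_esn(dup$x, dup$y, M = 10, seed = 1)
  probe <- flat_vs_zigzag(n_per_class = 20, len = 30, noise = 0.3,
                          seed = 99)
  expect_identical(predict(fit1, probe$x), predict(fit2, probe$x))
})

test_that("degenerate single-class training labels are rejected", {
  d <- flat_vs_zigzag(n_per_class = 4, len = 20)
  expect_error(diff_esn(d$x, rep("a", nrow(d$x)), M = 5, seed = 1),
               "single class")
})

test_that("multiclass one-vs-rest is equivariant to relabelling", {
  d <- gen_regular(n_per_class = 12, length = 60,
                   classes = list(
                     list(window = c(5, 20), amplitude = 8),
                     list(window = c(25, 40), amplitude = 8),
                     list(window = c(42, 57), amplitude = 8)),
                   seed = 21)
  fit <- diff_esn(d$train$x, d$train$y, M = 30, seed = 2)
  p <- predict(fit, d$test$x)
  # relabel 1->B, 2->C, 3->A and refit: predictions map through
  map <- c("1" = "B", "2" = "C", "3" = "A")
  y2 <- factor(map[as.character(d$train$y)])
  fit2 <- diff_esn(d$train$x, y2, M = 30, seed = 2)
  p2 <- predict(fit2, d$test$x)
  expect_identical(as.character(p2), unname(map[as.character(p)]))
})

test_that("the full pipeline is invariant to constant offsets of test samples", {
  d <- gen_regular(n_per_class = 20, length = 80, seed = 5)
  fit <- diff_esn(d$train$x, d$train$y, M = 25, seed = 3)
  base <- predict(fit, d$test$x)
  for (shift in c(-3, 0.5, 100))
    expect_identical(predict(fit, d$test$x + shift), base)
})

test_that("fixed data and seed give a bit-identical error rate", {
  d <- gen_regular(n_per_class = 15, length = 60, seed = 8)
  run <- function() {
    fit <- diff_esn(d$train$x, d$train$y, M = 20, seed = 6)
    error_rate(d$test$y, predict(fit, d$test$x))
  }
  expect_identical(run(), run())
})
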
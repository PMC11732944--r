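# Shared fixture builders; everything is generated in code.

# tiny cohort data frame: two clearly separated outcome groups
tiny_cohort_df <- function(n_ctrl = 4, n_case = 4, shift = 4, k = 2,
                           seed = 11) {
  withr::with_seed(seed, {
    rows <- list()
    mk <- function(pid, base, outcome) {
      nv <- sample(3:5, 1)
      tm <- cumsum(c(0, runif(nv - 1, 3, 9)))
      vals <- matrix(rnorm(nv * k, base, 0.3), nv, k)
      data.frame(id = pid, time = tm, vals, outcome = outcome)
    }
    for (i in seq_len(n_ctrl))
      rows[[length(rows) + 1]] <- mk(sprintf("C%02d", i), 0, "control")
    for (i in seq_len(n_case))
      rows[[length(rows) + 1]] <- mk(sprintf("K%02d", i), shift, "case")
    df <- do.call(rbind, rows)
    names(df)[3:(2 + k)] <- paste0("marker_", seq_len(k))
    df
  })
}

tiny_cohort <- function(...) {
  cohort(tiny_cohort_df(...), outcome_levels = c("control", "case"))
}

# regular dataset separable by the variance hallmark by construction:
# class 1 nearly flat, class 2 a large zig-zag
flat_vs_zigzag <- function(n_per_class = 10, len = 30, noise = 0, seed = 7) {
  withr::with_seed(seed, {
    x1 <- matrix(rnorm(n_per_class * len, 0, max(noise, 1e-3)),
                 n_per_class, len)
    zig <- rep(c(-1, 1), length.out = len)
    x2 <- matrix(rep(zig, each = n_per_class), n_per_class, len) +
      matrix(rnorm(n_per_class * len, 0, max(noise, 1e-3)),
             n_per_class, len)
    list(x = rbind(x1, x2),
         y = factor(rep(c("flat", "zigzag"), each = n_per_class)))
  })
}

# hand-unrolled leaky-integrator recurrence in scalar arithmetic
scalar_unroll <- function(seq, W_in, W_res, a) {
  M <- nrow(W_res); n <- nrow(seq); k <- ncol(seq)
  x <- rep(0, M)
  out <- matrix(0, n, M)
  for (t in 1:n) {
    xn <- numeric(M)
    for (m in 1:M) {
      acc <- 0
      for (j in 1:k) acc <- acc + W_in[m, j] * seq[t, j]
      for (j in 1:M) acc <- acc + W_res[m, j] * x[j]
      xn[m] <- (1 - a) * x[m] + a * tanh(acc)
    }
    x <- xn
    out[t, ] <- x
  }
  out
}
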
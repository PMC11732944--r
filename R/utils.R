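# internal helpers shared across the package

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. Mersenne-Twister + Inversion are pinned so results do not
# depend on session RNGkind settings.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = env)
    on.exit(assign(".Random.seed", old, envir = env), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf,
                             integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a single finite number", call. = FALSE)
  if (x < lower || x > upper)
    stop("'", name, "' must lie in [", lower, ", ", upper, "]", call. = FALSE)
  if (integerish && abs(x - round(x)) > 1e-8)
    stop("'", name, "' must be an integer", call. = FALSE)
  invisible(x)
}

# normal-approximation 95% CI of the mean of `x`
mean_ci <- function(x, level = 0.95) {
  m <- mean(x)
  half <- stats::qnorm(1 - (1 - level) / 2) * stats::sd(x) / sqrt(length(x))
  if (length(x) < 2L || !is.finite(half)) half <- 0
  c(mean = m, lower = m - half, upper = m + half)
}
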
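#' Specify a fixed random reservoir
#'
#' A reservoir specification collects the hyperparameters and the RNG seed
#' that fully determine one echo state network reservoir: the number of
#' neurons `M`, the leakage rate `a` of the leaky-integrator update, the
#' target spectral radius `rho` of the recurrent matrix, and the input
#' dimension `k`. Identical specifications reproduce bit-identical weights.
#'
#' @param M number of reservoir neurons (positive integer).
#' @param a leakage rate in `[0, 1]`; the state update is the convex
#'   combination `(1 - a) * x + a * tanh(W_in u + W_res x)`. Values slightly
#'   below 1 are conventional; the default is 0.9.
#' @param rho target spectral radius (> 0) of the recurrent weight matrix.
#'   Values below 1 preserve the echo state (fading memory) property; the
#'   default is 0.95.
#' @param k number of input features (positive integer).
#' @param seed integer RNG seed for the weight draws.
#' @param input_scale multiplicative scale applied to the input weights
#'   after the standard-normal draw (default 1, i.e. raw draws).
#' @param density fraction of non-zero entries in the recurrent matrix in
#'   `(0, 1]`; the default 1 keeps the matrices dense. Sparsification is
#'   applied by a Bernoulli mask before spectral-radius rescaling.
#' @return An object of class `"reservoir_spec"`.
#' @seealso [build_reservoir()], [run_sequence()]
#' @examples
#' spec <- reservoir_spec(M = 10, a = 0.9, rho = 0.95, k = 1, seed = 1)
#' spec
#' @export
reservoir_spec <- function(M = 50L, a = 0.9, rho = 0.95, k = 1L, seed = 1L,
                           input_scale = 1, density = 1) {
  stopifnot_scalar(M, "M", lower = 1, integerish = TRUE)
  stopifnot_scalar(a, "a", lower = 0, upper = 1)
  stopifnot_scalar(rho, "rho", lower = .Machine$double.eps)
  stopifnot_scalar(k, "k", lower = 1, integerish = TRUE)
  stopifnot_scalar(seed, "seed", integerish = TRUE)
  stopifnot_scalar(input_scale, "input_scale", lower = 0)
  stopifnot_scalar(density, "density", lower = .Machine$double.eps, upper = 1)
  structure(
    list(M = as.integer(M), a = a, rho = rho, k = as.integer(k),
         seed = as.integer(seed), input_scale = input_scale,
         density = density),
    class = "reservoir_spec")
}

#' @export
print.reservoir_spec <- function(x, ...) {
  cat("Reservoir specification: M =", x$M, ", a =", x$a, ", rho =", x$rho,
      ", k =", x$k, ", seed =", x$seed, "\n")
  invisible(x)
}

#' Build the fixed random weights of a reservoir
#'
#' Draws the input matrix `W_in` (`M x k`) and the recurrent matrix `W_res`
#' (`M x M`) i.i.d. from the standard normal distribution under the seed in
#' `spec`, then rescales `W_res` so that its spectral radius (largest
#' eigenvalue magnitude) equals `spec$rho`. The weights are fixed: no
#' training ever touches them.
#'
#' @param spec a [reservoir_spec()].
#' @return An object of class `"reservoir"` with components `W_in`, `W_res`
#'   and `spec`.
#' @examples
#' w <- build_reservoir(reservoir_spec(M = 5, k = 1, seed = 42))
#' max(Mod(eigen(w$W_res, only.values = TRUE)$values))  # equals rho
#' @export
build_reservoir <- function(spec) {
  if (!inherits(spec, "reservoir_spec"))
    stop("'spec' must be a reservoir_spec", call. = FALSE)
  w <- with_seed(spec$seed, {
    W_in <- matrix(stats::rnorm(spec$M * spec$k), spec$M, spec$k)
    W_res <- matrix(stats::rnorm(spec$M * spec$M), spec$M, spec$M)
    if (spec$density < 1) {
      mask <- matrix(stats::runif(spec$M * spec$M) < spec$density,
                     spec$M, spec$M)
      W_res <- W_res * mask
    }
    list(W_in = spec$input_scale * W_in, W_res = W_res)
  })
  raw_sr <- max(Mod(eigen(w$W_res, only.values = TRUE)$values))
  if (raw_sr < 1e-12)
    stop("recurrent matrix has numerically zero spectral radius; ",
         "cannot rescale", call. = FALSE)
  W_res <- w$W_res * (spec$rho / raw_sr)
  structure(list(W_in = w$W_in, W_res = W_res, spec = spec),
            class = "reservoir")
}

#' @export
print.reservoir <- function(x, ...) {
  cat("Fixed random reservoir (", x$spec$M, " neurons, k = ", x$spec$k,
      ", spectral radius ", x$spec$rho, ", seed ", x$spec$seed, ")\n",
      sep = "")
  invisible(x)
}

#' One leaky-integrator state update
#'
#' Advances the reservoir state by one time step:
#' `(1 - a) * x + a * tanh(W_in %*% u + W_res %*% x)`.
#'
#' @param x current state, length-`M` numeric vector.
#' @param u current input, length-`k` numeric vector.
#' @param w a [build_reservoir()] object.
#' @param a leakage rate; defaults to the one in `w$spec`.
#' @return The next state as a length-`M` numeric vector.
#' @export
update_state <- function(x, u, w, a = w$spec$a) {
  if (length(x) != w$spec$M)
    stop("state has length ", length(x), ", expected M = ", w$spec$M,
         call. = FALSE)
  if (length(u) != w$spec$k)
    stop("input has length ", length(u), ", expected k = ", w$spec$k,
         call. = FALSE)
  drop((1 - a) * x + a * tanh(w$W_in %*% u + w$W_res %*% x))
}

#' Drive a reservoir with an input sequence
#'
#' Iterates [update_state()] over the rows of `seq`, starting from the zero
#' state. The state is never carried across samples: every call starts
#' afresh, which removes any dependency between consecutively processed
#' samples.
#'
#' @param seq input sequence: an `n x k` numeric matrix (or a length-`n`
#'   vector when `k = 1`), one time step per row.
#' @param w a [build_reservoir()] object.
#' @param x0 optional initial state (length `M`); defaults to zeros. Only
#'   diagnostic code (e.g. fading-memory checks) should override it.
#' @return An `n x M` matrix of internal states, row `j` being the state
#'   after consuming input row `j`. With `x0 = 0` every entry lies strictly
#'   inside `(-1, 1)`: each state is a convex combination of a `tanh` value
#'   and a bounded predecessor.
#' @export
run_sequence <- function(seq, w, x0 = NULL) {
  if (is.vector(seq)) seq <- matrix(seq, ncol = 1L)
  if (!is.matrix(seq) || nrow(seq) < 1L)
    stop("'seq' must be a non-empty n x k matrix", call. = FALSE)
  if (ncol(seq) != w$spec$k)
    stop("'seq' has ", ncol(seq), " columns, expected k = ", w$spec$k,
         call. = FALSE)
  M <- w$spec$M; a <- w$spec$a; n <- nrow(seq)
  x <- if (is.null(x0)) numeric(M) else {
    if (length(x0) != M) stop("'x0' must have length M", call. = FALSE)
    as.numeric(x0)
  }
  drive <- w$W_in %*% t(seq)            # M x n, input part precomputed
  out <- matrix(0, n, M)
  for (t in seq_len(n)) {
    x <- (1 - a) * x + a * tanh(drop(drive[, t] + w$W_res %*% x))
    out[t, ] <- x
  }
  out
}

#' Fading-memory (echo state property) diagnostic
#'
#' Drives one reservoir twice with the same i.i.d. standard-normal input
#' sequence, from the zero state and from a constant-offset state, and
#' returns the Euclidean distance between the two state trajectories at
#' every step. Under the echo state property the distance decays to zero,
#' i.e. the influence of the initial condition is forgotten at a rate
#' independent of the input.
#'
#' @param spec a [reservoir_spec()]; its seed also seeds the probe input.
#' @param n length of the probe input sequence (default 200).
#' @param offset the alternative initial state is `rep(offset, M)`
#'   (default 0.5).
#' @return Numeric vector of length `n`: per-step distances between the two
#'   trajectories.
#' @examples
#' d <- esp_profile(reservoir_spec(M = 20, seed = 3), n = 100)
#' d[length(d)] < 1e-6
#' @export
esp_profile <- function(spec, n = 200L, offset = 0.5) {
  w <- build_reservoir(spec)
  u <- with_seed(spec$seed + 10007L, stats::rnorm(n))
  u <- matrix(u, ncol = 1L)[, rep(1L, spec$k), drop = FALSE]
  s1 <- run_sequence(u, w)
  s2 <- run_sequence(u, w, x0 = rep(offset, spec$M))
  sqrt(rowSums((s1 - s2)^2))
}
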
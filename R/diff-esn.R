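#' Adjacent pairwise differences of a sequence
#'
#' Replaces a sequence by its first differences: row `j` of the result is
#' `seq[j + 1, ] - seq[j, ]`. This differential encoding suppresses static
#' levels (any constant offset cancels exactly) and emphasises abrupt local
#' change, mirroring event-driven processing in sensory neurons: most
#' transformed observations sit near zero and only sharp transitions remain
#' prominent.
#'
#' @param seq an `n x k` numeric matrix or a length-`n` vector, `n >= 2`.
#' @return An `(n - 1) x k` matrix (a length-`n - 1` vector input returns a
#'   1-column matrix).
#' @examples
#' diff_transform(c(2, 5, 4))   # 3, -1
#' @export
diff_transform <- function(seq) {
  if (is.vector(seq)) seq <- matrix(seq, ncol = 1L)
  if (!is.matrix(seq) || !is.numeric(seq))
    stop("'seq' must be a numeric matrix or vector", call. = FALSE)
  if (nrow(seq) < 2L)
    stop("sequence too short to difference (need n >= 2)", call. = FALSE)
  seq[-1L, , drop = FALSE] - seq[-nrow(seq), , drop = FALSE]
}

#' Per-neuron variance hallmark of a state trajectory
#'
#' Summarises a state trajectory by the variance over time of each neuron's
#' state sequence (population variance, i.e. divided by the number of time
#' steps). The variance captures how strongly each neuron was excited over
#' the sample, and — because different neurons respond to input structure at
#' different effective time scales — the vector of per-neuron variances
#' discriminates classes whose sequences differ in the magnitude of abrupt
#' local change.
#'
#' @param traj an `n x M` state matrix with `n >= 2` rows, as produced by
#'   [run_sequence()].
#' @return A length-`M` non-negative numeric vector.
#' @export
variance_hallmark <- function(traj) {
  if (!is.matrix(traj) || nrow(traj) < 2L)
    stop("trajectory must have at least 2 rows", call. = FALSE)
  ctr <- sweep(traj, 2L, colMeans(traj))
  colSums(ctr * ctr) / nrow(traj)
}

# i-th sample of a regular dataset as a T x k matrix
sample_matrix <- function(x, i) {
  if (length(dim(x)) == 3L) {
    matrix(x[i, , ], ncol = dim(x)[3L])
  } else {
    matrix(x[i, ], ncol = 1L)
  }
}

#' Variance features for a regular dataset
#'
#' Runs the full Diff-ESN feature pipeline for every sample: adjacent
#' differences ([diff_transform()]), reservoir states from the zero state
#' ([run_sequence()], reset per sample), then the per-neuron variance
#' hallmark ([variance_hallmark()]). Rows are stacked in sample order.
#'
#' @param x an `N x T` matrix of univariate series, or an `N x T x k` array.
#' @param w a [build_reservoir()] object with `k` matching `x`.
#' @return An `N x M` matrix of non-negative variance features.
#' @export
variance_features <- function(x, w) {
  N <- dim(x)[1L]
  k <- if (length(dim(x)) == 3L) dim(x)[3L] else 1L
  if (k != w$spec$k)
    stop("data have ", k, " features but the reservoir expects k = ",
         w$spec$k, call. = FALSE)
  out <- matrix(0, N, w$spec$M)
  for (i in seq_len(N)) {
    u <- diff_transform(sample_matrix(x, i))
    out[i, ] <- variance_hallmark(run_sequence(u, w))
  }
  out
}

#' Differential echo state network classifier
#'
#' Fits the Diff-ESN classifier for equal-length regular time series. Each
#' series is encoded as its adjacent pairwise differences, driven through a
#' fixed random leaky-integrator reservoir (state reset to zero per sample),
#' and summarised by the per-neuron variance of the resulting state
#' trajectory. A linear support vector machine is then trained on the
#' stacked variance vectors. Only the readout is trained; the recurrent
#' part is random and fixed, so no backpropagation is needed.
#'
#' @param x training series: `N x T` numeric matrix (univariate) or
#'   `N x T x k` array (multivariate), `T >= 2`.
#' @param y length-`N` vector of class labels (2 or more classes); coerced
#'   to factor. With more than two classes a one-vs-rest scheme is used.
#' @param M,a,rho,seed,input_scale,density reservoir hyperparameters; see
#'   [reservoir_spec()]. Defaults `M = 50`, `a = 0.9`, `rho = 0.95`.
#' @param cost regularisation weight of the linear SVM (default 1).
#' @param scale_features if `TRUE`, z-scale the variance columns (training
#'   statistics) before the SVM. Default `FALSE`: raw variances are used.
#' @return An object of class `"diff_esn"` with a [predict][predict.diff_esn]
#'   method.
#' @examples
#' d <- gen_regular(n_per_class = 20, length = 60, seed = 1)
#' fit <- diff_esn(d$train$x, d$train$y, M = 20, seed = 1)
#' mean(predict(fit, d$test$x) != d$test$y)  # test error rate
#' @seealso [seed_robustness()] for the repeated-seed evaluation protocol.
#' @export
diff_esn <- function(x, y, M = 50L, a = 0.9, rho = 0.95, seed = 1L,
                     cost = 1, scale_features = FALSE, input_scale = 1,
                     density = 1) {
  if (length(dim(x)) < 2L)
    stop("'x' must be an N x T matrix or N x T x k array", call. = FALSE)
  if (dim(x)[1L] != length(y))
    stop("number of series and labels differ", call. = FALSE)
  k <- if (length(dim(x)) == 3L) dim(x)[3L] else 1L
  spec <- reservoir_spec(M = M, a = a, rho = rho, k = k, seed = seed,
                         input_scale = input_scale, density = density)
  w <- build_reservoir(spec)
  X <- variance_features(x, w)
  ctr <- NULL; scl <- NULL
  if (scale_features) {
    ctr <- colMeans(X)
    scl <- apply(X, 2L, stats::sd)
    scl[scl < 1e-12] <- 1
    X <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  }
  readout <- fit_linear_readout(X, y, cost = cost)
  structure(
    list(reservoir = w, readout = readout, levels = readout$levels,
         center = ctr, scale = scl, cost = cost, n_train = nrow(X),
         call = match.call()),
    class = "diff_esn")
}

#' Predict class labels from a Diff-ESN fit
#'
#' @param object a [diff_esn()] fit.
#' @param newdata series in the same shape as the training `x`
#'   (`N x T` matrix or `N x T x k` array; `T` may differ from training).
#' @param ... unused.
#' @return A length-`N` factor of hard labels with the training levels.
#' @export
predict.diff_esn <- function(object, newdata, ...) {
  X <- variance_features(newdata, object$reservoir)
  if (!is.null(object$center))
    X <- sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
  predict_linear_readout(object$readout, X)
}

#' @export
print.diff_esn <- function(x, ...) {
  s <- x$reservoir$spec
  cat("Differential echo state network classifier\n")
  cat("  reservoir: M =", s$M, ", a =", s$a, ", rho =", s$rho,
      ", seed =", s$seed, "\n")
  cat("  readout: linear SVM (cost ", x$cost, "), ",
      length(x$levels), " classes: ", paste(x$levels, collapse = ", "),
      "\n", sep = "")
  cat("  trained on", x$n_train, "samples\n")
  invisible(x)
}

#' @export
summary.diff_esn <- function(object, ...) {
  print(object)
  invisible(object)
}
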
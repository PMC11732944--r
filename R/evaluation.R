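#' Misclassification error rate
#'
#' Fraction of positions where the predicted label differs from the truth.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @return Scalar in `[0, 1]`.
#' @examples
#' error_rate(c(1, 2, 2, 1), c(1, 2, 1, 1))  # 0.25
#' @export
error_rate <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("'y_true' and 'y_pred' differ in length", call. = FALSE)
  if (!length(y_true)) stop("empty label vectors", call. = FALSE)
  mean(as.character(y_true) != as.character(y_pred))
}

#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, ties counted half — i.e. the rank-sum formulation, here
#' computed through the trapezoidal ROC integral of \pkg{pROC} with a fixed
#' score direction (higher score = more positive), so values below 0.5 are
#' reported as such rather than silently flipped.
#'
#' @param y_true binary labels; both classes must be present.
#' @param scores numeric scores, higher meaning more likely positive.
#' @param positive the positive label; default the last factor level of
#'   `y_true` (for cohorts generated here: `"case"`).
#' @return Scalar AUC in `[0, 1]`.
#' @export
roc_auc <- function(y_true, scores, positive = NULL) {
  y <- droplevels(as.factor(y_true))
  if (nlevels(y) != 2L)
    stop("AUC is undefined unless exactly two classes are present",
         call. = FALSE)
  if (length(scores) != length(y))
    stop("'scores' and 'y_true' differ in length", call. = FALSE)
  lev <- levels(y)
  if (is.null(positive)) positive <- lev[length(lev)]
  negative <- setdiff(lev, positive)
  r <- pROC::roc(response = y, predictor = as.numeric(scores),
                 levels = c(negative, positive), direction = "<",
                 quiet = TRUE)
  as.numeric(pROC::auc(r))
}

new_esn_eval <- function(metric, values, config = list(), extra = list()) {
  v <- if (is.matrix(values)) values else matrix(values, ncol = 1L,
    dimnames = list(NULL, metric))
  stats <- apply(v, 2L, mean_ci)
  structure(c(list(metric = metric, values = v,
                   mean = stats["mean", ], ci_lower = stats["lower", ],
                   ci_upper = stats["upper", ], n_runs = nrow(v),
                   config = config), extra),
            class = "esn_eval")
}

#' @export
print.esn_eval <- function(x, digits = 3, ...) {
  cat("Evaluation report:", x$metric, "over", x$n_runs, "runs\n")
  nm <- colnames(x$values)
  for (j in seq_along(x$mean))
    cat(sprintf("  %-12s mean %.*f  (95%% CI %.*f - %.*f)\n",
                nm[j], digits, x$mean[j], digits,
                x$ci_lower[j], digits, x$ci_upper[j]))
  if (!is.null(x$n_redraws) && x$n_redraws > 0L)
    cat("  (", x$n_redraws, " degenerate split(s) redrawn)\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.esn_eval <- function(x, ...) {
  data.frame(run = seq_len(x$n_runs), x$values, check.names = FALSE)
}

#' Seed-robustness protocol for the Diff-ESN
#'
#' Re-runs the full Diff-ESN pipeline once per reservoir seed — new random
#' input and recurrent connections every time — and reports the test error
#' rate distribution with its mean and normal-approximation 95% confidence
#' interval. Optionally perturbs the test set with Gaussian noise whose SD
#' is `noise_scale` times the maximum absolute training observation
#' (the noise-robustness protocol), with fresh noise per run.
#'
#' @param train,test lists with elements `x` and `y`, as returned by
#'   [gen_regular()] or [read_regular()].
#' @param n_seeds number of reservoir seeds (default 50).
#' @param seeds optional explicit integer seed vector (overrides
#'   `n_seeds`); the report is reproducible given the seed list.
#' @param noise_scale test-noise multiplier (default 0 = no noise).
#' @param M,a,rho,cost,input_scale,scale_features passed to [diff_esn()].
#' @return An object of class `"esn_eval"` holding the per-seed error
#'   rates, their mean and 95% CI, and the configuration snapshot.
#' @examples
#' d <- gen_regular(n_per_class = 15, length = 60, seed = 1)
#' seed_robustness(d$train, d$test, n_seeds = 3, M = 20)
#' @export
seed_robustness <- function(train, test, n_seeds = 50L, seeds = NULL,
                            noise_scale = 0, M = 50L, a = 0.9, rho = 0.95,
                            cost = 1, input_scale = 1,
                            scale_features = FALSE) {
  if (is.null(seeds)) {
    stopifnot_scalar(n_seeds, "n_seeds", lower = 2, integerish = TRUE)
    seeds <- seq_len(n_seeds)
  }
  errs <- vapply(seeds, function(s) {
    fit <- diff_esn(train$x, train$y, M = M, a = a, rho = rho, seed = s,
                    cost = cost, input_scale = input_scale,
                    scale_features = scale_features)
    tx <- test$x
    if (noise_scale > 0)
      tx <- add_test_noise(tx, noise_scale, train$x, seed = s + 20011L)
    error_rate(test$y, predict(fit, tx))
  }, numeric(1L))
  new_esn_eval("error_rate", errs,
               config = list(M = M, a = a, rho = rho, cost = cost,
                             noise_scale = noise_scale, seeds = seeds))
}

#' Repeated random-split protocol for the Interp-ESN
#'
#' Splits the cohort into train/test halves at random `n_splits` times
#' (no stratification); per split, fits the Interp-ESN on the training half
#' (marker standardization recomputed on that half), predicts
#' participant-level case probabilities on the test half — optionally with
#' a `gamma`-month forecast truncation on the test side only — and records
#' the ROC AUC. Splits that land all of one class in either half cannot be
#' scored and are redrawn (counted in the report). Reservoir connections
#' are held fixed across splits so the protocol isolates split variability.
#'
#' @param x an [cohort()] object with both outcome classes.
#' @param n_splits number of random splits (default 50).
#' @param frac training fraction in `(0, 1)` (default 0.5).
#' @param gamma forecast horizon in months applied to the test side
#'   (default 0 = plain classification).
#' @param baseline if `TRUE`, also run [last_point_baseline()] on every
#'   split and report both AUC columns.
#' @param markers,tau,M,a,rho,cost,input_scale passed to [interp_esn()].
#'   Note that slope-coded (rather than level-coded) class signals are only
#'   readable from the states when the `tanh` works in its quasi-linear
#'   regime; with several markers this calls for `input_scale` well below 1.
#' @param reservoir_seed seed of the fixed reservoir (default 1).
#' @param seed seed of the split draws (default 1).
#' @return An `"esn_eval"` whose `values` has one row per split and columns
#'   `esn` (and `baseline` if requested).
#' @examples
#' ch <- gen_cohort(n = 50, seed = 1)
#' split_robustness(ch, n_splits = 3, M = 20)
#' @export
split_robustness <- function(x, n_splits = 50L, frac = 0.5, gamma = 0L,
                             baseline = FALSE, markers = NULL, tau = 4L,
                             M = 50L, a = 0.9, rho = 0.95, cost = 1,
                             input_scale = 1, reservoir_seed = 1L,
                             seed = 1L) {
  stopifnot(inherits(x, "esn_cohort"))
  stopifnot_scalar(n_splits, "n_splits", lower = 1, integerish = TRUE)
  if (frac <= 0 || frac >= 1)
    stop("'frac' must lie strictly between 0 and 1", call. = FALSE)
  n <- length(x$participants)
  oc <- cohort_outcomes(x)
  n_redraws <- 0L
  vals <- with_seed(seed, {
    out <- matrix(NA_real_, n_splits, if (baseline) 2L else 1L,
                  dimnames = list(NULL,
                                  if (baseline) c("esn", "baseline")
                                  else "esn"))
    for (s in seq_len(n_splits)) {
      repeat {
        idx <- sample.int(n, round(frac * n))
        ok <- nlevels(droplevels(oc[idx])) == 2L &&
          nlevels(droplevels(oc[-idx])) == 2L
        if (ok) break
        n_redraws <- n_redraws + 1L
      }
      tr <- subset_cohort(x, idx)
      te <- subset_cohort(x, setdiff(seq_len(n), idx))
      fit <- interp_esn(tr, markers = markers, tau = tau, M = M, a = a,
                        rho = rho, seed = reservoir_seed, cost = cost,
                        input_scale = input_scale)
      pr <- predict(fit, te, gamma = gamma)
      truth <- cohort_outcomes(te)[names(pr)]
      out[s, "esn"] <- roc_auc(truth, pr)
      if (baseline)
        out[s, "baseline"] <- last_point_baseline(tr, te, markers = markers)
    }
    out
  })
  new_esn_eval("roc_auc", vals,
               config = list(n_splits = n_splits, frac = frac,
                             gamma = gamma, tau = tau, M = M, a = a,
                             rho = rho, cost = cost,
                             input_scale = input_scale,
                             reservoir_seed = reservoir_seed, seed = seed),
               extra = list(n_redraws = n_redraws))
}

#' Last-timepoint logistic regression baseline
#'
#' The reference model the trajectory-based classifier is compared against:
#' ignore the time series entirely, take each participant's last raw visit
#' marker values (standardized with training statistics), fit a logistic
#' regression on the training participants, and score the test
#' participants by predicted case probability.
#'
#' @param train,test [cohort()] objects.
#' @param markers marker names or indices (default all).
#' @return Test ROC AUC (scalar).
#' @export
last_point_baseline <- function(train, test, markers = NULL) {
  stopifnot(inherits(train, "esn_cohort"), inherits(test, "esn_cohort"))
  if (is.null(markers)) markers <- train$marker_names
  if (is.numeric(markers)) markers <- train$marker_names[markers]
  last_rows <- function(ch) {
    m <- do.call(rbind, lapply(ch$participants, function(p)
      p$values[nrow(p$values), markers, drop = FALSE]))
    colnames(m) <- markers
    m
  }
  std <- cohort_standardizer(train, markers)
  z <- function(m) sweep(sweep(m, 2L, std$center), 2L, std$scale, "/")
  ytr <- cohort_outcomes(train)
  if (nlevels(droplevels(ytr)) != 2L)
    stop("training cohort must contain both outcome classes",
         call. = FALSE)
  positive <- train$levels[length(train$levels)]
  dtr <- data.frame(z(last_rows(train)), check.names = FALSE)
  dtr$.y <- as.integer(ytr == positive)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., family = stats::binomial(), data = dtr))
  dte <- data.frame(z(last_rows(test)), check.names = FALSE)
  p <- suppressWarnings(
    as.numeric(stats::predict(fit, newdata = dte, type = "response")))
  roc_auc(cohort_outcomes(test), p, positive = positive)
}
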
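#' Monthly linear interpolation of an irregular visit series
#'
#' Fits a piecewise-linear curve through the raw `(time, value)` points of
#' each marker and samples it at consecutive integer months since the first
#' record (months 0, 1, ..., floor(span)). No extrapolation is performed
#' beyond the last visit. Because the last screening value is of the utmost
#' clinical relevance, the exact last-visit value is additionally appended
#' as a final row whenever the last visit falls between integer months.
#'
#' @param times strictly increasing numeric visit times, in months (length
#'   `n >= 2`). Only time differences matter; the first visit defines
#'   month 0.
#' @param values `n x k` numeric matrix of marker values per visit (a
#'   vector is treated as one marker).
#' @return A list with `months` (numeric grid, starting at 0) and `values`
#'   (`length(months) x k` matrix). Knot months reproduce the raw values
#'   exactly.
#' @examples
#' interpolate_monthly(c(0, 2), matrix(c(1, 3)))$values  # 1, 2, 3
#' @export
interpolate_monthly <- function(times, values) {
  if (is.vector(values)) values <- matrix(values, ncol = 1L)
  if (length(times) < 2L)
    stop("need at least two visits to interpolate", call. = FALSE)
  if (nrow(values) != length(times))
    stop("'times' and 'values' disagree in length", call. = FALSE)
  if (anyDuplicated(times) || is.unsorted(times, strictly = TRUE))
    stop("visit times must be strictly increasing", call. = FALSE)
  rel <- times - times[1L]
  span <- rel[length(rel)]
  grid <- seq(0, floor(span + 1e-9))
  if (span - grid[length(grid)] > 1e-9) grid <- c(grid, span)
  out <- apply(values, 2L, function(v)
    stats::approx(rel, v, xout = grid, method = "linear")$y)
  list(months = grid, values = matrix(out, nrow = length(grid)))
}

#' Skip-sampling index selection
#'
#' Selects the time-step indices retained when stacking reservoir states
#' into the design matrix: starting from the last index `n` and stepping
#' backwards by `tau`, truncated at the smallest index `>= 1`, returned in
#' increasing order. The last index `n` is always retained, because the
#' most recent observation carries the most relevant information.
#'
#' @param n sequence length (positive integer).
#' @param tau skip step, integer `>= 1`. `tau = 1` keeps every index.
#' @return Increasing integer vector of selected indices; `ceiling(n / tau)`
#'   of them, always ending in `n`.
#' @examples
#' skip_select(10, 4)  # 2 6 10
#' @export
skip_select <- function(n, tau) {
  stopifnot_scalar(n, "n", lower = 1, integerish = TRUE)
  stopifnot_scalar(tau, "tau", lower = 1, integerish = TRUE)
  rev(seq.int(from = as.integer(n), to = 1L, by = -as.integer(tau)))
}

# per-marker standardization statistics pooled over all raw visit rows
cohort_standardizer <- function(x, markers) {
  all_rows <- do.call(rbind, lapply(x$participants, function(p)
    p$values[, markers, drop = FALSE]))
  ctr <- colMeans(all_rows)
  scl <- apply(all_rows, 2L, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  list(center = ctr, scale = scl)
}

# interpolated + standardized monthly matrix for one participant
monthly_values <- function(p, markers, std) {
  ip <- interpolate_monthly(p$times, p$values[, markers, drop = FALSE])
  ip$values <- sweep(sweep(ip$values, 2L, std$center), 2L, std$scale, "/")
  ip
}

#' Interpolation echo state network classifier
#'
#' Fits the Interp-ESN classifier for irregular longitudinal series such as
#' screening biomarker trajectories. Each participant's markers are
#' standardized (per-marker z-score, training statistics), linearly
#' interpolated and resampled at monthly resolution since their first
#' record, and driven through a fixed random reservoir (state reset to zero
#' per participant). The per-month internal states are stacked into a
#' design matrix using skip sampling: every `tau`-th state counting
#' backwards from the last month, the last state always retained. Each
#' retained row inherits the participant's outcome, and a linear SVM with a
#' calibrated sigmoid probability output is trained on the stacked rows.
#'
#' Prediction ([predict.interp_esn()]) reports, per participant, the
#' positive-class probability of the last retained row — the state that has
#' seen the whole (possibly truncated) history.
#'
#' @param x an [cohort()] object with a binary outcome. The first factor
#'   level is the control class, the last the positive (case) class.
#' @param markers marker names (or indices) to use; default all.
#' @param tau skip-sampling step, integer `>= 1` and at most the shortest
#'   monthly sequence length in `x`. Default 4; values 3-6 are sensible for
#'   tumour-marker screening given typical tumour doubling times of a few
#'   months.
#' @param M,a,rho,seed,input_scale,density reservoir hyperparameters; see
#'   [reservoir_spec()].
#' @param cost linear SVM regularisation weight (default 1).
#' @param calib_folds folds for the seeded Platt calibration CV (default 5).
#' @return An object of class `"interp_esn"`.
#' @examples
#' ch <- gen_cohort(n = 60, seed = 1)
#' fit <- interp_esn(ch, M = 20, seed = 1)
#' head(predict(fit, ch))
#' @seealso [split_robustness()] for the repeated random split protocol,
#'   [last_point_baseline()] for the logistic baseline.
#' @export
interp_esn <- function(x, markers = NULL, tau = 4L, M = 50L, a = 0.9,
                       rho = 0.95, seed = 1L, cost = 1, input_scale = 1,
                       density = 1, calib_folds = 5L) {
  stopifnot(inherits(x, "esn_cohort"))
  if (is.null(markers)) markers <- x$marker_names
  if (is.numeric(markers)) markers <- x$marker_names[markers]
  oc <- cohort_outcomes(x)
  if (nlevels(droplevels(oc)) != 2L)
    stop("training cohort must contain exactly two outcome classes",
         call. = FALSE)
  positive <- x$levels[length(x$levels)]

  std <- cohort_standardizer(x, markers)
  spec <- reservoir_spec(M = M, a = a, rho = rho, k = length(markers),
                         seed = seed, input_scale = input_scale,
                         density = density)
  w <- build_reservoir(spec)

  blocks <- lapply(x$participants, function(p) {
    ip <- monthly_values(p, markers, std)
    states <- run_sequence(ip$values, w)
    sel <- skip_select(nrow(states), tau)
    list(X = states[sel, , drop = FALSE], months = ip$months[sel],
         id = p$id, outcome = p$outcome, m = nrow(states))
  })
  n_min <- min(vapply(blocks, `[[`, 0L, "m"))
  if (tau > n_min)
    stop("tau = ", tau, " exceeds the shortest monthly sequence length (",
         n_min, ") in the cohort", call. = FALSE)
  X <- do.call(rbind, lapply(blocks, `[[`, "X"))
  yrow <- factor(unlist(lapply(blocks, function(b)
    rep(b$outcome, nrow(b$X)))), levels = x$levels)
  row_index <- data.frame(
    id = unlist(lapply(blocks, function(b) rep(b$id, nrow(b$X)))),
    month = unlist(lapply(blocks, `[[`, "months")))

  readout <- fit_linear_readout(X, yrow, cost = cost)
  calib <- platt_calibrate(X, yrow, positive, cost,
                           seed = seed + 77L, nfolds = calib_folds)
  structure(
    list(reservoir = w, readout = readout, calibration = calib,
         center = std$center, scale = std$scale, markers = markers,
         tau = as.integer(tau), levels = x$levels, positive = positive,
         n_train = length(blocks), n_rows = nrow(X),
         row_index = row_index, call = match.call()),
    class = "interp_esn")
}

#' Predict participant-level case probabilities from an Interp-ESN fit
#'
#' Applies the trained pipeline to a cohort: standardize with the training
#' statistics, interpolate monthly, run the reservoir (reset per
#' participant), skip-sample the states, score the retained rows with the
#' calibrated linear SVM. The participant's prediction is the positive-class
#' probability at the last retained row.
#'
#' With `gamma > 0` the function forecasts `gamma` months ahead: only the
#' first `m_i - gamma` monthly rows of each participant enter the reservoir,
#' so the prediction uses no information from the last `gamma` months.
#' Participants whose truncated series would be empty (`m_i <= gamma`) are
#' excluded and reported in the `"excluded"` attribute.
#'
#' @param object an [interp_esn()] fit.
#' @param newdata an [cohort()] object with the same markers.
#' @param gamma forecasting horizon in months (non-negative integer;
#'   0 = classify on the full series).
#' @param per_row if `TRUE`, return a data frame with one row per retained
#'   state (`id`, `month`, `prob`) instead of the participant summary.
#' @param ... unused.
#' @return Named numeric vector of positive-class probabilities, one per
#'   included participant (names are participant ids), with attribute
#'   `"excluded"` listing the ids dropped by the forecast truncation.
#' @export
predict.interp_esn <- function(object, newdata, gamma = 0L,
                               per_row = FALSE, ...) {
  stopifnot(inherits(newdata, "esn_cohort"))
  stopifnot_scalar(gamma, "gamma", lower = 0, integerish = TRUE)
  std <- list(center = object$center, scale = object$scale)
  probs <- numeric(0); excluded <- character(0)
  rows <- list()
  for (p in newdata$participants) {
    ip <- monthly_values(p, object$markers, std)
    m <- nrow(ip$values)
    keep <- m - gamma
    if (keep < 1L) { excluded <- c(excluded, as.character(p$id)); next }
    vals <- ip$values[seq_len(keep), , drop = FALSE]
    states <- run_sequence(vals, object$reservoir)
    sel <- skip_select(keep, object$tau)
    dv <- svm_decision_readout(object, states[sel, , drop = FALSE])
    pr <- platt_predict(object$calibration, dv)
    probs[as.character(p$id)] <- pr[length(pr)]
    if (per_row)
      rows[[length(rows) + 1L]] <- data.frame(
        id = p$id, month = ip$months[sel], prob = pr)
  }
  if (!length(probs) && !per_row)
    stop("forecast horizon gamma = ", gamma,
         " leaves no usable participants", call. = FALSE)
  if (per_row) return(do.call(rbind, rows))
  attr(probs, "excluded") <- excluded
  probs
}

# decision values of the (binary) readout, oriented to the positive class
svm_decision_readout <- function(object, X) {
  svm_decision(object$readout$fit, X, object$positive)
}

#' @export
print.interp_esn <- function(x, ...) {
  s <- x$reservoir$spec
  cat("Interpolation echo state network classifier\n")
  cat("  reservoir: M =", s$M, ", a =", s$a, ", rho =", s$rho,
      ", seed =", s$seed, "\n")
  cat("  markers:", paste(x$markers, collapse = ", "), "\n")
  cat("  skip sampling tau =", x$tau, "-> design matrix", x$n_rows,
      "rows from", x$n_train, "participants\n")
  cat("  readout: linear SVM + sigmoid calibration; positive class:",
      x$positive, "\n")
  invisible(x)
}

#' @export
summary.interp_esn <- function(object, ...) {
  print(object)
  invisible(object)
}
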
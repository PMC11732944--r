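#' Generate a regular burst-classification dataset
#'
#' Simulates the data structure the Diff-ESN targets: equal-length,
#' regularly sampled series whose classes differ in the timing and
#' magnitude of abrupt local change. Each sample is Gaussian baseline noise
#' whose standard deviation is multiplied by a class-specific amplitude
#' inside the class's burst window — a quiet baseline with one localized
#' high-variance episode, the shape z-normalised benchmark series with a
#' single active region take.
#'
#' Defaults (two classes, `T = 100`, baseline SD 0.1, 30-step bursts in
#' disjoint windows with amplitude multipliers 6 and 12) put the
#' between-class contrast in burst variance well above its within-sample
#' sampling error, so the classes are reliably separable by the variance
#' hallmark while remaining heavily overlapped pointwise.
#'
#' @param n_per_class samples per class in each of train and test.
#' @param length series length `T`.
#' @param k number of features per series (default 1); features are
#'   independent draws sharing the class archetype.
#' @param classes list of class archetypes, each a list with `window`
#'   (integer `c(start, end)` within `[1, T]`), `amplitude` (extra noise-SD
#'   multiplier inside the window, `>= 0`) and optionally `sd` (baseline
#'   noise SD, default `baseline_sd`). The default archetypes place the two
#'   bursts in the disjoint windows `[0.16 T, 0.45 T]` and
#'   `[0.56 T, 0.85 T]` with amplitudes 5 and 11.
#' @param baseline_sd default baseline noise SD (> 0).
#' @param seed RNG seed; the generator is bit-reproducible and leaves the
#'   caller's RNG stream untouched.
#' @return A list with elements `train` and `test`, each a list holding `x`
#'   (`N x T` matrix, or `N x T x k` array for `k > 1`) and `y` (factor of
#'   class labels `"1"`, `"2"`, ...). Train and test are disjoint draws.
#' @examples
#' d <- gen_regular(n_per_class = 5, length = 50, seed = 1)
#' dim(d$train$x); table(d$train$y)
#' @export
gen_regular <- function(n_per_class = 100L, length = 100L, k = 1L,
                        classes = NULL, baseline_sd = 0.1, seed = 1L) {
  stopifnot_scalar(n_per_class, "n_per_class", lower = 1, integerish = TRUE)
  stopifnot_scalar(length, "length", lower = 2, integerish = TRUE)
  if (is.null(classes))
    classes <- list(
      list(window = pmax(1L, round(c(0.16, 0.45) * length)), amplitude = 5),
      list(window = pmax(1L, round(c(0.56, 0.85) * length)), amplitude = 11))
  stopifnot_scalar(baseline_sd, "baseline_sd",
                   lower = .Machine$double.eps)
  C <- base::length(classes)
  stopifnot(C >= 2L)
  for (cl in classes) {
    if (any(cl$window < 1L) || any(cl$window > length) ||
        cl$window[1L] > cl$window[2L])
      stop("burst window must lie within [1, T]", call. = FALSE)
    if (cl$amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  }
  gen_half <- function() {
    N <- C * n_per_class
    y <- factor(rep(seq_len(C), each = n_per_class))
    x <- array(0, dim = c(N, length, k))
    for (i in seq_len(N)) {
      cl <- classes[[as.integer(y[i])]]
      sd_i <- if (is.null(cl$sd)) baseline_sd else cl$sd
      mult <- rep(1, length)
      mult[cl$window[1L]:cl$window[2L]] <- 1 + cl$amplitude
      for (f in seq_len(k))
        x[i, , f] <- sd_i * mult * stats::rnorm(length)
    }
    if (k == 1L) x <- matrix(x, N, length)
    list(x = x, y = y)
  }
  with_seed(seed, list(train = gen_half(), test = gen_half()))
}

#' Generate an irregular screening cohort
#'
#' Simulates the structure of a longitudinal cancer-screening biomarker
#' dataset: participants with a small, uneven number of visits at irregular
#' intervals, several standardized markers, and a binary outcome. Controls
#' fluctuate around a participant-specific baseline. Cases follow the same
#' model until an onset point anchored to their *last* visit, after which
#' the affected markers rise linearly — emulating tumour-marker risk rising
#' towards diagnosis, so that forecasting a few months before the last
#' record still has signal to find.
#'
#' With `slope_only = TRUE` the rise is re-parameterised so that cases rise
#' *up to* their participant baseline at the last visit: the last-visit
#' marginal distribution is then identical between cases and controls by
#' construction, and the only case/control separation is in the trajectory
#' slope. This variant is the testbed on which a last-timepoint model is
#' blind but a trajectory model is not.
#'
#' @param n number of participants (default 222, a typical screening
#'   case-control cohort size after single-visit exclusions).
#' @param case_fraction fraction of cases in `(0, 1)` (default 1/3).
#' @param n_markers number of markers (default 6).
#' @param visit_range integer range `c(min, max)` of visits per participant,
#'   drawn uniformly (default 2 to 6).
#' @param gap_range inter-visit gap range in months, drawn uniformly
#'   (default 4 to 14 months, i.e. roughly annual screening with jitter).
#' @param affected indices of the markers that carry the case signal
#'   (default the first 3).
#' @param onset months before the last visit at which the case rise starts
#'   (default 18).
#' @param rise rise rate in standardized units per month on the affected
#'   markers (default 0.15).
#' @param anchor_sd SD of the participant-and-marker specific baseline
#'   (default 0.7).
#' @param noise_sd SD of the per-visit measurement noise (default 0.7).
#' @param slope_only see above (default `FALSE`).
#' @param seed RNG seed; bit-reproducible, caller's RNG untouched.
#' @return An [cohort()] object with outcome levels
#'   `c("control", "case")`.
#' @examples
#' ch <- gen_cohort(n = 40, seed = 2)
#' ch
#' @export
gen_cohort <- function(n = 222L, case_fraction = 1 / 3, n_markers = 6L,
                       visit_range = c(2L, 6L), gap_range = c(4, 14),
                       affected = 1:3, onset = 18, rise = 0.15,
                       anchor_sd = 0.7, noise_sd = 0.7,
                       slope_only = FALSE, seed = 1L) {
  stopifnot_scalar(n, "n", lower = 2, integerish = TRUE)
  stopifnot_scalar(case_fraction, "case_fraction",
                   lower = 1e-9, upper = 1 - 1e-9)
  stopifnot_scalar(n_markers, "n_markers", lower = 1, integerish = TRUE)
  stopifnot(length(visit_range) == 2L, visit_range[1L] >= 2L,
            visit_range[2L] >= visit_range[1L])
  stopifnot(length(gap_range) == 2L, gap_range[1L] > 0,
            gap_range[2L] >= gap_range[1L])
  stopifnot(all(affected >= 1L), all(affected <= n_markers))

  n_case <- max(1L, round(n * case_fraction))
  df <- with_seed(seed, {
    rows <- vector("list", n)
    status <- rep(c("case", "control"), c(n_case, n - n_case))
    nv_choices <- seq.int(visit_range[1L], visit_range[2L])
    for (i in seq_len(n)) {
      nv <- nv_choices[sample.int(length(nv_choices), 1L)]
      gaps <- stats::runif(nv - 1L, gap_range[1L], gap_range[2L])
      tm <- cumsum(c(0, gaps))
      anchor <- stats::rnorm(n_markers, 0, anchor_sd)
      vals <- matrix(stats::rnorm(nv * n_markers, 0, noise_sd),
                     nv, n_markers)
      vals <- sweep(vals, 2L, anchor, "+")
      if (status[i] == "case") {
        t_last <- tm[nv]
        for (j in affected) {
          if (slope_only) {
            # rise up to the baseline at the last visit: last-visit
            # marginals match controls, only the slope separates
            vals[, j] <- vals[, j] - rise * (t_last - tm)
          } else {
            vals[, j] <- vals[, j] + rise * pmax(0, tm - (t_last - onset))
          }
        }
      }
      rows[[i]] <- data.frame(id = sprintf("P%03d", i), time = tm,
                              vals, outcome = status[i])
    }
    do.call(rbind, rows)
  })
  names(df)[3:(2 + n_markers)] <- paste0("marker_", seq_len(n_markers))
  cohort(df, outcome_levels = c("control", "case"))
}

#' Add calibrated Gaussian noise to a test set
#'
#' Perturbs every observation of a regular test set with i.i.d. Gaussian
#' noise whose standard deviation is `scale` times the maximum absolute
#' observation in the training set — the convention used by the
#' noise-robustness protocol, which ties the perturbation to the data's own
#' dynamic range.
#'
#' @param x test series (`N x T` matrix or `N x T x k` array).
#' @param scale non-negative noise scale multiplier; 0 returns `x`
#'   unchanged.
#' @param train_ref the training series the noise SD is calibrated on.
#' @param seed RNG seed for the noise draws.
#' @return The perturbed array, with the applied SD in attribute `"sigma"`.
#' @examples
#' d <- gen_regular(n_per_class = 3, length = 20, seed = 1)
#' noisy <- add_test_noise(d$test$x, 0.05, d$train$x, seed = 9)
#' attr(noisy, "sigma")
#' @export
add_test_noise <- function(x, scale, train_ref, seed = 1L) {
  stopifnot_scalar(scale, "scale", lower = 0)
  sigma <- scale * max(abs(train_ref))
  if (scale == 0) {
    attr(x, "sigma") <- 0
    return(x)
  }
  noise <- with_seed(seed, stats::rnorm(base::length(x), 0, sigma))
  out <- x + array(noise, dim = dim(x))
  attr(out, "sigma") <- sigma
  out
}
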
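# Linear SVM readout helpers (wrapping e1071/libsvm) plus Platt-style
# sigmoid calibration. The multiclass scheme is one-vs-rest, built
# explicitly on top of binary libsvm fits.

# libsvm orients the decision value towards whichever class it saw first in
# the training data; normalize so that positive values mean `positive`.
orient_dv <- function(dv, positive) {
  cn <- colnames(dv)[1L]
  sgn <- if (startsWith(cn, paste0(positive, "/"))) 1 else -1
  sgn * dv[, 1L]
}

svm_binary <- function(X, y01, positive, cost) {
  # y01: factor with the positive class as one of its two levels
  e1071::svm(X, y01, kernel = "linear", cost = cost, scale = FALSE)
}

svm_decision <- function(fit, X, positive) {
  p <- stats::predict(fit, X, decision.values = TRUE)
  orient_dv(attr(p, "decision.values"), positive)
}

# One-vs-rest linear SVM for C >= 2 classes (single machine when C == 2).
fit_linear_readout <- function(X, y, cost = 1) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L)
    stop("training labels contain a single class; cannot fit a classifier",
         call. = FALSE)
  lev <- levels(y)
  if (nlevels(y) == 2L) {
    fit <- svm_binary(X, y, lev[2L], cost)
    structure(list(kind = "binary", fit = fit, levels = lev, cost = cost),
              class = "linear_readout")
  } else {
    fits <- lapply(lev, function(l) {
      yb <- factor(ifelse(y == l, l, ".rest"), levels = c(l, ".rest"))
      svm_binary(X, yb, l, cost)
    })
    names(fits) <- lev
    structure(list(kind = "ovr", fit = fits, levels = lev, cost = cost),
              class = "linear_readout")
  }
}

predict_linear_readout <- function(object, X) {
  lev <- object$levels
  if (object$kind == "binary") {
    factor(as.character(stats::predict(object$fit, X)), levels = lev)
  } else {
    dv <- vapply(lev, function(l) svm_decision(object$fit[[l]], X, l),
                 numeric(nrow(X)))
    factor(lev[max.col(dv, ties.method = "first")], levels = lev)
  }
}

# Platt-style sigmoid calibration: decision values are computed out-of-fold
# by seeded k-fold cross-validation, then a logistic sigmoid is fitted to
# (decision value, class) pairs. Returns the glm fit; orientation of the
# sigmoid is data-driven, so probabilities always increase towards the
# positive class.
platt_calibrate <- function(X, y, positive, cost, seed, nfolds = 5L) {
  y <- droplevels(as.factor(y))
  n <- length(y)
  nfolds <- max(2L, min(nfolds, n))
  folds <- with_seed(seed, sample(rep_len(seq_len(nfolds), n)))
  dv <- numeric(n)
  for (f in seq_len(nfolds)) {
    hold <- folds == f
    ytr <- droplevels(y[!hold])
    if (nlevels(ytr) < 2L) {              # degenerate fold: use full-data fit
      fit <- svm_binary(X, y, positive, cost)
    } else {
      fit <- svm_binary(X[!hold, , drop = FALSE], ytr, positive, cost)
    }
    dv[hold] <- svm_decision(fit, X[hold, , drop = FALSE], positive)
  }
  z <- as.integer(y == positive)
  suppressWarnings(
    stats::glm(z ~ dv, family = stats::binomial(),
               data = data.frame(z = z, dv = dv)))
}

platt_predict <- function(calib, dv) {
  as.numeric(stats::predict(calib, newdata = data.frame(dv = dv),
                            type = "response"))
}
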
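#' Fit a probability calibrator on out-of-fold scores
#'
#' Learns a mapping from a classifier's raw scores to calibrated
#' probabilities. To avoid calibrating on scores the classifier memorized,
#' the classifier (the bundle's algorithm + hyperparameters) is refit on
#' \code{cvFolds - 1} folds and scores the held-out fold; the calibration
#' curve is fit on the pooled out-of-fold (score, label) pairs.
#' \code{"sigmoid"} is Platt scaling (logistic regression of the label on the
#' score); \code{"isotonic"} is a pool-adjacent-violators least-squares fit
#' applied as a non-decreasing step function, clamped to its fitted range
#' outside the observed support.
#'
#' @param model a [TrainedTargetModel-class] (supplies algorithm,
#'   hyperparameters and pruned descriptors).
#' @param ds the training [TargetDataset-class].
#' @param method "isotonic" (default) or "sigmoid".
#' @param cvFolds folds for out-of-fold scoring (default 5).
#' @param seed integer seed.
#' @return a [Calibrator-class].
#' @export
fitCalibrator <- function(model, ds, method = c("isotonic", "sigmoid"),
                          cvFolds = 5L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(is(model, "TrainedTargetModel"), is(ds, "TargetDataset"))
  dm <- .designMatrix(ds)
  X <- dm$X[, model@descriptorNames, drop = FALSE]
  y <- dm$y
  if (length(unique(y)) < 2L) {
    stop("both classes must be present to fit a calibrator", call. = FALSE)
  }
  a <- .ALGOS[[model@algorithm]]
  folds <- .stratifiedFolds(y, k = cvFolds, times = 1L, seed = seed)[[1L]]
  raw <- numeric(length(y))
  for (f in seq_len(cvFolds)) {
    test <- folds == f
    fit <- a$fit(X[!test, , drop = FALSE], y[!test], model@classWeight,
                 model@meta$hyperparameters, seed + f)
    raw[test] <- a$score(fit, X[test, , drop = FALSE])
  }
  fitCalibratorFromScores(raw, y, method = method,
                          provenance = list(cvFolds = cvFolds, seed = seed))
}

#' Fit a calibration curve directly from (score, label) pairs
#'
#' Lower-level companion to [fitCalibrator()] for cases where out-of-fold
#' scores are already in hand.
#'
#' @param scores raw scores in [0, 1].
#' @param labels 0/1 labels aligned to \code{scores}.
#' @param method "isotonic" or "sigmoid".
#' @param provenance list stored on the calibrator.
#' @return a [Calibrator-class].
#' @export
fitCalibratorFromScores <- function(scores, labels,
                                    method = c("isotonic", "sigmoid"),
                                    provenance = list()) {
  method <- match.arg(method)
  labels <- .toBinary(labels, "labels")
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to fit a calibrator", call. = FALSE)
  }
  fit <- if (method == "sigmoid") {
    g <- stats::glm(labels ~ scores, family = stats::binomial)
    list(coef = unname(stats::coef(g)))
  } else {
    # Tied scores are pooled (mean label, weight = count) before the
    # pool-adjacent-violators pass, which is the exact least-squares isotonic
    # solution; stats::isoreg is unweighted and would split ties.
    ux <- sort(unique(scores))
    grp <- match(scores, ux)
    ybar <- tapply(labels, grp, mean)
    wts <- tapply(labels, grp, length)
    list(x = ux, y = .pava(as.numeric(ybar), as.numeric(wts)))
  }
  new("Calibrator", method = method, fit = fit, provenance = provenance)
}

# Weighted pool-adjacent-violators: least-squares non-decreasing fit.
.pava <- function(y, w) {
  vals <- numeric(0); wts <- numeric(0); counts <- integer(0)
  for (i in seq_along(y)) {
    v <- y[i]; ww <- w[i]; cnt <- 1L
    while (length(vals) && vals[length(vals)] > v) {
      k <- length(vals)
      v <- (vals[k] * wts[k] + v * ww) / (wts[k] + ww)
      ww <- wts[k] + ww
      cnt <- counts[k] + cnt
      vals <- vals[-k]; wts <- wts[-k]; counts <- counts[-k]
    }
    vals <- c(vals, v); wts <- c(wts, ww); counts <- c(counts, cnt)
  }
  rep(vals, counts)
}

#' Apply a calibrator to raw scores
#'
#' Maps raw scores through the fitted calibration curve. Inputs are clipped
#' to [0, 1] first; an isotonic calibrator clamps queries outside its fitted
#' support to the nearest fitted value; \code{method = "none"} returns the
#' (clipped) scores unchanged.
#'
#' @param cal a [Calibrator-class].
#' @param raw numeric vector of raw scores.
#' @return calibrated probabilities in [0, 1].
#' @export
applyCalibrator <- function(cal, raw) {
  stopifnot(is(cal, "Calibrator"))
  raw <- pmin(pmax(as.numeric(raw), 0), 1)
  if (cal@method == "none") return(raw)
  if (!length(cal@fit)) stop("calibrator is not fitted", call. = FALSE)
  if (cal@method == "sigmoid") {
    co <- cal@fit$coef
    return(stats::plogis(co[1] + co[2] * raw))
  }
  f <- stats::approxfun(cal@fit$x, cal@fit$y, method = "constant",
                        f = 0, rule = 2, ties = "ordered")
  pmin(pmax(f(raw), 0), 1)
}

#' Fit the logistic stacking fusion model
#'
#' Evaluation-time comparator to Hooper fusion: a logistic regression of the
#' activity label on the similarity belief, the machine-learning belief, and
#' their interaction. The interaction coefficient lets the meta-model learn
#' the redundancy between the two beliefs and down-weight doubled evidence.
#'
#' @param b_ecfp,b_ml numeric belief vectors in [0, 1], equal length.
#' @param labels 0/1 labels.
#' @return a [StackingModel-class].
#' @export
fitStacking <- function(b_ecfp, b_ml, labels) {
  labels <- .toBinary(labels, "labels")
  if (length(b_ecfp) != length(b_ml) || length(b_ml) != length(labels)) {
    stop("belief vectors and labels must have equal length", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  g <- suppressWarnings(
    stats::glm(labels ~ b_ecfp * b_ml, family = stats::binomial))
  co <- stats::coef(g)
  co[is.na(co)] <- 0   # collinear beliefs zero out the redundant term
  new("StackingModel", coefficients = stats::setNames(
    unname(co), c("intercept", "b_ecfp", "b_ml", "b_ecfp:b_ml")))
}

#' @rdname fitStacking
#' @param model a [StackingModel-class].
#' @return \code{predictStacking()}: fused probabilities in (0, 1).
#' @export
predictStacking <- function(model, b_ecfp, b_ml) {
  stopifnot(is(model, "StackingModel"))
  co <- model@coefficients
  eta <- co[1] + co[2] * b_ecfp + co[3] * b_ml + co[4] * b_ecfp * b_ml
  stats::plogis(as.numeric(eta))
}

#' Redundancy diagnostics between two beliefs
#'
#' Quantifies how much two belief vectors duplicate each other: Spearman rank
#' correlation and mutual information estimated on a fixed 10 x 10
#' equal-width binning of the unit square, reported in bits. High values mean
#' the two evidence sources are redundant and independent-belief fusion will
#' overcount.
#'
#' @param b_ecfp,b_ml numeric vectors in [0, 1], length >= 10.
#' @return list with \code{spearman_rho} (NA when either vector is constant)
#'   and \code{mutual_information_bits}.
#' @export
redundancyDiagnostics <- function(b_ecfp, b_ml) {
  if (length(b_ecfp) != length(b_ml) || length(b_ecfp) < 10L) {
    stop("need equal-length vectors of at least 10 values", call. = FALSE)
  }
  rho <- if (stats::sd(b_ecfp) == 0 || stats::sd(b_ml) == 0) {
    message("redundancyDiagnostics: constant vector, Spearman rho undefined")
    NA_real_
  } else {
    stats::cor(b_ecfp, b_ml, method = "spearman")
  }
  cut10 <- function(v) pmin(floor(pmin(pmax(v, 0), 1) * 10), 9) + 1L
  tab <- table(factor(cut10(b_ecfp), levels = 1:10),
               factor(cut10(b_ml), levels = 1:10))
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  mi <- sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
  list(spearman_rho = rho, mutual_information_bits = max(mi, 0))
}
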
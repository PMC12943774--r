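#' Construct curve parameters
#'
#' Validated constructor for the sigmoid probability-assignment curve
#' \eqn{B(x) = F_{max} / (1 + 10^{(SC_{50} - x) \times slope})}.
#'
#' @param fMax maximum fraction active, in (0, 1].
#' @param sc50 similarity at half-maximum, in [0, 1].
#' @param slope steepness, in (0, 50].
#' @param diagnostics optional list of fit diagnostics.
#' @return a [CurveParams-class].
#' @export
curveParams <- function(fMax, sc50, slope, diagnostics = list()) {
  new("CurveParams", fMax = as.numeric(fMax), sc50 = as.numeric(sc50),
      slope = as.numeric(slope), diagnostics = diagnostics)
}

#' The published global curve parameters
#'
#' The global probability-assignment curve fitted over pooled pairs from all
#' safety-panel targets: \eqn{F_{max} = 0.842}, \eqn{SC_{50} = 0.281},
#' slope \eqn{= 3.417}. Shipped as the default similarity-to-belief mapping.
#'
#' @return a [CurveParams-class].
#' @export
defaultCurveParams <- function() curveParams(0.842, 0.281, 3.417)

#' Bin compound pairs by similarity
#'
#' Groups pairs into ten similarity bins of width 0.1 on [0, 1]; bins are
#' half-open \code{[lo, hi)} with the last bin closed at 1. A pair counts as
#' active evidence iff its class is \code{active}; inactive and random
#' (active-decoy) pairs count as non-active evidence.
#'
#' @param pairs pair data.frame with \code{similarity} filled.
#' @return data.frame with columns lo, hi, mid, n_pairs, n_active_pairs,
#'   fraction_active (NA for empty bins).
#' @export
binPairs <- function(pairs) {
  if (!NROW(pairs)) stop("empty pair list", call. = FALSE)
  s <- pairs$similarity
  if (any(is.na(s)) || any(s < 0 | s > 1)) {
    stop("pair similarities must be present and within [0, 1]", call. = FALSE)
  }
  idx <- pmin(floor(s * 10), 9) + 1L   # similarity 1.0 joins the last bin
  lo <- seq(0, 0.9, by = 0.1)
  n <- tabulate(idx, nbins = 10L)
  na <- tabulate(idx[pairs$pair_class == "active"], nbins = 10L)
  data.frame(
    lo = lo, hi = lo + 0.1, mid = lo + 0.05,
    n_pairs = n, n_active_pairs = na,
    fraction_active = ifelse(n > 0, na / n, NA_real_)
  )
}

#' Evaluate the similarity-to-belief curve
#'
#' \eqn{B_{ECFP}(x) = F_{max} / (1 + 10^{(SC_{50} - x) \times slope})}: the
#' belief that a query shares the activity of its most similar known active.
#' At \code{x = sc50} the value is exactly \code{fMax / 2}; the curve is
#' strictly increasing and bounded by (0, fMax).
#'
#' @param similarity numeric vector in [0, 1].
#' @param params a [CurveParams-class].
#' @return beliefs in (0, fMax).
#' @examples
#' bEcfp(0.281, defaultCurveParams())  # 0.421 = fMax / 2
#' @export
bEcfp <- function(similarity, params = defaultCurveParams()) {
  stopifnot(is(params, "CurveParams"))
  if (!is.numeric(similarity) || any(is.na(similarity)) ||
      any(similarity < 0 | similarity > 1)) {
    stop("similarity must be within [0, 1]", call. = FALSE)
  }
  params@fMax / (1 + 10^((params@sc50 - similarity) * params@slope))
}

#' Fit the probability-assignment curve to binned pairs
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) of per-bin fraction
#' active against the bin midpoint. Empty bins are skipped, not imputed; at
#' least four occupied bins are required (three parameters plus one).
#' Initialization is fixed (fMax = max observed fraction, sc50 = 0.5,
#' slope = 3) so the fit is deterministic. When the observed fractions are
#' flat the slope is not identifiable; the fit is returned with a
#' \code{degenerate} diagnostic flag instead of failing.
#'
#' @param bins bin data.frame from [binPairs()].
#' @param weighted weight squared residuals by per-bin pair counts
#'   (default FALSE: unweighted).
#' @return a [CurveParams-class] with fit diagnostics (residuals, bins used,
#'   convergence info, degeneracy flag).
#' @export
fitCurve <- function(bins, weighted = FALSE) {
  occ <- bins[!is.na(bins$fraction_active) & bins$n_pairs > 0, , drop = FALSE]
  if (nrow(occ) < 4L) {
    stop("need at least 4 occupied similarity bins, got ", nrow(occ),
         call. = FALSE)
  }
  x <- occ$mid
  y <- occ$fraction_active
  w <- if (weighted) occ$n_pairs else rep(1, nrow(occ))
  if (stats::sd(y) < 1e-8) {
    # Flat response: the plateau is identifiable, the midpoint and slope are
    # not. Return it as fMax with the degeneracy flagged.
    return(curveParams(min(max(mean(y), 1e-6), 1), 0.5, 1e-6,
                       diagnostics = list(
                         residuals = rep(0, nrow(occ)), rss = 0,
                         bins_used = x, n_pairs = occ$n_pairs,
                         weighted = weighted, degenerate = TRUE,
                         converged = TRUE)))
  }
  start <- list(fMax = max(max(y), 1e-3), sc50 = 0.5, slope = 3)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ fMax / (1 + 10^((sc50 - x) * slope)),
      start = start,
      lower = c(fMax = 1e-6, sc50 = 0, slope = 1e-6),
      upper = c(fMax = 1, sc50 = 1, slope = 50),
      weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    stop("curve fit did not converge: ", conditionMessage(fit),
         "; observed fractions: ", paste(signif(y, 4), collapse = ", "),
         call. = FALSE)
  }
  cf <- stats::coef(fit)
  resid <- y - cf[["fMax"]] / (1 + 10^((cf[["sc50"]] - x) * cf[["slope"]]))
  degenerate <- stats::sd(y) < 1e-8
  curveParams(cf[["fMax"]], cf[["sc50"]], cf[["slope"]],
              diagnostics = list(
                residuals = as.numeric(resid),
                rss = sum(w * resid^2),
                bins_used = x,
                n_pairs = occ$n_pairs,
                weighted = weighted,
                degenerate = degenerate,
                converged = fit$convInfo$isConv %||% TRUE
              ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Persist / load curve parameters as JSON
#'
#' Saves the three curve parameters with their fit diagnostics and the
#' fingerprint settings they were derived under; loading restores a
#' [CurveParams-class] and the provenance list.
#'
#' @param params a [CurveParams-class].
#' @param path JSON path.
#' @param fingerprint optional list recording radius/nBits provenance.
#' @return \code{path} (save) or a [CurveParams-class] (load).
#' @export
saveCurve <- function(params, path, fingerprint = list()) {
  stopifnot(is(params, "CurveParams"))
  jsonlite::write_json(
    list(f_max = params@fMax, sc50 = params@sc50, slope = params@slope,
         diagnostics = params@diagnostics, fingerprint = fingerprint),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveCurve
#' @export
loadCurve <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  curveParams(obj$f_max, obj$sc50, obj$slope,
              diagnostics = as.list(obj$diagnostics))
}
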
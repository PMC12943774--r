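#' Accessors for package classes
#'
#' Small accessor generics so user code never reaches into slots:
#' \code{targetId()} works on datasets, libraries and trained models;
#' \code{records()} returns a dataset's record table; \code{fMax()},
#' \code{sc50()} and \code{curveSlope()} read curve parameters;
#' \code{nActives()} counts servable library entries.
#'
#' @param x an object of the documented class.
#' @return the slot value (see each method).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("targetId", function(x) standardGeneric("targetId"))
#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @rdname accessors
#' @export
setGeneric("fMax", function(x) standardGeneric("fMax"))
#' @rdname accessors
#' @export
setGeneric("sc50", function(x) standardGeneric("sc50"))
#' @rdname accessors
#' @export
setGeneric("curveSlope", function(x) standardGeneric("curveSlope"))
#' @rdname accessors
#' @export
setGeneric("nActives", function(x) standardGeneric("nActives"))

#' @rdname accessors
setMethod("targetId", "TargetDataset", function(x) x@targetId)
#' @rdname accessors
setMethod("targetId", "ActiveLibrary", function(x) x@targetId)
#' @rdname accessors
setMethod("targetId", "TrainedTargetModel", function(x) x@targetId)
#' @rdname accessors
setMethod("records", "TargetDataset", function(x) x@records)
#' @rdname accessors
setMethod("fMax", "CurveParams", function(x) x@fMax)
#' @rdname accessors
setMethod("sc50", "CurveParams", function(x) x@sc50)
#' @rdname accessors
setMethod("curveSlope", "CurveParams", function(x) x@slope)
#' @rdname accessors
setMethod("nActives", "ActiveLibrary", function(x) length(x@fps))

setMethod("show", "TargetDataset", function(object) {
  rec <- object@records
  cat("TargetDataset:", object@targetId, "\n")
  cat(" ", nrow(rec), "records (",
      sum(rec$label == "active"), "active,",
      sum(rec$label == "inactive"), "inactive,",
      sum(rec$label == "decoy"), "decoy )\n")
  if (nzchar(object@provenance)) cat("  provenance:", object@provenance, "\n")
})

setMethod("show", "ECFP", function(object) {
  cat(sprintf("ECFP radius=%d nBits=%d: %d bits set\n",
              object@radius, object@nBits, length(object@bits)))
})

setMethod("show", "ActiveLibrary", function(object) {
  cat(sprintf("ActiveLibrary '%s': %d actives (ECFP radius=%d, nBits=%d)\n",
              object@targetId, length(object@fps), object@radius,
              object@nBits))
})

setMethod("show", "CurveParams", function(object) {
  cat(sprintf(
    "Probability-assignment curve: B(x) = %.4g / (1 + 10^((%.4g - x) * %.4g))\n",
    object@fMax, object@sc50, object@slope))
  if (isTRUE(object@diagnostics$degenerate)) {
    cat("  [degenerate fit: flat response, slope not identifiable]\n")
  }
})

setMethod("show", "Calibrator", function(object) {
  cat("Calibrator:", object@method,
      if (length(object@fit)) "(fitted)" else "(identity)", "\n")
})

setMethod("show", "TrainedTargetModel", function(object) {
  cat(sprintf("TrainedTargetModel '%s': %s, %d descriptors, calibrator=%s\n",
              object@targetId, object@algorithm,
              length(object@descriptorNames), object@calibrator@method))
  if (nrow(object@cvMetrics)) {
    cat(sprintf("  mean CV: acc=%.3f mcc=%.3f kappa=%.3f auc=%.3f\n",
                mean(object@cvMetrics$accuracy), mean(object@cvMetrics$mcc),
                mean(object@cvMetrics$kappa),
                mean(object@cvMetrics$auc, na.rm = TRUE)))
  }
})
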
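#' @import methods
NULL

#' TargetDataset: a curated per-target compound table
#'
#' Holds one safety-panel target's curated compound records. Each record has a
#' canonical SMILES, an optional IC50 in nM, an activity label and a source
#' tag. Records are labeled \code{active} when IC50 <= 100 nM and
#' \code{inactive} when IC50 > 100 nM; \code{decoy} records carry no IC50.
#' Records labeled inactive without an IC50 are permitted only when they were
#' retained through the low-inhibition prefilter (less than 30% inhibition at
#' the retrieval ceiling), mirroring how primary-screen non-binders enter
#' training sets.
#'
#' @slot targetId single string naming the panel target.
#' @slot records data.frame with columns \code{compound_id}, \code{smiles}
#'   (canonical), \code{ic50_nM}, \code{label}, \code{source} and the logical
#'   \code{prefilter_inactive}.
#' @slot provenance free-text notes on where the rows came from.
#'
#' @seealso [curateDataset()], [buildActiveLibrary()]
#' @export
setClass("TargetDataset",
  representation(
    targetId = "character",
    records = "data.frame",
    provenance = "character"
  ),
  prototype(targetId = NA_character_, provenance = "")
)

.validTargetDataset <- function(object) {
  msg <- character()
  req <- c("compound_id", "smiles", "ic50_nM", "label", "source",
           "prefilter_inactive")
  rec <- object@records
  if (!all(req %in% names(rec))) {
    return(paste("records must have columns:", paste(req, collapse = ", ")))
  }
  if (length(object@targetId) != 1L) msg <- c(msg, "targetId must be length 1")
  if (anyDuplicated(rec$compound_id)) {
    msg <- c(msg, "compound_id values must be unique")
  }
  if (anyDuplicated(rec$smiles)) {
    msg <- c(msg, "canonical SMILES must be unique within a dataset")
  }
  if (!all(rec$label %in% c("active", "inactive", "decoy"))) {
    msg <- c(msg, "labels must be active/inactive/decoy")
  }
  has_ic50 <- !is.na(rec$ic50_nM)
  if (any(has_ic50 & rec$ic50_nM <= 0)) {
    msg <- c(msg, "ic50_nM must be positive where present")
  }
  bad_thr <- has_ic50 &
    ((rec$label == "active") != (rec$ic50_nM <= ACTIVITY_THRESHOLD_NM))
  if (any(bad_thr & rec$label != "decoy")) {
    msg <- c(msg, "labels disagree with the 100 nM threshold")
  }
  if (any(rec$label == "decoy" & has_ic50)) {
    msg <- c(msg, "decoy records must not carry an IC50")
  }
  if (any(rec$label == "active" & !has_ic50)) {
    msg <- c(msg, "active records must carry an IC50")
  }
  if (any(rec$label == "inactive" & !has_ic50 & !rec$prefilter_inactive)) {
    msg <- c(msg, "inactive records without IC50 must be prefilter inactives")
  }
  if (length(msg)) msg else TRUE
}
setValidity("TargetDataset", .validTargetDataset)

#' ECFP: an extended-connectivity fingerprint
#'
#' A folded binary circular fingerprint. \code{bits} stores the indices of the
#' set bits (0-based, strictly increasing, all below \code{nBits}). Two
#' fingerprints are comparable only when both \code{radius} and \code{nBits}
#' agree.
#'
#' @slot bits integer vector of set-bit positions (0-based).
#' @slot radius non-negative integer neighborhood radius in bonds.
#' @slot nBits folded length; a power of two.
#' @seealso [ecfp()], [tanimoto()]
#' @export
setClass("ECFP",
  representation(bits = "integer", radius = "integer", nBits = "integer")
)

setValidity("ECFP", function(object) {
  msg <- character()
  if (length(object@radius) != 1L || object@radius < 0L) {
    msg <- c(msg, "radius must be a single non-negative integer")
  }
  n <- object@nBits
  if (length(n) != 1L || n < 1L || bitwAnd(n, n - 1L) != 0L) {
    msg <- c(msg, "nBits must be a single power of two")
  }
  b <- object@bits
  if (length(b) && (is.unsorted(b, strictly = TRUE) || b[1L] < 0L ||
                    b[length(b)] >= n)) {
    msg <- c(msg, "bits must be strictly increasing 0-based indices < nBits")
  }
  if (length(msg)) msg else TRUE
})

#' ActiveLibrary: fingerprinted known actives for one target
#'
#' The per-target similarity-search library: every active-labeled compound of
#' a curated dataset with its precomputed fingerprint. Queries are compared
#' against this library to obtain the best Tanimoto similarity, the nearest
#' active neighbor and the applicability-domain decision.
#'
#' @slot targetId single string.
#' @slot ids compound identifiers, parallel to \code{fps}.
#' @slot smiles canonical SMILES, parallel to \code{fps}.
#' @slot fps list of [ECFP-class] objects sharing one (radius, nBits).
#' @slot radius,nBits fingerprint settings common to all entries.
#' @seealso [buildActiveLibrary()], [maxSimilarityToLibrary()]
#' @export
setClass("ActiveLibrary",
  representation(
    targetId = "character",
    ids = "character",
    smiles = "character",
    fps = "list",
    radius = "integer",
    nBits = "integer"
  )
)

setValidity("ActiveLibrary", function(object) {
  msg <- character()
  n <- length(object@fps)
  if (length(object@ids) != n || length(object@smiles) != n) {
    msg <- c(msg, "ids, smiles and fps must have equal length")
  }
  if (n == 0L) msg <- c(msg, "library must be non-empty to be servable")
  ok <- vapply(object@fps, function(fp) {
    is(fp, "ECFP") && fp@radius == object@radius && fp@nBits == object@nBits
  }, logical(1))
  if (n && !all(ok)) {
    msg <- c(msg, "all fingerprints must match the library's radius/nBits")
  }
  if (length(msg)) msg else TRUE
})

#' CurveParams: the sigmoid probability-assignment curve
#'
#' Parameters of the similarity-to-belief curve
#' \deqn{B_{ECFP}(x) = F_{max} / (1 + 10^{(SC_{50} - x) \times slope})}
#' where \eqn{x} is an ECFP Tanimoto similarity in [0,1]. \code{fMax} is the
#' maximum fraction-active, \code{sc50} the similarity at half-maximum and
#' \code{slope} the steepness. The published global fit over pooled
#' safety-panel pairs is (0.842, 0.281, 3.417); see [defaultCurveParams()].
#'
#' @slot fMax maximum fraction active, in (0, 1].
#' @slot sc50 similarity at half of \code{fMax}, in [0, 1].
#' @slot slope positive steepness, at most 50.
#' @slot diagnostics list of fit diagnostics (residuals, bins used, flags);
#'   empty for hand-constructed parameter sets.
#' @seealso [fitCurve()], [bEcfp()]
#' @export
setClass("CurveParams",
  representation(fMax = "numeric", sc50 = "numeric", slope = "numeric",
                 diagnostics = "list"),
  prototype(diagnostics = list())
)

setValidity("CurveParams", function(object) {
  msg <- character()
  if (length(object@fMax) != 1L || is.na(object@fMax) ||
      object@fMax <= 0 || object@fMax > 1) {
    msg <- c(msg, "fMax must be a single value in (0, 1]")
  }
  if (length(object@sc50) != 1L || is.na(object@sc50) ||
      object@sc50 < 0 || object@sc50 > 1) {
    msg <- c(msg, "sc50 must be a single value in [0, 1]")
  }
  if (length(object@slope) != 1L || is.na(object@slope) ||
      object@slope <= 0 || object@slope > 50) {
    msg <- c(msg, "slope must be a single value in (0, 50]")
  }
  if (length(msg)) msg else TRUE
})

#' Calibrator: maps raw classifier scores to probabilities
#'
#' Post-hoc probability calibration of a classifier's raw class-membership
#' scores. \code{"sigmoid"} is Platt scaling (a logistic fit of the outcome on
#' the raw score); \code{"isotonic"} is a pool-adjacent-violators fit applied
#' as a non-decreasing step function; \code{"none"} is the identity. Fit on
#' out-of-fold scores so the mapping never sees scores the classifier was
#' trained on.
#'
#' @slot method one of "sigmoid", "isotonic", "none".
#' @slot fit method-specific fitted representation.
#' @slot provenance list recording folds and seed used for fitting.
#' @seealso [fitCalibrator()], [applyCalibrator()]
#' @export
setClass("Calibrator",
  representation(method = "character", fit = "list", provenance = "list"),
  prototype(method = "none", fit = list(), provenance = list())
)

setValidity("Calibrator", function(object) {
  if (!object@method %in% c("sigmoid", "isotonic", "none")) {
    "method must be one of sigmoid/isotonic/none"
  } else TRUE
})

#' StackingModel: logistic fusion of two beliefs with interaction
#'
#' A logistic meta-model over the similarity belief, the machine-learning
#' belief and their product, used as an evaluation-time comparator to
#' Hooper-rule fusion. The interaction term lets the meta-model down-weight
#' redundant evidence.
#'
#' @slot coefficients named numeric vector: intercept, b_ecfp, b_ml,
#'   b_ecfp:b_ml.
#' @seealso [fitStacking()], [predictStacking()]
#' @export
setClass("StackingModel", representation(coefficients = "numeric"))

setValidity("StackingModel", function(object) {
  if (length(object@coefficients) != 4L) {
    "coefficients must have length 4 (intercept, b_ecfp, b_ml, interaction)"
  } else TRUE
})

#' TrainedTargetModel: per-target classifier bundle
#'
#' Everything needed to score a query against one target: the winning
#' algorithm and its fitted model, the pruned descriptor list enforced at
#' predict time, an optional calibrator, the cross-validation metrics that
#' drove selection, and the class weight applied to actives during training.
#' A bundle with \code{algorithm == "similarity-only"} has no classifier and
#' serves the similarity belief alone.
#'
#' @slot targetId single string.
#' @slot algorithm name of the selected algorithm.
#' @slot descriptorNames pruned descriptor names, fixed at train time.
#' @slot model opaque fitted classifier (NULL for similarity-only).
#' @slot calibrator a [Calibrator-class] (method "none" when uncalibrated).
#' @slot cvMetrics data.frame of per-fold accuracy, mcc, kappa, auc for the
#'   winning configuration.
#' @slot classWeight weight on the active class (n_inactive / n_active).
#' @slot meta list: hyperparameters, seed, performance-target flags.
#' @seealso [trainTargetModel()], [predictTarget()]
#' @export
setClass("TrainedTargetModel",
  representation(
    targetId = "character",
    algorithm = "character",
    descriptorNames = "character",
    model = "ANY",
    calibrator = "Calibrator",
    cvMetrics = "data.frame",
    classWeight = "numeric",
    meta = "list"
  ),
  prototype(model = NULL, calibrator = new("Calibrator"), meta = list())
)

#' SynthConfig: parameters of the synthetic study generator
#'
#' Describes a synthetic per-target compound library: scaffold families built
#' from a fixed core/substituent vocabulary, log10-normal IC50 distributions
#' for active-leaning and inactive-leaning scaffolds (base-10 log of nM), and
#' a decoy count. One seed fixes all randomness.
#'
#' @slot nScaffolds number of scaffold families.
#' @slot compoundsPerScaffold compounds enumerated per family.
#' @slot activeScaffoldFraction fraction of families drawn around the active
#'   potency mean.
#' @slot ic50LogMeanActive,ic50LogMeanInactive base-10 log10(nM) means.
#' @slot ic50LogSdActive,ic50LogSdInactive base-10 log10(nM) sds.
#' @slot nDecoys decoys to generate alongside the library.
#' @slot seed integer seed fixing all randomness.
#' @seealso [synthConfig()], [generateTargetLibrary()]
#' @export
setClass("SynthConfig",
  representation(
    nScaffolds = "integer",
    compoundsPerScaffold = "integer",
    activeScaffoldFraction = "numeric",
    ic50LogMeanActive = "numeric",
    ic50LogMeanInactive = "numeric",
    ic50LogSdActive = "numeric",
    ic50LogSdInactive = "numeric",
    nDecoys = "integer",
    seed = "integer"
  )
)

setValidity("SynthConfig", function(object) {
  msg <- character()
  if (object@nScaffolds < 1L) msg <- c(msg, "nScaffolds must be positive")
  if (object@compoundsPerScaffold < 1L) {
    msg <- c(msg, "compoundsPerScaffold must be positive")
  }
  if (object@activeScaffoldFraction < 0 || object@activeScaffoldFraction > 1) {
    msg <- c(msg, "activeScaffoldFraction must be in [0, 1]")
  }
  if (object@ic50LogSdActive <= 0 || object@ic50LogSdInactive <= 0) {
    msg <- c(msg, "log-sds must be positive")
  }
  if (object@nDecoys < 0L) msg <- c(msg, "nDecoys must be non-negative")
  if (length(object@seed) != 1L || is.na(object@seed)) {
    msg <- c(msg, "seed must be a single integer")
  }
  if (length(msg)) msg else TRUE
})
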
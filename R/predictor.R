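#' Hooper's rule: combine independent beliefs
#'
#' \eqn{joint = 1 - (1 - b_1)(1 - b_2)}: the belief that at least one of two
#' independent evidence sources supports activity. Commutative, bounded by
#' \eqn{[\max(b_1, b_2), \min(1, b_1 + b_2)]}, and monotone non-decreasing in
#' each argument, so any supporting evidence can only raise the joint belief.
#'
#' @param b1,b2 numeric vectors of beliefs in [0, 1] (recycled).
#' @return joint beliefs in [0, 1].
#' @examples
#' hooperJoint(0.421, 0.6)  # 0.7684
#' @export
hooperJoint <- function(b1, b2) {
  if (!is.numeric(b1) || !is.numeric(b2) ||
      any(is.na(b1)) || any(is.na(b2)) ||
      any(b1 < 0 | b1 > 1) || any(b2 < 0 | b2 > 1)) {
    stop("beliefs must be within [0, 1]", call. = FALSE)
  }
  1 - (1 - b1) * (1 - b2)
}

#' Predict one query against one target
#'
#' The full per-target prediction flow: fingerprint the query, find its best
#' Tanimoto similarity to the target's active library (and the neighbor
#' attaining it), gate on the applicability-domain threshold, and -- when in
#' domain -- evaluate the similarity belief from the probability-assignment
#' curve at that best similarity, the calibrated machine-learning belief from
#' the query's pruned descriptors, and their Hooper-rule fusion, reported as
#' a percentage likelihood. Out-of-domain queries still report their nearest
#' neighbor but carry no likelihood. Similarity-only bundles (and
#' \code{model = NULL}) serve \code{joint = b_ecfp} with a flag.
#'
#' @param smiles a single query SMILES.
#' @param model a [TrainedTargetModel-class], or NULL for similarity-only.
#' @param lib the target's [ActiveLibrary-class] (fingerprint settings must
#'   match the curve's provenance).
#' @param curve a [CurveParams-class].
#' @param adThreshold applicability-domain similarity cutoff in [0, 1];
#'   0.7 or higher is recommended, and 0 disables the gate.
#' @param queryId identifier echoed into the report.
#' @return one-row data.frame: query_id, smiles, target_id, in_domain,
#'   ad_threshold, likelihood_percent, b_ecfp, b_ml_raw, b_icml, joint,
#'   nn_id, nn_similarity, similarity_only, error.
#' @export
predictTarget <- function(smiles, model, lib, curve = defaultCurveParams(),
                          adThreshold = 0.7, queryId = NA_character_) {
  stopifnot(is(lib, "ActiveLibrary"), is(curve, "CurveParams"))
  .assertScalarNumber(adThreshold, "adThreshold", 0, 1)
  can <- standardizeSmiles(smiles)
  if (is.na(can)) stop("invalid SMILES: ", smiles, call. = FALSE)

  fp <- ecfp(can, radius = lib@radius, nBits = lib@nBits,
             standardize = FALSE)
  nn <- maxSimilarityToLibrary(fp, lib)
  in_domain <- nn$best_similarity >= adThreshold

  rep <- data.frame(
    query_id = queryId, smiles = as.character(can),
    target_id = lib@targetId,
    in_domain = in_domain, ad_threshold = adThreshold,
    likelihood_percent = NA_real_,
    b_ecfp = NA_real_, b_ml_raw = NA_real_, b_icml = NA_real_,
    joint = NA_real_,
    nn_id = nn$best_compound_id, nn_similarity = nn$best_similarity,
    similarity_only = FALSE, error = NA_character_,
    stringsAsFactors = FALSE
  )
  if (!in_domain) return(rep)

  b_e <- bEcfp(nn$best_similarity, curve)
  sim_only <- is.null(model) || model@algorithm == "similarity-only"
  if (sim_only) {
    rep$similarity_only <- TRUE
    rep$b_ecfp <- b_e
    rep$joint <- b_e
    rep$likelihood_percent <- round(100 * b_e, 1)
    return(rep)
  }
  X <- computeDescriptorMatrix(can)
  if (!nrow(X)) {
    stop("descriptor computation failed at the prediction stage for: ",
         smiles, call. = FALSE)
  }
  raw <- predictRawScores(model, X)
  b_ic <- applyCalibrator(model@calibrator, raw)
  joint <- hooperJoint(b_e, b_ic)
  rep$b_ecfp <- b_e
  rep$b_ml_raw <- raw
  rep$b_icml <- b_ic
  rep$joint <- joint
  rep$likelihood_percent <- round(100 * joint, 1)
  rep
}

#' Predict a batch of queries against a panel of targets
#'
#' One report row per (query, target). Failures are isolated per row: a bad
#' SMILES or a descriptor failure marks that row's \code{error} column and
#' leaves the rest of the batch intact.
#'
#' @param queries character vector of SMILES; names become query ids.
#' @param panel named list of targets, each a list with elements
#'   \code{library} (an [ActiveLibrary-class]) and \code{model} (a
#'   [TrainedTargetModel-class] or NULL).
#' @param curve a [CurveParams-class].
#' @param adThreshold applicability-domain cutoff.
#' @return data.frame with the [predictTarget()] columns, \code{nrow =
#'   length(queries) * length(panel)}.
#' @export
predictPanel <- function(queries, panel, curve = defaultCurveParams(),
                         adThreshold = 0.7) {
  if (!length(panel)) stop("panel must be non-empty", call. = FALSE)
  qids <- names(queries)
  if (is.null(qids)) qids <- paste0("query_", seq_along(queries))
  rows <- list()
  k <- 0L
  for (i in seq_along(queries)) {
    for (tgt in names(panel)) {
      k <- k + 1L
      rows[[k]] <- tryCatch(
        suppressMessages(predictTarget(
          queries[[i]], panel[[tgt]]$model, panel[[tgt]]$library,
          curve = curve, adThreshold = adThreshold, queryId = qids[i])),
        error = function(e) data.frame(
          query_id = qids[i], smiles = queries[[i]],
          target_id = tgt, in_domain = NA, ad_threshold = adThreshold,
          likelihood_percent = NA_real_, b_ecfp = NA_real_,
          b_ml_raw = NA_real_, b_icml = NA_real_, joint = NA_real_,
          nn_id = NA_character_, nn_similarity = NA_real_,
          similarity_only = NA, error = conditionMessage(e),
          stringsAsFactors = FALSE)
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
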
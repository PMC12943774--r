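# Synthetic per-target libraries with the statistical structure the method
# assumes: scaffold families (shared cores, varying substituents) so that
# within-family Tanimoto similarity is high and between-family similarity is
# low, log10-normal IC50s separated by scaffold class, and structurally
# disjoint decoys. A fixed core/substituent vocabulary is hard-coded so no
# chemistry download is needed.

# Drug-like cores for actives/inactives; each template has two substituent
# slots on distinct atoms.
.SYNTH_CORES <- c(
  benzamide      = "O=C(N%s)c1ccc(%s)cc1",
  sulfonamide    = "O=S(=O)(N%s)c1ccc(%s)cc1",
  piperazine     = "C(%s)N1CCN(c2ccc(%s)cc2)CC1",
  pyridine_amide = "O=C(N%s)c1ccc(%s)cn1",
  aryl_ether     = "C(%s)Oc1ccc(%s)cc1",
  aryl_urea      = "O=C(N%s)Nc1ccc(%s)cc1",
  thiophene_keto = "O=C(c1cccs1)C(%s)%s",
  acetanilide    = "C(%s)C(=O)Nc1ccc(%s)cc1",
  benzylamine    = "C(%s)NCc1ccc(%s)cc1"
)

# Aliphatic cores for decoys: no aromatic rings, different linkers.
.DECOY_CORES <- c(
  cyclohexane = "C(%s)C1CCC(C%s)CC1",
  diether     = "C(%s)OCCOCC%s",
  diamine     = "C(%s)CNCCNC%s",
  morpholine  = "C(%s)N1CCOC(C%s)C1",
  chain       = "C(%s)CCCCCCC%s",
  cyclopentane = "C(%s)C1CCCC1C%s"
)

.SYNTH_SUBS <- c(
  "C", "CC", "CCC", "CCCC", "CO", "CCO", "CCCO", "CN", "CCN", "CCCN",
  "C(C)C", "CC(C)C", "COC", "CCOC", "CCOCC", "CCl", "CF", "CCS", "CC#N",
  "C=C", "CC=C", "CC(O)C", "C(F)F", "CCCl", "CCF"
)

#' Construct a synthetic-study configuration
#'
#' Defaults describe the study conditions the generator emulates: 8 scaffold
#' families of 25 compounds, half the families potent (log10 IC50 centered at
#' 1.3, i.e. ~20 nM, sd 0.3) and half weak (centered at 3.2, ~1600 nM, sd
#' 0.5), 100 decoys. See [SynthConfig-class].
#'
#' @param nScaffolds scaffold families (at most
#'   \code{length(syntheticCores())}).
#' @param compoundsPerScaffold compounds per family.
#' @param activeScaffoldFraction fraction of families drawn around the active
#'   mean.
#' @param ic50LogMeanActive,ic50LogSdActive log10(nM) potency distribution of
#'   active-leaning scaffolds.
#' @param ic50LogMeanInactive,ic50LogSdInactive same for weak scaffolds.
#' @param nDecoys decoys to pair with the library.
#' @param seed integer; fixes all randomness.
#' @return a [SynthConfig-class].
#' @export
synthConfig <- function(nScaffolds = 8L, compoundsPerScaffold = 25L,
                        activeScaffoldFraction = 0.5,
                        ic50LogMeanActive = 1.3, ic50LogSdActive = 0.3,
                        ic50LogMeanInactive = 3.2, ic50LogSdInactive = 0.5,
                        nDecoys = 100L, seed = 1L) {
  new("SynthConfig",
      nScaffolds = as.integer(nScaffolds),
      compoundsPerScaffold = as.integer(compoundsPerScaffold),
      activeScaffoldFraction = activeScaffoldFraction,
      ic50LogMeanActive = ic50LogMeanActive,
      ic50LogMeanInactive = ic50LogMeanInactive,
      ic50LogSdActive = ic50LogSdActive,
      ic50LogSdInactive = ic50LogSdInactive,
      nDecoys = as.integer(nDecoys), seed = as.integer(seed))
}

#' The generator's scaffold vocabularies
#'
#' \code{syntheticCores()} returns the drug-like core templates used for
#' library scaffolds; \code{syntheticDecoyCores()} the aliphatic templates
#' reserved for decoys. Exposed mainly for documentation and tests.
#'
#' @return named character vector of SMILES templates with two substituent
#'   slots.
#' @export
syntheticCores <- function() .SYNTH_CORES

#' @rdname syntheticCores
#' @export
syntheticDecoyCores <- function() .DECOY_CORES

# Deterministically sample `n` distinct substituent combos and instantiate a
# core template.
.enumerateFamily <- function(core, n) {
  subs <- .SYNTH_SUBS
  combos <- expand.grid(a = seq_along(subs), b = seq_along(subs))
  if (n > nrow(combos)) {
    stop("compoundsPerScaffold exceeds the substituent vocabulary (",
         nrow(combos), ")", call. = FALSE)
  }
  pick <- sample.int(nrow(combos), n)
  sprintf(core, subs[combos$a[pick]], subs[combos$b[pick]])
}

#' Generate a synthetic target library
#'
#' Builds scaffold families by substituting a fixed substituent vocabulary
#' into core templates, assigns each family an active-leaning or
#' inactive-leaning potency distribution, draws log10-normal IC50s, and runs
#' the result through [curateDataset()] so labels follow the 100 nM rule.
#' Deterministic under the configuration seed. Compound ids encode the
#' scaffold (\code{S<k>_C<j>}) so structural family membership stays visible.
#'
#' @param cfg a [SynthConfig-class].
#' @param targetId name stamped on the dataset.
#' @return a curated [TargetDataset-class].
#' @export
generateTargetLibrary <- function(cfg, targetId = "SYNTH1") {
  stopifnot(is(cfg, "SynthConfig"))
  validObject(cfg)
  if (cfg@nScaffolds > length(.SYNTH_CORES)) {
    stop("nScaffolds must be <= ", length(.SYNTH_CORES), call. = FALSE)
  }
  set.seed(cfg@seed)
  nAct <- round(cfg@activeScaffoldFraction * cfg@nScaffolds)
  coreIdx <- sample.int(length(.SYNTH_CORES), cfg@nScaffolds)
  rows <- list()
  for (k in seq_len(cfg@nScaffolds)) {
    smi <- .enumerateFamily(.SYNTH_CORES[[coreIdx[k]]],
                            cfg@compoundsPerScaffold)
    potent <- k <= nAct
    mu <- if (potent) cfg@ic50LogMeanActive else cfg@ic50LogMeanInactive
    sd <- if (potent) cfg@ic50LogSdActive else cfg@ic50LogSdInactive
    ic50 <- 10^stats::rnorm(length(smi), mean = mu, sd = sd)
    rows[[k]] <- data.frame(
      compound_id = sprintf("S%d_C%02d", k, seq_along(smi)),
      smiles = smi, ic50_nM = ic50, source = "internal",
      stringsAsFactors = FALSE)
  }
  raw <- do.call(rbind, rows)
  # The generator emulates post-retrieval data: no ceiling cut, so weak-tail
  # draws above 10 uM stay in the library.
  suppressMessages(curateDataset(raw, targetId = targetId,
                                 ic50Ceiling = Inf,
                                 provenance = sprintf(
                                   "synthetic: %d scaffolds x %d, seed %d",
                                   cfg@nScaffolds, cfg@compoundsPerScaffold,
                                   cfg@seed)))
}

#' Generate structurally disjoint decoys
#'
#' Draws decoy molecules from aliphatic core families disjoint from the
#' library scaffolds and enforces, by rejection, that every decoy's maximum
#' Tanimoto similarity to any active stays below \code{maxSimilarity}
#' (default 0.4). Decoys carry no IC50 and label \code{decoy}.
#'
#' @param actives data.frame of active records with columns compound_id and
#'   smiles (canonical).
#' @param n number of decoys (>= 1).
#' @param seed integer seed.
#' @param maxSimilarity rejection ceiling on decoy-to-active similarity.
#' @param radius,nBits fingerprint settings used for the rejection test.
#' @return data.frame of decoy records (compound_id, smiles, ic50_nM = NA,
#'   label = "decoy", source = "decoy").
#' @export
generateDecoys <- function(actives, n, seed = 1L, maxSimilarity = 0.4,
                           radius = 6L, nBits = 2048L) {
  if (n < 1L) stop("n must be at least 1", call. = FALSE)
  if (!NROW(actives)) stop("actives must be non-empty", call. = FALSE)
  set.seed(seed)
  activeFps <- ecfpSet(actives$smiles, radius = radius, nBits = nBits,
                       standardize = FALSE)
  # Lazy rejection: enumerate and fingerprint candidates in chunks until n
  # are accepted or the budget (20n candidates) is spent.
  budget <- 20L * n
  perCore <- min(200L, ceiling(budget / length(.DECOY_CORES)))
  pool <- unlist(lapply(sample(.DECOY_CORES), .enumerateFamily, n = perCore),
                 use.names = FALSE)
  pool <- pool[sample.int(length(pool))]
  accepted <- character(0)
  offset <- 0L
  while (length(accepted) < n && offset < length(pool)) {
    chunk <- pool[seq.int(offset + 1L, min(offset + 2L * n, length(pool)))]
    offset <- offset + length(chunk)
    chunk <- unique(standardizeSmiles(chunk))
    chunk <- setdiff(chunk[!is.na(chunk)], accepted)
    if (!length(chunk)) next
    fps <- ecfpSet(chunk, radius = radius, nBits = nBits,
                   standardize = FALSE)
    for (i in seq_along(chunk)) {
      maxSim <- max(vapply(activeFps, tanimoto, numeric(1), a = fps[[i]]))
      if (maxSim < maxSimilarity) accepted <- c(accepted, chunk[i])
      if (length(accepted) >= n) break
    }
  }
  if (length(accepted) < n) {
    stop("decoy rejection budget exhausted: got ", length(accepted), " of ",
         n, "; consider a looser similarity ceiling", call. = FALSE)
  }
  data.frame(
    compound_id = sprintf("DEC%04d", seq_len(n)),
    smiles = accepted[seq_len(n)],
    ic50_nM = NA_real_, label = "decoy", source = "decoy",
    prefilter_inactive = FALSE, stringsAsFactors = FALSE)
}

#' End-to-end benchmark on a synthetic panel
#'
#' Runs the complete pipeline on a seeded synthetic panel: generate per-target
#' libraries, hold out a stratified fraction, build active/inactive/decoy
#' pairs from the training split, fit the global probability-assignment curve
#' on the pooled pairs, train and isotonic-calibrate a classifier per target,
#' and predict every held-out compound with the fused belief. Returns pooled
#' held-out recall (decision threshold 0.5) for the joint belief and for each
#' component belief alone -- the fusion-does-not-hurt check: the joint can
#' only flag more actives than either component.
#'
#' @param nTargets number of panel targets (default 3).
#' @param seed integer seed driving generation, splits, folds and fits.
#' @param heldoutFraction fraction of each class held out per target.
#' @param algorithms candidate roster forwarded to [trainTargetModel()].
#' @param nDecoysPerTarget decoys generated per target for curve pairs.
#' @return list: \code{recall_joint}, \code{recall_ecfp}, \code{recall_ml},
#'   \code{curve} (the fitted [CurveParams-class]), \code{n_heldout},
#'   \code{per_target} data.frame.
#' @export
benchmarkSyntheticPanel <- function(nTargets = 3L, seed = 1L,
                                    heldoutFraction = 0.3,
                                    algorithms = availableAlgorithms(),
                                    nDecoysPerTarget = 50L) {
  targets <- list()
  pairs <- list()
  for (t in seq_len(nTargets)) {
    ds <- generateTargetLibrary(synthConfig(seed = seed + t),
                                targetId = sprintf("SYNTH%d", t))
    rec <- records(ds)
    set.seed(seed + 100L + t)
    test <- unlist(lapply(split(seq_len(nrow(rec)), rec$label), function(ix) {
      sample(ix, round(heldoutFraction * length(ix)))
    }), use.names = FALSE)
    train <- newTargetDataset(rec[-test, , drop = FALSE], targetId(ds))
    trainRec <- records(train)
    fps <- ecfpSet(trainRec$smiles, standardize = FALSE)
    names(fps) <- trainRec$compound_id
    acts <- trainRec[trainRec$label == "active", , drop = FALSE]
    decoys <- generateDecoys(acts, nDecoysPerTarget, seed = seed + 200L + t)
    dfps <- ecfpSet(decoys$smiles, standardize = FALSE)
    names(dfps) <- decoys$compound_id
    tp <- rbind(makeActivePairs(train), makeInactivePairs(train),
                makeDecoyPairs(acts, decoys, nPerActive = 1L,
                               seed = seed + 300L + t,
                               targetId = targetId(ds)))
    pairs[[t]] <- addPairSimilarities(tp, c(fps, dfps))
    targets[[t]] <- list(train = train, heldout = rec[test, , drop = FALSE])
  }
  curve <- fitCurve(binPairs(do.call(rbind, pairs)))

  truth <- integer(0)
  b_e <- numeric(0); b_ml <- numeric(0); b_joint <- numeric(0)
  per_target <- list()
  for (t in seq_len(nTargets)) {
    train <- targets[[t]]$train
    heldout <- targets[[t]]$heldout
    model <- trainTargetModel(train, seed = seed + 400L + t,
                              algorithms = algorithms)
    model@calibrator <- fitCalibrator(model, train, method = "isotonic",
                                      seed = seed + 500L + t)
    lib <- buildActiveLibrary(train)
    reports <- do.call(rbind, lapply(seq_len(nrow(heldout)), function(i) {
      predictTarget(heldout$smiles[i], model, lib, curve = curve,
                    adThreshold = 0, queryId = heldout$compound_id[i])
    }))
    truth <- c(truth, as.integer(heldout$label == "active"))
    b_e <- c(b_e, reports$b_ecfp)
    b_ml <- c(b_ml, reports$b_icml)
    b_joint <- c(b_joint, reports$joint)
    per_target[[t]] <- data.frame(
      target_id = targetId(train), algorithm = model@algorithm,
      n_heldout = nrow(heldout),
      mean_cv_mcc = mean(model@cvMetrics$mcc))
  }
  rec_of <- function(b) classificationMetrics(truth, as.integer(b >= 0.5))$recall
  list(recall_joint = rec_of(b_joint), recall_ecfp = rec_of(b_e),
       recall_ml = rec_of(b_ml), curve = curve, n_heldout = length(truth),
       per_target = do.call(rbind, per_target))
}

#' Generate compound pairs directly from a curve
#'
#' The inverse of curve estimation, for parameter-recovery tests: pair
#' similarities are drawn uniformly on [0, 1] and each pair is classed active
#' with probability \eqn{B_{ECFP}(similarity)} (else inactive). Ids are
#' synthetic placeholders.
#'
#' @param params a [CurveParams-class] (the generating truth).
#' @param nPairs number of pairs (>= 100).
#' @param seed integer seed.
#' @return pair data.frame compatible with [binPairs()].
#' @export
generatePairsFromCurve <- function(params, nPairs, seed = 1L) {
  stopifnot(is(params, "CurveParams"))
  if (nPairs < 100L) stop("nPairs must be at least 100", call. = FALSE)
  set.seed(seed)
  s <- stats::runif(nPairs)
  p <- bEcfp(s, params)
  cls <- ifelse(stats::rbinom(nPairs, 1L, p) == 1L, "active", "inactive")
  data.frame(
    id_a = sprintf("P%06da", seq_len(nPairs)),
    id_b = sprintf("P%06db", seq_len(nPairs)),
    pair_class = cls, similarity = s, target_id = "curve_sim",
    stringsAsFactors = FALSE)
}
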
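# Compound-pair construction for probability-assignment-curve generation.
# A pair table has columns: id_a, id_b, pair_class, similarity, target_id.

.emptyPairs <- function() {
  data.frame(id_a = character(0), id_b = character(0),
             pair_class = character(0), similarity = numeric(0),
             target_id = character(0), stringsAsFactors = FALSE)
}

.pairEligible <- function(ds) {
  rec <- records(ds)
  rec <- rec[rec$label != "decoy", , drop = FALSE]
  noic <- is.na(rec$ic50_nM)
  if (any(noic)) {
    message("pair builder: skipping ", sum(noic),
            " records without numeric IC50 (prefilter inactives)")
    rec <- rec[!noic, , drop = FALSE]
  }
  rec
}

# Enumerate all unordered pairs satisfying `cond(label_i, label_j, dlog)`.
.enumPairs <- function(ds, pair_class, cond, maxPairs = NULL, seed = 1L) {
  rec <- .pairEligible(ds)
  n <- nrow(rec)
  if (n < 2L) return(.emptyPairs())
  lg <- log10(rec$ic50_nM)
  rows <- vector("list", 0L)
  k <- 0L
  ia <- character(0); ib <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (cond(rec$label[i], rec$label[j], abs(lg[i] - lg[j]))) {
        k <- k + 1L
        ia[k] <- rec$compound_id[i]
        ib[k] <- rec$compound_id[j]
      }
    }
  }
  if (k == 0L) return(.emptyPairs())
  out <- data.frame(id_a = ia, id_b = ib, pair_class = pair_class,
                    similarity = NA_real_, target_id = targetId(ds),
                    stringsAsFactors = FALSE)
  if (!is.null(maxPairs) && nrow(out) > maxPairs) {
    set.seed(seed)
    out <- out[sort(sample.int(nrow(out), maxPairs)), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Build active compound pairs
#'
#' An active pair is an unordered pair of compounds in which at least one
#' member is active (IC50 <= 100 nM) and the two IC50s differ by less than
#' one log10 unit (strict). Every qualifying pair is enumerated once; records
#' without a numeric IC50 are skipped with a message.
#'
#' @param ds a curated [TargetDataset-class].
#' @param maxPairs optional cap; when exceeded, a seeded subsample is kept.
#' @param seed seed for the optional cap subsampling.
#' @return pair data.frame (id_a, id_b, pair_class, similarity, target_id);
#'   similarity is NA until [addPairSimilarities()] fills it.
#' @export
makeActivePairs <- function(ds, maxPairs = NULL, seed = 1L) {
  stopifnot(is(ds, "TargetDataset"))
  .enumPairs(ds, "active",
             function(la, lb, dlog) (la == "active" || lb == "active") &&
               dlog < 1,
             maxPairs, seed)
}

#' Build inactive compound pairs
#'
#' An inactive pair has at least one member with IC50 > 100 nM and an IC50
#' difference greater than one log10 unit (strict). The active- and
#' inactive-pair rules are mutually exclusive through the opposite log10
#' conditions; pairs at exactly one log unit fall in neither class, as do
#' pairs of two inactives within one log unit.
#'
#' @inheritParams makeActivePairs
#' @return pair data.frame, \code{pair_class = "inactive"}.
#' @export
makeInactivePairs <- function(ds, maxPairs = NULL, seed = 1L) {
  stopifnot(is(ds, "TargetDataset"))
  .enumPairs(ds, "inactive",
             function(la, lb, dlog) (la == "inactive" || lb == "inactive") &&
               dlog > 1,
             maxPairs, seed)
}

#' Build random (active-decoy) pairs
#'
#' Random pairs couple one active compound with a presumed-inactive decoy and
#' populate the low-similarity end of the curve as non-active evidence. For
#' each active, \code{nPerActive} decoys are sampled without replacement
#' under the seed.
#'
#' @param actives data.frame of active records (compound_id, smiles).
#' @param decoys data.frame of decoy records (compound_id, smiles).
#' @param nPerActive decoys sampled per active (default 1).
#' @param seed integer seed.
#' @param targetId target name stamped on the pairs.
#' @return pair data.frame, \code{pair_class = "random"}.
#' @export
makeDecoyPairs <- function(actives, decoys, nPerActive = 1L, seed = 1L,
                           targetId = "target") {
  if (!NROW(actives) || !NROW(decoys)) {
    stop("actives and decoys must be non-empty", call. = FALSE)
  }
  if (nPerActive > nrow(decoys)) {
    stop("nPerActive (", nPerActive, ") exceeds the number of decoys (",
         nrow(decoys), ")", call. = FALSE)
  }
  set.seed(seed)
  rows <- lapply(seq_len(nrow(actives)), function(i) {
    pick <- sample.int(nrow(decoys), nPerActive)
    data.frame(id_a = actives$compound_id[i],
               id_b = decoys$compound_id[pick],
               pair_class = "random", similarity = NA_real_,
               target_id = targetId, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Attach Tanimoto similarities to a pair table
#'
#' Fills the \code{similarity} column using a named fingerprint list (one
#' [ECFP-class] per compound id), so every pair's similarity is computed with
#' the same fingerprint settings as the curve it feeds.
#'
#' @param pairs pair data.frame from the pair builders.
#' @param fps named list of [ECFP-class] objects covering all pair members.
#' @return \code{pairs} with \code{similarity} filled.
#' @export
addPairSimilarities <- function(pairs, fps) {
  missing <- setdiff(unique(c(pairs$id_a, pairs$id_b)), names(fps))
  if (length(missing)) {
    stop("no fingerprint for: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  pairs$similarity <- mapply(function(a, b) tanimoto(fps[[a]], fps[[b]]),
                             pairs$id_a, pairs$id_b, USE.NAMES = FALSE)
  pairs
}

#' Write / read a pair table
#'
#' CSV serialization of pair tables (id_a, id_b, pair_class, similarity,
#' target_id), used to pool per-target pairs into the global curve fit.
#'
#' @param pairs pair data.frame.
#' @param path CSV path.
#' @return \code{path} (write) or the pair data.frame (read).
#' @export
writePairs <- function(pairs, path) {
  utils::write.csv(pairs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writePairs
#' @export
readPairs <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
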
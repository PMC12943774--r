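#' Extended-connectivity fingerprint of one molecule
#'
#' Computes a folded binary circular fingerprint by iterative neighborhood
#' hashing. Each heavy atom starts from an invariant of (atomic number, heavy
#' degree, attached hydrogens, formal charge, ring membership); for each of
#' \code{radius} iterations an atom's identifier is rehashed together with its
#' neighbors' previous identifiers and bond orders, sorted so the result is
#' independent of input atom ordering. All identifiers from iterations
#' \code{0..radius} are folded modulo \code{nBits}. The default radius of 6
#' follows the reference protocol's literal "radius of six"; the alternative
#' naming convention in which "ECFP6" means diameter 6 corresponds to
#' \code{radius = 3} and is available through the same argument.
#'
#' @param smiles a single SMILES string.
#' @param radius non-negative integer neighborhood radius in bonds.
#' @param nBits folded fingerprint length; a power of two (default 2048).
#' @param standardize canonicalize the SMILES first (default TRUE), so
#'   different spellings of one molecule give bit-identical fingerprints.
#' @return an [ECFP-class] object.
#' @examples
#' identical(ecfp("OCC")@bits, ecfp("CCO")@bits)
#' @export
ecfp <- function(smiles, radius = 6L, nBits = 2048L, standardize = TRUE) {
  if (!is.character(smiles) || length(smiles) != 1L) {
    stop("'smiles' must be a single string; use ecfpSet() for vectors",
         call. = FALSE)
  }
  ecfpSet(smiles, radius = radius, nBits = nBits,
          standardize = standardize)[[1L]]
}

#' Fingerprints for a vector of molecules
#'
#' Batch companion to [ecfp()]: one conversion pass, one fingerprint per
#' input. Unparseable SMILES raise an error naming the offenders.
#'
#' @inheritParams ecfp
#' @param smiles character vector of SMILES.
#' @return named list of [ECFP-class] objects, names taken from
#'   \code{names(smiles)} when present.
#' @export
ecfpSet <- function(smiles, radius = 6L, nBits = 2048L, standardize = TRUE) {
  radius <- as.integer(radius)
  nBits <- as.integer(nBits)
  if (is.na(radius) || radius < 0L) {
    stop("'radius' must be a non-negative integer", call. = FALSE)
  }
  if (is.na(nBits) || !.isPowerOfTwo(nBits)) {
    stop("'nBits' must be a power of two", call. = FALSE)
  }
  if (standardize) {
    can <- standardizeSmiles(smiles)
    if (anyNA(can)) {
      stop("invalid SMILES: ",
           paste(attr(can, "failed"), collapse = ", "), call. = FALSE)
    }
  } else can <- smiles
  graphs <- .molGraphs(as.character(can))
  bad <- vapply(graphs, is.null, logical(1))
  if (any(bad)) {
    stop("molecule conversion failed for: ",
         paste(smiles[bad], collapse = ", "), call. = FALSE)
  }
  out <- lapply(graphs, function(g) {
    new("ECFP", bits = .ecfpBits(g, radius, nBits), radius = radius,
        nBits = nBits)
  })
  names(out) <- names(smiles)
  out
}

# Core Morgan-style iteration over a heavy-atom graph.
.ecfpBits <- function(g, radius, nBits) {
  n <- length(g$z)
  if (n == 0L) return(integer(0))
  ids <- integer(n)
  for (a in seq_len(n)) {
    ids[a] <- .hashInts(c(g$z[a], length(g$adj[[a]]), g$nH[a],
                          g$charge[a], as.integer(g$inRing[a])))
  }
  all_ids <- ids
  if (radius > 0L) {
    for (r in seq_len(radius)) {
      nxt <- integer(n)
      for (a in seq_len(n)) {
        nb <- g$adj[[a]]
        if (length(nb)) {
          o <- g$order[[a]]
          key <- order(o, ids[nb])
          flat <- as.integer(rbind(o[key], ids[nb][key]))
        } else flat <- integer(0)
        nxt[a] <- .hashInts(c(r, ids[a], flat))
      }
      ids <- nxt
      all_ids <- c(all_ids, ids)
    }
  }
  sort(unique(as.integer(unique(all_ids) %% nBits)))
}

#' Tanimoto similarity between two fingerprints
#'
#' \eqn{|A \cap B| / |A \cup B|} over set bits. Fingerprints must share radius
#' and folded length; comparing across settings is an error, not a silent
#' mismatch.
#'
#' @param a,b [ECFP-class] objects with identical radius and nBits.
#' @return similarity in [0, 1].
#' @export
tanimoto <- function(a, b) {
  stopifnot(is(a, "ECFP"), is(b, "ECFP"))
  if (a@radius != b@radius || a@nBits != b@nBits) {
    stop("fingerprints are not comparable: radius/nBits differ", call. = FALSE)
  }
  inter <- sum(a@bits %in% b@bits)
  uni <- length(a@bits) + length(b@bits) - inter
  if (uni == 0L) return(0)
  inter / uni
}

#' Build the active library for a target
#'
#' Collects every active-labeled record of a curated dataset and fingerprints
#' it, producing the similarity-search library used for nearest-neighbor
#' lookups and applicability-domain gating.
#'
#' @param ds a [TargetDataset-class].
#' @inheritParams ecfp
#' @return an [ActiveLibrary-class].
#' @export
buildActiveLibrary <- function(ds, radius = 6L, nBits = 2048L) {
  stopifnot(is(ds, "TargetDataset"))
  rec <- records(ds)
  act <- rec[rec$label == "active", , drop = FALSE]
  if (nrow(act) == 0L) {
    stop("no active compounds: target '", targetId(ds),
         "' has no servable library", call. = FALSE)
  }
  fps <- ecfpSet(act$smiles, radius = radius, nBits = nBits,
                 standardize = FALSE)
  new("ActiveLibrary", targetId = targetId(ds), ids = act$compound_id,
      smiles = act$smiles, fps = fps, radius = as.integer(radius),
      nBits = as.integer(nBits))
}

#' Best similarity of a query to a library
#'
#' Exhaustive Tanimoto scan of the active library; returns the highest
#' similarity and the identifier attaining it (ties broken by first
#' occurrence in library order). This value drives both the similarity belief
#' and the applicability-domain decision.
#'
#' @param query an [ECFP-class] or a single SMILES string.
#' @param lib an [ActiveLibrary-class].
#' @return list with \code{best_similarity} and \code{best_compound_id}.
#' @export
maxSimilarityToLibrary <- function(query, lib) {
  stopifnot(is(lib, "ActiveLibrary"))
  if (nActives(lib) == 0L) stop("empty active library", call. = FALSE)
  if (is.character(query)) {
    query <- ecfp(query, radius = lib@radius, nBits = lib@nBits)
  }
  sims <- vapply(lib@fps, tanimoto, numeric(1), a = query)
  best <- which.max(sims)
  list(best_similarity = sims[[best]], best_compound_id = lib@ids[[best]])
}

#' Mean pairwise similarity within a library
#'
#' Mean and standard deviation of Tanimoto similarity over all unordered
#' distinct pairs of library members; a low mean (the reference libraries sit
#' near 0.08) indicates a structurally diverse library.
#'
#' @param lib an [ActiveLibrary-class] with at least two entries.
#' @return named numeric vector \code{c(mean =, sd =)}.
#' @export
meanPairwiseSimilarity <- function(lib) {
  stopifnot(is(lib, "ActiveLibrary"))
  n <- nActives(lib)
  if (n < 2L) stop("need at least 2 library entries", call. = FALSE)
  sims <- numeric(n * (n - 1L) / 2L)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      k <- k + 1L
      sims[k] <- tanimoto(lib@fps[[i]], lib@fps[[j]])
    }
  }
  c(mean = mean(sims),
    sd = if (length(sims) > 1L) stats::sd(sims) else 0)
}

#' Persist and reload an active library
#'
#' \code{saveActiveLibrary()} writes a per-target directory holding a
#' compounds CSV (id, canonical_smiles), a plain-text fingerprint file (one
#' line of set-bit indices per compound) and a JSON sidecar recording radius
#' and nBits. \code{loadActiveLibrary()} validates the sidecar against the
#' requested settings before reconstructing the library.
#'
#' @param lib an [ActiveLibrary-class].
#' @param dir directory to create/read.
#' @param radius,nBits expected fingerprint settings; NULL accepts whatever
#'   the sidecar records.
#' @return the directory (save) or an [ActiveLibrary-class] (load).
#' @export
saveActiveLibrary <- function(lib, dir) {
  stopifnot(is(lib, "ActiveLibrary"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(
    data.frame(id = lib@ids, canonical_smiles = lib@smiles,
               stringsAsFactors = FALSE),
    file.path(dir, "compounds.csv"), row.names = FALSE)
  writeLines(vapply(lib@fps, function(fp) paste(fp@bits, collapse = " "),
                    character(1)),
             file.path(dir, "fingerprints.txt"))
  jsonlite::write_json(
    list(target_id = lib@targetId, radius = lib@radius, nBits = lib@nBits,
         n = nActives(lib)),
    file.path(dir, "library.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname saveActiveLibrary
#' @export
loadActiveLibrary <- function(dir, radius = NULL, nBits = NULL) {
  meta <- jsonlite::read_json(file.path(dir, "library.json"),
                              simplifyVector = TRUE)
  if (!is.null(radius) && meta$radius != radius) {
    stop("library radius ", meta$radius, " != requested ", radius,
         call. = FALSE)
  }
  if (!is.null(nBits) && meta$nBits != nBits) {
    stop("library nBits ", meta$nBits, " != requested ", nBits, call. = FALSE)
  }
  cmp <- utils::read.csv(file.path(dir, "compounds.csv"),
                         stringsAsFactors = FALSE)
  lines <- readLines(file.path(dir, "fingerprints.txt"))
  if (length(lines) != nrow(cmp)) {
    stop("fingerprint file does not match compounds.csv", call. = FALSE)
  }
  fps <- lapply(lines, function(l) {
    bits <- if (nzchar(l)) as.integer(strsplit(l, " ")[[1]]) else integer(0)
    new("ECFP", bits = bits, radius = as.integer(meta$radius),
        nBits = as.integer(meta$nBits))
  })
  new("ActiveLibrary", targetId = meta$target_id, ids = as.character(cmp$id),
      smiles = cmp$canonical_smiles, fps = fps,
      radius = as.integer(meta$radius), nBits = as.integer(meta$nBits))
}
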
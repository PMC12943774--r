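#' Standardize SMILES to canonical form
#'
#' Converts raw SMILES to OpenBabel canonical SMILES, so that different
#' spellings of one molecule collapse to a single string and stereochemistry,
#' when specified, is preserved. Unparseable inputs are not repaired: they map
#' to \code{NA}, the offending strings are attached as the \code{"failed"}
#' attribute, and a message reports them, so callers can drop them with a
#' logged reason rather than silently.
#'
#' @param smiles character vector of raw SMILES (no internal whitespace).
#' @return character vector of canonical SMILES, \code{NA} where parsing
#'   failed; attribute \code{"failed"} lists the rejected inputs.
#' @examples
#' standardizeSmiles(c("OCC", "CCO"))   # both map to "CCO"
#' @export
standardizeSmiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) == 0L) {
    stop("'smiles' must be a non-empty character vector", call. = FALSE)
  }
  if (any(is.na(smiles)) || any(!nzchar(smiles))) {
    stop("SMILES must be non-empty text", call. = FALSE)
  }
  if (any(grepl("[[:space:]]", smiles))) {
    stop("SMILES must not contain whitespace", call. = FALSE)
  }
  # Titles carry the input index so failed molecules (silently skipped by the
  # converter) can be re-aligned.
  txt <- paste0(paste(smiles, seq_along(smiles)), "\n", collapse = "")
  out <- ChemmineOB::convertFormat("SMI", "CAN", txt)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  res <- rep(NA_character_, length(smiles))
  if (length(lines)) {
    parts <- strsplit(lines, "[ \t]+")
    can <- vapply(parts, `[`, character(1), 1L)
    idx <- as.integer(vapply(parts, `[`, character(1), 2L))
    keep <- !is.na(idx) & nzchar(can)
    res[idx[keep]] <- can[keep]
  }
  failed <- smiles[is.na(res)]
  if (length(failed)) {
    message("standardizeSmiles: dropped ", length(failed),
            " unparseable SMILES: ",
            paste(utils::head(failed, 5L), collapse = ", "),
            if (length(failed) > 5L) ", ..." else "")
    attr(res, "failed") <- failed
  }
  res
}

#' Label activity from IC50
#'
#' Applies the panel activity threshold: a compound is \code{active} when its
#' IC50 is at most 100 nM and \code{inactive} otherwise.
#'
#' @param ic50_nM positive numeric vector of IC50 values in nM.
#' @return character vector of "active"/"inactive".
#' @examples
#' labelActivity(c(100, 99.9, 101))
#' @export
labelActivity <- function(ic50_nM) {
  if (!is.numeric(ic50_nM) || length(ic50_nM) == 0L) {
    stop("'ic50_nM' must be numeric", call. = FALSE)
  }
  if (any(is.na(ic50_nM)) || any(ic50_nM <= 0)) {
    stop("IC50 values must be present and positive", call. = FALSE)
  }
  ifelse(ic50_nM <= ACTIVITY_THRESHOLD_NM, "active", "inactive")
}

#' Construct a TargetDataset from a record table
#'
#' Low-level constructor; most users should call [curateDataset()]. The record
#' table must already be canonical and consistent with the labeling rules.
#'
#' @param records data.frame with columns compound_id, smiles, ic50_nM, label,
#'   source, prefilter_inactive.
#' @param targetId panel target name.
#' @param provenance free-text notes.
#' @return a [TargetDataset-class].
#' @export
newTargetDataset <- function(records, targetId, provenance = "") {
  rownames(records) <- NULL
  new("TargetDataset", targetId = as.character(targetId),
      records = records, provenance = provenance)
}

#' Curate a raw per-target compound table
#'
#' Runs the standard curation pipeline: SMILES standardization (unparseable
#' rows dropped with a logged reason), exclusion of rows above the IC50
#' retrieval ceiling (default 10,000 nM) unless they carry the low-inhibition
#' prefilter flag, duplicate collapsing by canonical SMILES, and activity
#' labeling at the 100 nM threshold. Replicate IC50s for one molecule are
#' aggregated by geometric mean (potencies are log-distributed) and the label
#' is assigned after aggregation. When internal and public rows describe the
#' same molecule, only the internal measurements are kept.
#'
#' @param rows data.frame with columns \code{compound_id}, \code{smiles} and
#'   \code{ic50_nM}; optional \code{source} (default "public"), and logical
#'   \code{prefilter_inactive} marking rows retained as inactive from a
#'   low-inhibition primary screen (no IC50 required).
#' @param targetId panel target name.
#' @param ic50Ceiling retrieval ceiling in nM; rows above it are excluded.
#' @param provenance free-text notes stored on the dataset.
#' @return a [TargetDataset-class].
#' @examples
#' rows <- data.frame(compound_id = c("a", "b"), smiles = c("OCC", "CCO"),
#'                    ic50_nM = c(40, 90))
#' curateDataset(rows, "demo")  # one record, IC50 = 60 nM (geometric mean)
#' @export
curateDataset <- function(rows, targetId = "target",
                          ic50Ceiling = DEFAULT_IC50_CEILING_NM,
                          provenance = "") {
  req <- c("compound_id", "smiles", "ic50_nM")
  if (!is.data.frame(rows) || !all(req %in% names(rows))) {
    stop("rows must be a data.frame with columns: ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  .assertScalarNumber(ic50Ceiling, "ic50Ceiling", lo = 0)
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  if (is.null(rows$source)) rows$source <- "public"
  if (is.null(rows$prefilter_inactive)) rows$prefilter_inactive <- FALSE
  rows$prefilter_inactive <- isTRUE_vec(rows$prefilter_inactive)
  if (nrow(rows) == 0L) {
    stop("curation failed: input table is empty", call. = FALSE)
  }

  can <- standardizeSmiles(as.character(rows$smiles))
  rows$smiles <- as.character(can)
  rows <- rows[!is.na(rows$smiles), , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("curation failed: SMILES standardization removed every row",
         call. = FALSE)
  }

  has_ic50 <- !is.na(rows$ic50_nM)
  if (any(has_ic50 & rows$ic50_nM <= 0)) {
    stop("IC50 values must be positive where present", call. = FALSE)
  }
  # Rows with no IC50 are only meaningful as prefilter inactives or decoys.
  is_decoy <- rows$source == "decoy"
  drop_noic <- !has_ic50 & !rows$prefilter_inactive & !is_decoy
  if (any(drop_noic)) {
    message("curateDataset: dropped ", sum(drop_noic),
            " rows lacking IC50 (not flagged prefilter-inactive)")
    rows <- rows[!drop_noic, , drop = FALSE]
    has_ic50 <- !is.na(rows$ic50_nM)
  }
  over <- has_ic50 & rows$ic50_nM > ic50Ceiling & !rows$prefilter_inactive
  if (any(over)) {
    message("curateDataset: excluded ", sum(over), " rows with IC50 above ",
            ic50Ceiling, " nM")
    rows <- rows[!over, , drop = FALSE]
  }
  if (nrow(rows) == 0L) {
    stop("curation failed: the IC50 ceiling filter removed every row",
         call. = FALSE)
  }

  # Collapse duplicates per canonical SMILES; internal measurements win.
  out <- lapply(split(rows, rows$smiles), function(grp) {
    if (any(grp$source == "internal") && any(grp$source != "internal")) {
      grp <- grp[grp$source == "internal", , drop = FALSE]
    }
    ic <- grp$ic50_nM[!is.na(grp$ic50_nM)]
    ic50 <- if (length(ic)) .geomMean(ic) else NA_real_
    decoy <- all(grp$source == "decoy")
    label <- if (decoy) "decoy"
             else if (!is.na(ic50)) labelActivity(ic50)
             else "inactive"   # prefilter-inactive, no IC50
    data.frame(
      compound_id = grp$compound_id[1L],
      smiles = grp$smiles[1L],
      ic50_nM = if (decoy) NA_real_ else ic50,
      label = label,
      source = grp$source[1L],
      prefilter_inactive = any(grp$prefilter_inactive) && is.na(ic50),
      stringsAsFactors = FALSE
    )
  })
  rec <- do.call(rbind, out)
  # Deterministic, input-order-independent record order.
  rec <- rec[order(rec$smiles), , drop = FALSE]
  if (anyDuplicated(rec$compound_id)) {
    stop("duplicate compound_id across distinct molecules", call. = FALSE)
  }
  newTargetDataset(rec, targetId, provenance)
}

# Coerce assorted truthy encodings to logical, NA -> FALSE.
isTRUE_vec <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  x <- tolower(as.character(x))
  x %in% c("true", "t", "1", "yes")
}

#' Filter an external test set against a training dataset
#'
#' Applies the external-data retention rules: only rows whose standard
#' relation is "=" and whose unit is nM are kept, the survivors are curated
#' with [curateDataset()], and any molecule whose canonical SMILES already
#' occurs in the training dataset is removed so the test set stays disjoint
#' from training.
#'
#' @param rows data.frame with the [curateDataset()] columns plus
#'   \code{relation} and \code{units}.
#' @param training the training [TargetDataset-class].
#' @param ... passed to [curateDataset()].
#' @return a [TargetDataset-class] disjoint from \code{training}.
#' @export
filterExternalTestset <- function(rows, training, ...) {
  stopifnot(is(training, "TargetDataset"))
  if (is.null(rows$relation)) rows$relation <- "="
  if (is.null(rows$units)) rows$units <- "nM"
  keep <- rows$relation == "=" & rows$units == "nM"
  if (any(!keep)) {
    message("filterExternalTestset: dropped ", sum(!keep),
            " rows with relation != '=' or units != 'nM'")
  }
  rows <- rows[keep, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("curation failed: the relation/unit filter removed every row",
         call. = FALSE)
  }
  ds <- curateDataset(rows, targetId = targetId(training), ...)
  rec <- records(ds)
  dup <- rec$smiles %in% records(training)$smiles
  if (any(dup)) {
    message("filterExternalTestset: removed ", sum(dup),
            " compounds already present in training")
  }
  rec <- rec[!dup, , drop = FALSE]
  if (nrow(rec) == 0L) {
    stop("curation failed: every external compound duplicated training",
         call. = FALSE)
  }
  newTargetDataset(rec, targetId(training),
                   provenance = "external test set")
}

#' Read a compound table or .smi file
#'
#' \code{readCompoundTable()} reads the standard comma-separated input
#' (header required; columns compound_id, smiles, ic50_nM, optional relation,
#' units, source, prefilter_inactive). \code{readSmiFile()} reads one
#' "SMILES id" per line, as used for decoy and query inputs.
#'
#' @param path file path.
#' @return data.frame of raw rows (not yet curated).
#' @export
readCompoundTable <- function(path) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("compound_id", "smiles")
  if (!all(req %in% names(rows))) {
    stop("CSV must have a header with at least: ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (is.null(rows$ic50_nM)) rows$ic50_nM <- NA_real_
  rows
}

#' @rdname readCompoundTable
#' @export
readSmiFile <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty .smi file: ", path, call. = FALSE)
  parts <- strsplit(lines, "[ \t]+")
  data.frame(
    compound_id = vapply(parts, function(p) {
      if (length(p) > 1L) p[2L] else NA_character_
    }, character(1)),
    smiles = vapply(parts, `[`, character(1), 1L),
    stringsAsFactors = FALSE
  )
}

#' Write a curated dataset to CSV
#'
#' Serializes a curated dataset with explicit \code{canonical_smiles} and
#' \code{label} columns. The file round-trips through
#' [readCompoundTable()] + [curateDataset()] unchanged.
#'
#' @param ds a [TargetDataset-class].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeDataset <- function(ds, path) {
  stopifnot(is(ds, "TargetDataset"))
  rec <- records(ds)
  out <- data.frame(
    compound_id = rec$compound_id,
    smiles = rec$smiles,
    canonical_smiles = rec$smiles,
    ic50_nM = rec$ic50_nM,
    label = rec$label,
    source = rec$source,
    prefilter_inactive = rec$prefilter_inactive,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
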
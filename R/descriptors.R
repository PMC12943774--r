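#' 2D physicochemical descriptors for one molecule
#'
#' A fixed-order vector of 2D descriptors: OpenBabel whole-molecule
#' properties (logP, molar refractivity, molecular weight, topological polar
#' surface area, hydrogen-bond donor and acceptor counts, fluorine count)
#' plus graph-derived counts (heavy atoms, rings, element counts, bond-order
#' counts, rotatable-bond estimate, formal charges, mean heavy degree).
#' Deterministic for a given molecule regardless of SMILES spelling.
#'
#' @param smiles a single SMILES string.
#' @return named numeric vector; names are identical for every molecule.
#' @examples
#' computeDescriptors("CCO")["n_heavy"]  # 3
#' @export
computeDescriptors <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L) {
    stop("'smiles' must be a single string; use computeDescriptorMatrix()",
         call. = FALSE)
  }
  computeDescriptorMatrix(smiles)[1L, ]
}

#' 2D descriptor matrix for a vector of molecules
#'
#' Batch companion to [computeDescriptors()]. Molecules whose descriptor
#' computation fails are dropped with a message; the returned matrix carries
#' the surviving SMILES as rownames and a \code{"dropped"} attribute with the
#' failures.
#'
#' @param smiles character vector of SMILES.
#' @return numeric matrix, molecules x descriptors.
#' @export
computeDescriptorMatrix <- function(smiles) {
  can <- standardizeSmiles(smiles)
  ok <- !is.na(can)
  if (!any(ok)) stop("no molecule survived standardization", call. = FALSE)
  can_ok <- can[ok]

  txt <- paste0(paste(can_ok, seq_along(can_ok)), "\n", collapse = "")
  props <- ChemmineOB::forEachMol("SMILES", txt, ChemmineOB::prop_OB)

  graphs <- .molGraphs(can_ok)
  obcols <- c("HBA1", "HBA2", "HBD", "logP", "MR", "MW", "nF", "TPSA")
  rows <- vector("list", length(can_ok))
  for (k in seq_along(props)) {
    i <- suppressWarnings(as.integer(props[[k]]$title))
    if (is.na(i) || is.null(graphs[[i]])) next
    ob <- suppressWarnings(as.numeric(props[[k]][1, obcols]))
    if (anyNA(ob)) next
    names(ob) <- tolower(obcols)
    rows[[i]] <- c(ob, .graphDescriptors(graphs[[i]]))
  }
  failed <- vapply(rows, is.null, logical(1))
  if (all(failed)) stop("descriptor computation failed for every molecule",
                        call. = FALSE)
  if (any(failed) || any(!ok)) {
    dropped <- unique(c(smiles[!ok], can_ok[failed]))
    message("computeDescriptorMatrix: dropped ", length(dropped),
            " molecules with failed descriptors")
  }
  mat <- do.call(rbind, rows[!failed])
  rownames(mat) <- can_ok[!failed]
  attr(mat, "dropped") <- c(smiles[!ok], can_ok[failed])
  mat
}

.graphDescriptors <- function(g) {
  deg <- lengths(g$adj)
  ords <- unlist(g$order)        # each bond counted twice, consistently
  n <- length(g$z)
  # Rotatable-bond estimate: acyclic single bonds between non-terminal atoms.
  rot <- 0L
  for (a in seq_len(n)) {
    nb <- g$adj[[a]]
    for (k in seq_along(nb)) {
      b <- nb[k]
      if (b <= a) next
      if (g$order[[a]][k] == 1L && !(g$inRing[a] && g$inRing[b]) &&
          deg[a] > 1L && deg[b] > 1L) {
        rot <- rot + 1L
      }
    }
  }
  c(
    n_heavy = n,
    n_ring_atoms = sum(g$inRing),
    n_bonds = sum(deg) / 2,
    n_rot_bonds = rot,
    n_C = sum(g$z == 6L), n_N = sum(g$z == 7L), n_O = sum(g$z == 8L),
    n_S = sum(g$z == 16L),
    n_halogen = sum(g$z %in% c(9L, 17L, 35L, 53L)),
    n_double = sum(ords == 2L) / 2, n_triple = sum(ords == 3L) / 2,
    n_charged = sum(g$charge != 0L),
    mean_degree = if (n) mean(deg) else 0,
    frac_ring = if (n) sum(g$inRing) / n else 0
  )
}

#' Prune a descriptor matrix
#'
#' Three sequential stages, mirroring common QSAR feature hygiene:
#' (1) drop descriptors with variance below \code{varThreshold};
#' (2) among descriptor pairs with absolute Pearson correlation above
#' \code{corThreshold}, drop the later-ordered column; (3) rank survivors by
#' impurity importance from a seeded random forest against the activity
#' labels and keep the top \code{k}. Deterministic given the seed.
#'
#' @param x numeric matrix, molecules x descriptors (>= 2 rows).
#' @param y activity labels (factor or character, two classes) for stage 3.
#' @param varThreshold minimum variance (default 1e-5).
#' @param corThreshold maximum absolute pairwise correlation (default 0.95).
#' @param k maximum descriptors kept by stage 3 (default 50).
#' @param seed integer seed for the random forest.
#' @return character vector of retained descriptor names (ordered by
#'   decreasing importance).
#' @export
pruneDescriptors <- function(x, y, varThreshold = 1e-5, corThreshold = 0.95,
                             k = 50L, seed = 1L) {
  if (!is.matrix(x) || nrow(x) < 2L) {
    stop("x must be a matrix with at least 2 rows", call. = FALSE)
  }
  vars <- apply(x, 2, stats::var)
  keep <- colnames(x)[vars > varThreshold]
  if (!length(keep)) stop("all descriptors pruned at the variance stage",
                          call. = FALSE)
  x1 <- x[, keep, drop = FALSE]
  if (ncol(x1) > 1L) {
    cm <- abs(stats::cor(x1))
    drop <- logical(ncol(x1))
    for (j in seq_len(ncol(x1) - 1L)) {
      if (drop[j]) next
      hits <- which(cm[j, ] > corThreshold)
      drop[hits[hits > j]] <- TRUE
    }
    keep <- keep[!drop]
  }
  if (!length(keep)) stop("all descriptors pruned at the correlation stage",
                          call. = FALSE)
  x2 <- x[, keep, drop = FALSE]
  y <- factor(y)
  if (nlevels(y) < 2L || ncol(x2) <= k) {
    return(keep)
  }
  rf <- ranger::ranger(
    x = as.data.frame(x2), y = y, num.trees = 500,
    importance = "impurity", seed = seed, num.threads = 1
  )
  imp <- sort(rf$variable.importance, decreasing = TRUE)
  names(imp)[seq_len(min(k, length(imp)))]
}
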
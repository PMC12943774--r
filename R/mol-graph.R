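# Heavy-atom molecular graphs extracted from OpenBabel-parsed SDF blocks.
# These feed the circular fingerprint; hydrogens are made explicit during
# conversion so per-atom H counts are exact, then folded into atom attributes.

.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe"
)

# MDL V2000 charge field codes -> formal charge.
.MDL_CHARGE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                 `5` = -1L, `6` = -2L, `7` = -3L)

# Parse a vector of (assumed valid) SMILES into heavy-atom graphs.
# Returns a list parallel to `smiles`; NULL where conversion failed.
# Each graph: list(z, nH, charge, inRing, adj, order) where adj/order are
# lists of neighbor indices and integer bond orders.
.molGraphs <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) > 0L)
  txt <- paste0(paste(smiles, seq_along(smiles)), "\n", collapse = "")
  sdftxt <- ChemmineOB::convertFormat(
    "SMI", "SDF", txt,
    options = data.frame(names = c("h", "gen2D"), args = c("", ""),
                         stringsAsFactors = FALSE))
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(sdftxt, tf)
  sdfs <- ChemmineR::read.SDFset(tf)
  out <- vector("list", length(smiles))
  titles <- suppressWarnings(as.integer(ChemmineR::sdfid(sdfs)))
  for (k in seq_along(titles)) {
    i <- titles[k]
    if (is.na(i)) next
    out[[i]] <- .graphFromSDF(sdfs[[k]])
  }
  out
}

.graphFromSDF <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_.*$", "", rownames(ab))
  z <- match(elem, .ELEMENTS)
  z[is.na(z)] <- 0L
  chargeCode <- if ("C6" %in% colnames(ab)) as.integer(ab[, "C6"]) else
    rep(0L, nrow(ab))
  charge <- .MDL_CHARGE[as.character(chargeCode)]
  charge[is.na(charge)] <- 0L

  n <- nrow(ab)
  a1 <- as.integer(bb[, 1L]); a2 <- as.integer(bb[, 2L])
  ord <- as.integer(bb[, 3L])

  heavy <- which(elem != "H")
  newIdx <- integer(n); newIdx[heavy] <- seq_along(heavy)
  nH <- integer(length(heavy))
  adj <- vector("list", length(heavy))
  order <- vector("list", length(heavy))
  for (j in seq_along(heavy)) { adj[[j]] <- integer(0); order[[j]] <- integer(0) }
  hset <- elem == "H"
  for (e in seq_along(a1)) {
    i <- a1[e]; j <- a2[e]
    if (hset[i] && !hset[j]) { nH[newIdx[j]] <- nH[newIdx[j]] + 1L; next }
    if (hset[j] && !hset[i]) { nH[newIdx[i]] <- nH[newIdx[i]] + 1L; next }
    if (hset[i] && hset[j]) next
    ii <- newIdx[i]; jj <- newIdx[j]
    adj[[ii]] <- c(adj[[ii]], jj); order[[ii]] <- c(order[[ii]], ord[e])
    adj[[jj]] <- c(adj[[jj]], ii); order[[jj]] <- c(order[[jj]], ord[e])
  }
  list(
    z = z[heavy],
    nH = nH,
    charge = as.integer(charge[heavy]),
    inRing = .ringAtoms(adj),
    adj = adj,
    order = order
  )
}

# An atom is a ring atom iff it is incident to an edge whose removal leaves
# its endpoints connected. Molecular graphs are tiny, so the O(E^2) test is
# fine and exact.
.ringAtoms <- function(adj) {
  n <- length(adj)
  inRing <- logical(n)
  if (n == 0L) return(inRing)
  for (i in seq_len(n)) {
    for (j in adj[[i]]) {
      if (j <= i || (inRing[i] && inRing[j])) next
      if (.connectedWithout(adj, i, j)) inRing[i] <- inRing[j] <- TRUE
    }
  }
  inRing
}

# BFS from `from` to `to` skipping the direct edge from-to.
.connectedWithout <- function(adj, from, to) {
  seen <- logical(length(adj))
  seen[from] <- TRUE
  queue <- from
  first <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[v]]
    if (v == from && first) { nb <- nb[nb != to]; first <- FALSE }
    for (w in nb) {
      if (w == to) return(TRUE)
      if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  FALSE
}
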
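# Shared fixtures, built in code and cached across test files.

.fixtures <- new.env(parent = emptyenv())

# A standard synthetic target library (200 compounds, 8 scaffolds).
fixtureDataset <- function() {
  if (is.null(.fixtures$ds)) {
    .fixtures$ds <- suppressMessages(
      generateTargetLibrary(synthConfig(seed = 42)))
  }
  .fixtures$ds
}

# A small trained bundle + library on a reduced dataset, for predictor tests.
# Restricted to two fast algorithms; the full roster is exercised elsewhere.
fixtureBundle <- function() {
  if (is.null(.fixtures$bundle)) {
    ds <- fixtureDataset()
    model <- suppressMessages(trainTargetModel(
      ds, seed = 7, algorithms = c("logistic", "random_forest")))
    model@calibrator <- suppressMessages(
      fitCalibrator(model, ds, method = "isotonic", seed = 7))
    .fixtures$bundle <- list(ds = ds, model = model,
                             lib = buildActiveLibrary(ds))
  }
  .fixtures$bundle
}

# Chemistry-free dataset: ids/IC50s only (pair-building and metrics tests
# never touch the SMILES, so placeholder strings keep these fixtures fast).
toyDataset <- function(ic50, target = "TOY") {
  n <- length(ic50)
  rec <- data.frame(
    compound_id = sprintf("cpd%02d", seq_len(n)),
    smiles = sprintf("smiles%02d", seq_len(n)),
    ic50_nM = ic50,
    label = ifelse(ic50 <= 100, "active", "inactive"),
    source = "public",
    prefilter_inactive = FALSE,
    stringsAsFactors = FALSE
  )
  newTargetDataset(rec, target)
}

# Hand-built fingerprint from explicit bit positions (0-based).
makeFp <- function(bits, radius = 6L, nBits = 2048L) {
  new("ECFP", bits = as.integer(sort(bits)), radius = as.integer(radius),
      nBits = as.integer(nBits))
}

# Hand-built library from a list of fingerprints.
makeLib <- function(fps, ids = paste0("lib", seq_along(fps)),
                    target = "LIB") {
  new("ActiveLibrary", targetId = target, ids = ids,
      smiles = paste0("smi", seq_along(fps)), fps = fps,
      radius = fps[[1]]@radius, nBits = fps[[1]]@nBits)
}

# Brute-force pair-rule oracle: enumerate all unordered pairs and apply the
# printed definitions directly.
oraclePairs <- function(ic50, ids = sprintf("cpd%02d", seq_along(ic50))) {
  act <- ic50 <= 100
  a_pairs <- character(0); i_pairs <- character(0)
  n <- length(ic50)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dlog <- abs(log10(ic50[i]) - log10(ic50[j]))
    if ((act[i] || act[j]) && dlog < 1) {
      a_pairs <- c(a_pairs, paste(ids[i], ids[j]))
    }
    if ((!act[i] || !act[j]) && dlog > 1) {
      i_pairs <- c(i_pairs, paste(ids[i], ids[j]))
    }
  }
  list(active = sort(a_pairs), inactive = sort(i_pairs))
}

pairKeys <- function(pairs) sort(paste(pairs$id_a, pairs$id_b))
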
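# Internal helpers shared across modules.

# Activity threshold in nM: active iff IC50 <= 100 nM.
ACTIVITY_THRESHOLD_NM <- 100

# Default retrieval ceiling for curation, in nM.
DEFAULT_IC50_CEILING_NM <- 10000

.assertScalarNumber <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  }
  invisible(x)
}

.isPowerOfTwo <- function(n) n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L

# Deterministic 31-bit polynomial hash of an integer vector. Constants follow
# the FNV multiplier; arithmetic stays below 2^53 so doubles are exact.
.hashInts <- function(v) {
  h <- 97531
  for (x in v) {
    h <- (h * 16777619 + (x %% 2147483647)) %% 2147483647
  }
  as.integer(h)
}

# Stratified fold assignment: within each class, a seeded permutation is
# dealt round-robin into k folds. Returns a list of `times` integer vectors
# (fold id per observation).
.stratifiedFolds <- function(y, k = 5L, times = 3L, seed = 1L) {
  y <- as.integer(y)
  lapply(seq_len(times), function(rep) {
    set.seed(seed + 1000L * rep)
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

# Geometric mean, for aggregating replicate IC50s of one molecule.
.geomMean <- function(x) exp(mean(log(x)))
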
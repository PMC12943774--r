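test_that("binning partitions [0,1] into ten intervals with a closed top bin", {
  pairs <- data.frame(
    id_a = letters[1:4], id_b = LETTERS[1:4],
    pair_class = c("inactive", "active", "inactive", "active"),
    similarity = c(0.05, 0.15, 0.15, 0.95),
    target_id = "T")
  bins <- binPairs(pairs)
  expect_equal(nrow(bins), 10L)
  expect_equal(bins$lo, seq(0, 0.9, by = 0.1))
  expect_equal(bins$fraction_active[1], 0)
  expect_equal(bins$fraction_active[2], 0.5)
  expect_equal(bins$fraction_active[10], 1)
  expect_true(all(is.na(bins$fraction_active[bins$n_pairs == 0])))

  # similarity exactly 1.0 joins the last bin
  one <- data.frame(id_a = "x", id_b = "y", pair_class = "active",
                    similarity = 1.0, target_id = "T")
  expect_equal(binPairs(one)$n_pairs[10], 1L)

  # random (decoy) pairs count as non-active evidence
  pairs$pair_class[4] <- "random"
  expect_equal(binPairs(pairs)$fraction_active[10], 0)

  expect_error(binPairs(pairs[0, ]), "empty")
})

test_that("the belief curve hits its anchors with the published parameters", {
  p <- defaultCurveParams()
  expect_identical(c(fMax(p), sc50(p), curveSlope(p)), c(0.842, 0.281, 3.417))
  expect_equal(bEcfp(0.281, p), 0.842 / 2)
  expect_equal(bEcfp(1, p), 0.842 / (1 + 10^((0.281 - 1) * 3.417)))
  expect_error(bEcfp(-0.1, p), "within")
  expect_error(bEcfp(1.1, p), "within")
})

test_that("the curve is strictly increasing and bounded for random params", {
  set.seed(7)
  x <- seq(0, 1, by = 0.01)
  for (i in 1:20) {
    p <- curveParams(runif(1, 0.05, 1), runif(1), runif(1, 0.2, 20))
    y <- bEcfp(x, p)
    expect_true(all(diff(y) > 0))
    expect_true(all(y > 0 & y < fMax(p)))
    expect_equal(bEcfp(sc50(p), p), fMax(p) / 2)
  }
})

test_that("noise-free bins round-trip the generating parameters", {
  mids <- seq(0.05, 0.95, by = 0.1)
  analyticBins <- function(p) data.frame(
    lo = mids - 0.05, hi = mids + 0.05, mid = mids,
    n_pairs = 1000L, n_active_pairs = NA_integer_,
    fraction_active = bEcfp(mids, p))

  truth <- defaultCurveParams()
  fit <- fitCurve(analyticBins(truth))
  expect_equal(fMax(fit), fMax(truth), tolerance = 1e-6)
  expect_equal(sc50(fit), sc50(truth), tolerance = 1e-6)
  expect_equal(curveSlope(fit), curveSlope(truth), tolerance = 1e-6)

  set.seed(13)
  for (i in 1:5) {
    p <- curveParams(runif(1, 0.3, 0.95), runif(1, 0.1, 0.6),
                     runif(1, 1.5, 8))
    fit <- fitCurve(analyticBins(p))
    expect_equal(fMax(fit), fMax(p), tolerance = 1e-6)
    expect_equal(sc50(fit), sc50(p), tolerance = 1e-6)
    expect_equal(curveSlope(fit), curveSlope(p), tolerance = 1e-6)
  }
})

test_that("fit degeneracies and preconditions are reported", {
  mids <- seq(0.05, 0.95, by = 0.1)
  flat <- data.frame(lo = mids - 0.05, hi = mids + 0.05, mid = mids,
                     n_pairs = 100L, n_active_pairs = 40L,
                     fraction_active = 0.4)
  fit <- fitCurve(flat)
  expect_true(fit@diagnostics$degenerate)
  expect_equal(fMax(fit), 0.4, tolerance = 0.05)

  few <- flat[1:3, ]
  expect_error(fitCurve(few), "4 occupied")
})

test_that("unweighted fits ignore per-bin pair counts", {
  mids <- seq(0.05, 0.95, by = 0.1)
  p <- defaultCurveParams()
  set.seed(5)
  bins <- data.frame(lo = mids - 0.05, hi = mids + 0.05, mid = mids,
                     n_pairs = 500L, n_active_pairs = 0L,
                     fraction_active = pmin(pmax(
                       bEcfp(mids, p) + rnorm(10, 0, 0.02), 0), 1))
  doubled <- bins
  doubled$n_pairs <- 1000L
  f1 <- fitCurve(bins); f2 <- fitCurve(doubled)
  expect_identical(c(fMax(f1), sc50(f1), curveSlope(f1)),
                   c(fMax(f2), sc50(f2), curveSlope(f2)))

  # while the weighted option responds to counts
  lopsided <- bins
  lopsided$n_pairs <- c(10000L, rep(10L, 9))
  fw <- fitCurve(lopsided, weighted = TRUE)
  expect_false(identical(curveSlope(fw), curveSlope(f1)))
})

test_that("curve parameters persist through JSON", {
  p <- defaultCurveParams()
  path <- withr::local_tempfile(fileext = ".json")
  saveCurve(p, path, fingerprint = list(radius = 6, nBits = 2048))
  back <- loadCurve(path)
  expect_equal(fMax(back), fMax(p))
  expect_equal(sc50(back), sc50(p))
  expect_equal(curveSlope(back), curveSlope(p))
})

test_that("curve parameter bounds are enforced at construction", {
  expect_error(curveParams(0, 0.3, 3))       # fMax must exceed 0
  expect_error(curveParams(0.8, 1.2, 3))     # sc50 above 1
  expect_error(curveParams(0.8, 0.3, 0))     # slope must be positive
  expect_error(curveParams(0.8, 0.3, 60))    # slope above 50
})
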
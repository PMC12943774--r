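# Seeded synthetic (score, label) sets with a miscalibrated score:
# P(y=1 | s) = s^2, so raw scores are systematically optimistic at the top.
syntheticScores <- function(n, seed) {
  set.seed(seed)
  s <- runif(n)
  list(scores = s, labels = rbinom(n, 1, s^2))
}

brier <- function(p, y) mean((p - y)^2)

test_that("isotonic calibration is a non-decreasing step map", {
  for (seed in 1:5) {
    d <- syntheticScores(400, seed)
    cal <- fitCalibratorFromScores(d$scores, d$labels, "isotonic")
    grid <- seq(0, 1, by = 0.01)
    out <- applyCalibrator(cal, grid)
    expect_true(all(diff(out) >= 0))
    expect_true(all(out >= 0 & out <= 1))
    expect_lte(applyCalibrator(cal, 0.2), applyCalibrator(cal, 0.8))
  }
})

test_that("isotonic matches stats::isoreg on tie-free data", {
  set.seed(91)
  s <- sample(seq(0.001, 0.999, length.out = 200))  # distinct scores
  y <- rbinom(200, 1, s)
  cal <- fitCalibratorFromScores(s, y, "isotonic")
  iso <- stats::isoreg(s, y)
  expect_equal(applyCalibrator(cal, sort(s)), iso$yf, tolerance = 1e-12)
})

test_that("calibration never worsens the Brier score on calibration data", {
  for (seed in 1:10) {
    d <- syntheticScores(500, seed)
    cal <- fitCalibratorFromScores(d$scores, d$labels, "isotonic")
    expect_lte(brier(applyCalibrator(cal, d$scores), d$labels),
               brier(d$scores, d$labels))
  }
})

test_that("already-calibrated scores map nearly to themselves", {
  set.seed(3)
  s <- runif(2000)
  y <- rbinom(2000, 1, s)   # scores equal true probabilities
  cal <- fitCalibratorFromScores(s, y, "isotonic")
  expect_lt(mean(abs(applyCalibrator(cal, s) - s)), 0.06)
})

test_that("step lookup, identity passthrough, and clipping behave", {
  step <- new("Calibrator", method = "isotonic",
              fit = list(x = c(0, 0.5), y = c(0.1, 0.9)))
  expect_equal(applyCalibrator(step, 0.6), 0.9)
  expect_equal(applyCalibrator(step, 0.4), 0.1)
  expect_equal(applyCalibrator(step, 0.5), 0.9)

  none <- new("Calibrator")
  expect_equal(applyCalibrator(none, c(0.3, 1.7, -2)), c(0.3, 1, 0))

  unfitted <- new("Calibrator", method = "sigmoid")
  expect_error(applyCalibrator(unfitted, 0.5), "not fitted")
})

test_that("sigmoid calibration is monotone and preserves ranking AUC", {
  d <- syntheticScores(600, 17)
  cal <- fitCalibratorFromScores(d$scores, d$labels, "sigmoid")
  grid <- seq(0, 1, by = 0.01)
  out <- applyCalibrator(cal, grid)
  expect_true(all(diff(out) > 0))
  m_raw <- classificationMetrics(d$labels, as.integer(d$scores >= 0.5),
                                 d$scores)
  m_cal <- classificationMetrics(d$labels,
                                 as.integer(applyCalibrator(cal, d$scores) >= 0.5),
                                 applyCalibrator(cal, d$scores))
  expect_equal(m_cal$auc, m_raw$auc)
})

test_that("out-of-fold calibration improves a trained model's Brier score", {
  b <- fixtureBundle()
  dm <- offTargetBelief:::.designMatrix(b$ds)
  raw <- predictRawScores(b$model, dm$X)
  calp <- applyCalibrator(b$model@calibrator, raw)
  expect_true(all(calp >= 0 & calp <= 1))
  expect_identical(b$model@calibrator@method, "isotonic")
  expect_identical(b$model@calibrator@provenance$cvFolds, 5L)
})

test_that("stacking follows the informative belief and tolerates redundancy", {
  set.seed(23)
  n <- 800
  b_e <- runif(n)
  b_m <- runif(n)
  y <- rbinom(n, 1, plogis(6 * (b_e - 0.5)))   # labels driven by b_e only
  tr <- 1:600; te <- 601:800
  sm <- fitStacking(b_e[tr], b_m[tr], y[tr])
  pred <- predictStacking(sm, b_e[te], b_m[te])
  expect_gte(cor(pred, b_e[te], method = "spearman"), 0.95)

  # a duplicated belief adds (almost) nothing over the single feature
  logloss <- function(p, y) -mean(y * log(p) + (1 - y) * log(1 - p))
  sm_dup <- fitStacking(b_e[tr], b_e[tr], y[tr])
  p_dup <- predictStacking(sm_dup, b_e[te], b_e[te])
  g1 <- glm(y[tr] ~ b_e[tr], family = binomial)
  p1 <- plogis(coef(g1)[1] + coef(g1)[2] * b_e[te])
  expect_lte(abs(logloss(p_dup, y[te]) - logloss(p1, y[te])) /
               logloss(p1, y[te]), 0.02)
})

test_that("degenerate stacking features reduce to the empirical rate", {
  set.seed(5)
  y <- rbinom(400, 1, 0.35)
  sm <- suppressWarnings(fitStacking(rep(0, 400), rep(0, 400), y))
  expect_equal(predictStacking(sm, 0, 0), mean(y), tolerance = 1e-3)
  expect_error(fitStacking(runif(5), runif(5), rep(1, 5)), "both classes")
})

test_that("redundancy diagnostics separate identical from independent beliefs", {
  set.seed(61)
  x <- runif(5000)
  same <- redundancyDiagnostics(x, x)
  expect_equal(same$spearman_rho, 1)

  mono <- redundancyDiagnostics(x, x^3)   # strictly increasing transform
  expect_equal(mono$spearman_rho, 1)

  indep <- redundancyDiagnostics(x, runif(5000))
  expect_lt(abs(indep$spearman_rho), 0.05)
  expect_lt(indep$mutual_information_bits, 0.02)
  expect_gte(indep$mutual_information_bits, 0)
  expect_gt(same$mutual_information_bits, indep$mutual_information_bits)

  expect_message(konst <- redundancyDiagnostics(rep(0.5, 20), runif(20)),
                 "undefined")
  expect_true(is.na(konst$spearman_rho))
  expect_error(redundancyDiagnostics(runif(5), runif(5)), "at least 10")
})
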
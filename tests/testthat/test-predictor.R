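test_that("Hooper's rule matches its closed form and absorbing cases", {
  expect_equal(hooperJoint(0, 0), 0)
  expect_equal(hooperJoint(1, 0.3), 1)
  expect_equal(hooperJoint(0.421, 0.6), 0.7684)
  expect_error(hooperJoint(-0.1, 0.5), "within")
  expect_error(hooperJoint(0.5, 1.2), "within")
})

test_that("fusion is commutative, bounded, and monotone", {
  set.seed(3)
  b1 <- runif(2000); b2 <- runif(2000)
  j <- hooperJoint(b1, b2)
  expect_equal(j, hooperJoint(b2, b1))
  expect_true(all(j >= pmax(b1, b2)))
  expect_true(all(j <= pmin(1, b1 + b2)))
  eps <- 0.01
  expect_true(all(hooperJoint(pmin(b1 + eps, 1), b2) >= j))
  expect_true(all(hooperJoint(b1, pmin(b2 + eps, 1)) >= j))
})

constantCalibrator <- function(value) {
  new("Calibrator", method = "isotonic",
      fit = list(x = c(0, 1), y = c(value, value)))
}

test_that("a library-identical query chains Eq.-style beliefs to ~98.4%", {
  b <- fixtureBundle()
  model <- b$model
  model@calibrator <- constantCalibrator(0.9)   # force b_icml = 0.9
  query <- records(b$ds)$smiles[records(b$ds)$label == "active"][1]
  rep <- predictTarget(query, model, b$lib, curve = defaultCurveParams(),
                       adThreshold = 0.7)
  expect_true(rep$in_domain)
  expect_equal(rep$nn_similarity, 1.0)
  expect_equal(rep$b_ecfp, bEcfp(1, defaultCurveParams()), tolerance = 1e-12)
  expect_equal(rep$b_icml, 0.9)
  expect_equal(rep$joint, 1 - (1 - rep$b_ecfp) * 0.1)
  expect_equal(rep$joint, 0.9839, tolerance = 1e-4)
  expect_equal(rep$likelihood_percent, 98.4)
})

test_that("out-of-domain queries report the neighbor but no likelihood", {
  b <- fixtureBundle()
  # a molecule unlike any library member
  rep <- predictTarget("CCCCCCCCCCCC", b$model, b$lib, adThreshold = 0.7)
  expect_false(rep$in_domain)
  expect_true(is.na(rep$likelihood_percent))
  expect_true(is.na(rep$joint))
  expect_false(is.na(rep$nn_id))
  expect_gte(rep$nn_similarity, 0)

  # ad_threshold 0 always admits
  rep0 <- predictTarget("CCCCCCCCCCCC", b$model, b$lib, adThreshold = 0)
  expect_true(rep0$in_domain)
  expect_false(is.na(rep0$likelihood_percent))
})

test_that("raising the domain threshold never re-admits a query", {
  b <- fixtureBundle()
  query <- records(b$ds)$smiles[3]
  thresholds <- seq(0, 1, by = 0.1)
  dom <- vapply(thresholds, function(th) {
    predictTarget(query, b$model, b$lib, adThreshold = th)$in_domain
  }, logical(1))
  expect_true(all(diff(as.integer(dom)) <= 0))   # TRUE..TRUE FALSE..FALSE
  # gate definition: in_domain == (nn_similarity >= threshold)
  rep <- predictTarget(query, b$model, b$lib, adThreshold = 0.5)
  expect_identical(rep$in_domain, rep$nn_similarity >= 0.5)
})

test_that("a neutral classifier reduces fusion to the similarity belief", {
  b <- fixtureBundle()
  model <- b$model
  model@calibrator <- constantCalibrator(0)
  query <- records(b$ds)$smiles[10]
  rep <- predictTarget(query, model, b$lib, adThreshold = 0)
  expect_equal(rep$joint, rep$b_ecfp)
})

test_that("similarity-only bundles serve b_ecfp with a flag", {
  b <- fixtureBundle()
  rep <- predictTarget(records(b$ds)$smiles[1], similarityOnlyModel("T"),
                       b$lib, adThreshold = 0)
  expect_true(rep$similarity_only)
  expect_equal(rep$joint, rep$b_ecfp)
  rep2 <- predictTarget(records(b$ds)$smiles[1], NULL, b$lib, adThreshold = 0)
  expect_true(rep2$similarity_only)
})

test_that("batch prediction is cartesian, fault-isolated, and deterministic", {
  b <- fixtureBundle()
  panel <- list(T1 = list(model = b$model, library = b$lib),
                T2 = list(model = NULL, library = b$lib),
                T3 = list(model = b$model, library = b$lib))
  queries <- c(q1 = records(b$ds)$smiles[1], q2 = "this_is_not_a_smiles")
  out1 <- predictPanel(queries, panel, adThreshold = 0)
  expect_equal(nrow(out1), 6L)
  bad <- out1[out1$query_id == "q2", ]
  expect_true(all(!is.na(bad$error)))
  good <- out1[out1$query_id == "q1", ]
  expect_true(all(is.na(good$error)))
  expect_true(all(!is.na(good$likelihood_percent)))

  out2 <- predictPanel(queries, panel, adThreshold = 0)
  expect_identical(out1, out2)

  expect_error(predictPanel(queries, list()), "non-empty")
})
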
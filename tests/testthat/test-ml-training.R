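test_that("descriptors are spelling-invariant with sane counts", {
  d1 <- computeDescriptors("OCC")
  d2 <- computeDescriptors("CCO")
  expect_identical(d1, d2)
  expect_equal(unname(d1["n_heavy"]), 3)
  expect_equal(unname(computeDescriptors("C")["hbd"]), 0)   # methane
  expect_equal(unname(computeDescriptors("c1ccccc1")["n_ring_atoms"]), 6)
  expect_false(anyNA(d1))
})

test_that("descriptor names are identical across molecules", {
  X <- computeDescriptorMatrix(c("CCO", "c1ccccc1", "CC(=O)NC"))
  expect_equal(nrow(X), 3L)
  expect_false(anyNA(X))
  expect_identical(names(computeDescriptors("CCO")), colnames(X))
})

test_that("pruning removes constant and duplicated descriptors, then top-k", {
  set.seed(17)
  n <- 60
  X <- cbind(
    signal = c(rnorm(n / 2, 0), rnorm(n / 2, 3)),
    noise1 = rnorm(n),
    constant = rep(1.5, n),
    noise2 = rnorm(n)
  )
  X <- cbind(X, dupe = X[, "signal"])
  y <- rep(c(0, 1), each = n / 2)

  kept <- pruneDescriptors(X, y, k = 10)
  expect_false("constant" %in% kept)
  # correlation stage keeps the earlier of (signal, dupe)
  expect_true("signal" %in% kept)
  expect_false("dupe" %in% kept)

  top2 <- pruneDescriptors(X, y, k = 2)
  expect_lte(length(top2), 2L)
  expect_identical(top2[1], "signal")   # impurity importance ranks it first

  expect_identical(pruneDescriptors(X, y, k = 2, seed = 3),
                   pruneDescriptors(X, y, k = 2, seed = 3))
  expect_error(pruneDescriptors(X, y, varThreshold = 1e9), "variance stage")
})

test_that("classification metrics match the hand-derived worked example", {
  truth <- c(rep(1, 9), rep(0, 11))
  pred <- c(rep(1, 8), 0, rep(1, 2), rep(0, 9))  # tp=8 fn=1 fp=2 tn=9
  m <- classificationMetrics(truth, pred)
  expect_equal(m$tp, 8); expect_equal(m$fp, 2)
  expect_equal(m$fn, 1); expect_equal(m$tn, 9)
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 0.8889, tolerance = 1e-4)
  expect_equal(m$f1, 0.8421, tolerance = 1e-4)
  expect_equal(m$mcc, 0.7035, tolerance = 1e-4)
})

test_that("metric identities and degenerate predictors behave as defined", {
  y <- c(1, 0, 1, 1, 0, 0, 1, 0)
  perfect <- classificationMetrics(y, y)
  expect_equal(perfect$precision, 1); expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1); expect_equal(perfect$mcc, 1)
  expect_equal(perfect$kappa, 1)
  expect_equal(classificationMetrics(y, 1 - y)$mcc, -1)

  allpos <- classificationMetrics(y, rep(1, 8))
  expect_equal(allpos$recall, 1)
  expect_equal(allpos$precision, 0.5)
  expect_equal(allpos$mcc, 0)   # zero marginal convention

  expect_message(
    m <- classificationMetrics(rep(1, 5), rep(1, 5), runif(5)),
    "single-class")
  expect_true(is.na(m$auc))
})

test_that("metrics agree with a brute-force confusion oracle and pROC AUC", {
  set.seed(29)
  for (i in 1:20) {
    n <- sample(10:80, 1)
    truth <- rbinom(n, 1, 0.5)
    if (length(unique(truth)) < 2) next
    scores <- runif(n)
    pred <- as.integer(scores >= 0.5)
    m <- classificationMetrics(truth, pred, scores)
    expect_equal(m$tp, sum(truth & pred))
    expect_equal(m$tn, sum(!truth & !pred))
    expect_equal(m$fp, sum(!truth & pred))
    expect_equal(m$fn, sum(truth & !pred))
    auc <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(m$auc, auc)
  }
})

test_that("a structurally separable target yields a perfect CV winner", {
  # actives all share a sulfur-bearing scaffold, inactives an ether scaffold:
  # a single descriptor separates the classes.
  subs <- c("C", "CC", "CCC", "CCO", "CN", "CCN", "COC", "C(C)C", "CCCC",
            "CCl", "CF", "CCOC", "CCCO", "CCCN", "CC(C)C")
  actives <- sprintf("O=S(=O)(N%s)c1ccc(%s)cc1", subs, rev(subs))
  inactives <- sprintf("C(%s)Oc1ccc(%s)cc1", subs, rev(subs))
  rows <- data.frame(
    compound_id = sprintf("m%02d", seq_len(2 * length(subs))),
    smiles = c(actives, inactives),
    ic50_nM = rep(c(5, 50000), each = length(subs)),
    prefilter_inactive = rep(c(FALSE, TRUE), each = length(subs))
  )
  rows$ic50_nM[rows$prefilter_inactive] <- NA
  ds <- suppressMessages(curateDataset(rows, "SEP"))
  model <- suppressMessages(trainTargetModel(
    ds, seed = 11, algorithms = c("logistic", "random_forest")))
  expect_equal(mean(model@cvMetrics$mcc), 1.0)
  expect_true(model@meta$meets_mcc_target)
})

test_that("permuted labels give near-zero cross-validated MCC", {
  ds <- fixtureDataset()
  rec <- records(ds)
  set.seed(41)
  perm <- sample(nrow(rec))
  rec$ic50_nM <- rec$ic50_nM[perm]
  rec$label <- rec$label[perm]
  null_ds <- newTargetDataset(rec, "NULL")
  model <- suppressMessages(trainTargetModel(null_ds, seed = 19,
                                             algorithms = "logistic"))
  expect_lt(abs(mean(model@cvMetrics$mcc)), 0.15)
})

test_that("training is reproducible and records its selection metadata", {
  ds <- fixtureDataset()
  m1 <- suppressMessages(trainTargetModel(
    ds, seed = 7, algorithms = c("logistic", "extra_trees")))
  m2 <- suppressMessages(trainTargetModel(
    ds, seed = 7, algorithms = c("logistic", "extra_trees")))
  expect_identical(m1@algorithm, m2@algorithm)
  expect_identical(m1@cvMetrics, m2@cvMetrics)
  expect_equal(nrow(m1@cvMetrics), 15L)   # 5 folds x 3 repeats
  expect_identical(m1@meta$exported_fold, m2@meta$exported_fold)
  # class weight is the inactive/active ratio
  rec <- records(ds)
  expect_equal(m1@classWeight,
               sum(rec$label == "inactive") / sum(rec$label == "active"))
})

test_that("class-starved targets are pushed to similarity-only mode", {
  ds <- toyDataset(c(rep(10, 3), rep(1000, 30)))
  # toy smiles never reach descriptor computation: the class check fires first
  expect_error(suppressMessages(trainTargetModel(ds)), "similarity-only")

  so <- similarityOnlyModel("STARVED")
  expect_identical(so@algorithm, "similarity-only")
  expect_error(predictRawScores(so, matrix(0, 1, 1)), "similarity-only")
})

test_that("model bundles round-trip through their directory format", {
  b <- fixtureBundle()
  dir <- withr::local_tempdir()
  saveTargetModel(b$model, dir)
  expect_true(file.exists(file.path(dir, "model.json")))
  back <- loadTargetModel(dir)
  expect_identical(back@algorithm, b$model@algorithm)
  expect_identical(back@descriptorNames, b$model@descriptorNames)
  X <- computeDescriptorMatrix(records(b$ds)$smiles[1:5])
  expect_equal(predictRawScores(back, X), predictRawScores(b$model, X))
})

test_that("prediction enforces the pruned descriptor contract", {
  b <- fixtureBundle()
  X <- computeDescriptorMatrix(records(b$ds)$smiles[1:3])
  sc <- predictRawScores(b$model, X)
  expect_length(sc, 3L)
  expect_true(all(sc >= 0 & sc <= 1))
  Xbad <- X[, 1:2, drop = FALSE]
  if (length(setdiff(b$model@descriptorNames, colnames(Xbad)))) {
    expect_error(predictRawScores(b$model, Xbad), "lacks")
  }
})
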
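test_that("standardization collapses equivalent spellings and keeps stereo", {
  can <- standardizeSmiles(c("OCC", "CCO"))
  expect_identical(can[1], can[2])

  benz <- standardizeSmiles(c("C1=CC=CC=C1", "c1ccccc1"))
  expect_identical(benz[1], benz[2])

  # canonical output is a fixed point
  expect_identical(standardizeSmiles(can[1])[1], can[1])

  # E and Z difluoroethene must stay distinct
  ez <- standardizeSmiles(c("F/C=C/F", "F/C=C\\F"))
  expect_false(ez[1] == ez[2])
})

test_that("unparseable SMILES are rejected with the offending input", {
  expect_message(res <- standardizeSmiles(c("CCO", "not_a_smiles")),
                 "not_a_smiles")
  expect_false(is.na(res[1]))
  expect_true(is.na(res[2]))
  expect_identical(attr(res, "failed"), "not_a_smiles")
  expect_error(standardizeSmiles(character(0)))
  expect_error(standardizeSmiles(""))
})

test_that("activity labeling applies the 100 nM threshold inclusively", {
  expect_identical(labelActivity(c(100, 99.9, 101)),
                   c("active", "active", "inactive"))
  expect_error(labelActivity(0))
  expect_error(labelActivity(-5))
  expect_error(labelActivity(NA_real_))
})

test_that("curation aggregates replicates by geometric mean, then labels", {
  rows <- data.frame(compound_id = c("a", "b"), smiles = c("OCC", "CCO"),
                     ic50_nM = c(40, 90))
  ds <- curateDataset(rows, "T")
  rec <- records(ds)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$ic50_nM, sqrt(40 * 90))   # 60 nM
  expect_identical(rec$label, "active")

  # aggregation happens before labeling: 50 and 150 -> geomean 86.6 -> active
  rows2 <- data.frame(compound_id = c("a", "b"), smiles = c("OCC", "CCO"),
                      ic50_nM = c(50, 150))
  expect_identical(records(curateDataset(rows2, "T"))$label, "active")
})

test_that("curation enforces the retrieval ceiling and the prefilter rule", {
  rows <- data.frame(
    compound_id = c("keep", "toohigh", "prefilter"),
    smiles = c("CCO", "CCN", "CCC"),
    ic50_nM = c(50, 12000, NA),
    prefilter_inactive = c(FALSE, FALSE, TRUE)
  )
  ds <- suppressMessages(curateDataset(rows, "T"))
  rec <- records(ds)
  expect_setequal(rec$compound_id, c("keep", "prefilter"))
  pf <- rec[rec$compound_id == "prefilter", ]
  expect_identical(pf$label, "inactive")
  expect_true(is.na(pf$ic50_nM))

  # the error after an all-removing filter names the filter
  high <- data.frame(compound_id = "x", smiles = "CCO", ic50_nM = 50000)
  expect_error(suppressMessages(curateDataset(high, "T")), "ceiling")
})

test_that("internal measurements take precedence over public ones", {
  rows <- data.frame(
    compound_id = c("pub", "int"),
    smiles = c("CCO", "OCC"),
    ic50_nM = c(500, 50),
    source = c("public", "internal")
  )
  rec <- records(curateDataset(rows, "T"))
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$ic50_nM, 50)
  expect_identical(rec$label, "active")
})

test_that("curation is idempotent and order-independent", {
  rows <- data.frame(
    compound_id = c("a", "b", "c", "d"),
    smiles = c("CCO", "CCN", "CCC", "c1ccccc1"),
    ic50_nM = c(10, 99, 250, 5000)
  )
  ds1 <- curateDataset(rows, "T")
  ds2 <- curateDataset(records(ds1), "T")
  expect_identical(records(ds1), records(ds2))

  set.seed(1)
  shuf <- rows[sample(nrow(rows)), ]
  expect_identical(records(curateDataset(shuf, "T")), records(ds1))
})

test_that("every non-decoy record is exactly one of active/inactive", {
  rec <- records(fixtureDataset())
  nondecoy <- rec[rec$label != "decoy", ]
  expect_true(all(nondecoy$label %in% c("active", "inactive")))
  expect_equal(sum(nondecoy$label == "active") +
                 sum(nondecoy$label == "inactive"), nrow(nondecoy))
})

test_that("external test sets keep only relation '=' nM rows not in training", {
  training <- curateDataset(
    data.frame(compound_id = "t1", smiles = "CCO", ic50_nM = 10), "T")
  ext <- data.frame(
    compound_id = c("gt", "dup", "novel"),
    smiles = c("CCN", "OCC", "CCC"),
    ic50_nM = c(50, 60, 70),
    relation = c(">", "=", "="),
    units = "nM"
  )
  ds <- suppressMessages(filterExternalTestset(ext, training))
  expect_identical(records(ds)$compound_id, "novel")

  all_dup <- data.frame(compound_id = "dup", smiles = "OCC", ic50_nM = 60,
                        relation = "=", units = "nM")
  expect_error(suppressMessages(filterExternalTestset(all_dup, training)),
               "duplicated")
})

test_that("datasets round-trip through CSV", {
  ds <- curateDataset(
    data.frame(compound_id = c("a", "b"), smiles = c("CCO", "CCCCN"),
               ic50_nM = c(10, 900)), "T")
  path <- withr::local_tempfile(fileext = ".csv")
  writeDataset(ds, path)
  back <- curateDataset(readCompoundTable(path), "T")
  expect_identical(records(back), records(ds))
})

test_that(".smi files parse into id/smiles tables", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO mol1", "c1ccccc1\tmol2"), path)
  tab <- readSmiFile(path)
  expect_identical(tab$compound_id, c("mol1", "mol2"))
  expect_identical(tab$smiles, c("CCO", "c1ccccc1"))
})
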
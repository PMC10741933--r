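test_that("stratum counts, age ranges and bookkeeping match the design", {
  des <- syntheticDesign(nMiddle = 3, nOlder = 2,
                         idpSpec = idpSpec(n = 2L), seed = 11)
  co <- simulateCohort(des)
  expect_equal(ncol(co), 5L)
  expect_equal(sum(co$stratum == "middle"), 3L)
  expect_equal(sum(co$stratum == "older"), 2L)
  expect_true(all(co$age[co$stratum == "older"] >= 65))
  expect_true(all(co$age[co$stratum == "middle"] < 65))
  expect_equal(co$age_sq, co$age^2)
  expect_false(anyDuplicated(colnames(co)) > 0)
  # variable names unique across IDPs and subject-level columns
  expect_false(anyDuplicated(c(rownames(co),
    names(SummarizedExperiment::colData(co)))) > 0)
  expect_error(syntheticDesign(nMiddle = -1, nOlder = 5),
               class = "cogage_error_config")
  expect_error(
    syntheticDesign(idpSpec = data.frame(family = "PET", n = 3L,
                                         effect = 0, noiseSd = 1)),
    class = "cogage_error_config"
  )
})

test_that("zero-noise unit-loading battery reproduces the latent factor exactly", {
  des <- syntheticDesign(
    nMiddle = 30, nOlder = 30, loadings = 1, testNoiseSd = 0,
    idpSpec = idpSpec(n = 1L), seed = 5
  )
  co <- simulateCohort(des)
  oriented <- orientScores(co)
  for (t in colnames(oriented)) {
    expect_equal(unname(oriented[, t]), unname(co$latent_g))
  }
})

test_that("generation is a pure function of the design and its seed", {
  d1 <- smallDesign(seed = 21)
  a <- simulateCohort(d1)
  b <- simulateCohort(d1)
  expect_identical(idpMatrix(a), idpMatrix(b))
  expect_identical(
    as.data.frame(SummarizedExperiment::colData(a)),
    as.data.frame(SummarizedExperiment::colData(b))
  )
  c <- simulateCohort(smallDesign(seed = 22))
  expect_false(identical(idpMatrix(a), idpMatrix(c)))
})

test_that("a planted standardized effect is recovered at its nominal size", {
  des <- syntheticDesign(
    nMiddle = 2000, nOlder = 2000,
    idpSpec = idpSpec("dMRI_skeleton", n = 1L, effect = 0.8),
    confoundEffects = NULL, seed = 33
  )
  co <- simulateCohort(des)
  v <- idpMatrix(co)[1L, ]
  hi <- co$latent_g_high
  expect_equal(sum(hi), 2000L) # median split, both strata
  d <- cohensD(v[hi], v[!hi])
  expect_lt(abs(d - 0.8), 0.1)
})

test_that("null cohorts achieve nominal per-variable type-I error", {
  des <- syntheticDesign(
    nMiddle = 100, nOlder = 100,
    idpSpec = idpSpec("dMRI_skeleton", n = 1000L, effect = 0.7),
    confoundEffects = NULL, seed = 40
  )
  co <- simulateNullCohort(des) # planted effects forced to zero
  labels <- factor(ifelse(co$latent_g_high, "hi", "lo"), c("hi", "lo"))
  dat <- as.list(as.data.frame(t(idpMatrix(co))))
  specs <- data.frame(name = names(dat), family = "dMRI_skeleton",
                      scale = "continuous")
  cmp <- compareGroups(dat, labels, specs)
  frac <- mean(cmp$p < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("zero-noise null IDPs are identical across subjects given equal confounds", {
  des <- syntheticDesign(
    nMiddle = 10, nOlder = 10,
    idpSpec = idpSpec("rsfMRI", n = 3L, effect = 1, noiseSd = 0),
    confoundEffects = NULL, seed = 3
  )
  co <- simulateNullCohort(des)
  expect_true(all(apply(idpMatrix(co), 1, function(r) all(r == r[1]))))
})

test_that("cohort CSV fixtures round-trip losslessly", {
  des <- syntheticDesign(nMiddle = 3, nOlder = 2,
                         idpSpec = idpSpec(n = 2L), seed = 77)
  co <- simulateCohort(des)
  f <- withr::local_tempfile(fileext = ".csv")
  writeCohortCsv(co, f)
  expect_length(readLines(f), 6L) # header + 5 subjects
  expect_true(file.exists(paste0(f, ".provenance")))

  back <- readPhenotypeTable(f)
  expect_equal(unname(as.character(back$stratum)), as.character(co$stratum))
  expect_equal(cognitiveScores(back), cognitiveScores(co))
  expect_equal(idpMatrix(back), idpMatrix(co))
  expect_equal(back$t1_scale_factor, co$t1_scale_factor)
  expect_equal(
    as.character(demographics(back)$usual_walking_pace),
    as.character(demographics(co)$usual_walking_pace)
  )

  # header-only file: empty cohort, no error
  empty <- co[, 0]
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeCohortCsv(empty, f2)
  back2 <- readPhenotypeTable(f2)
  expect_equal(ncol(back2), 0L)
})
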
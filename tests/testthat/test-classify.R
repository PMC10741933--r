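test_that("orientation flips lower-is-better tests and guards re-orientation", {
  bt <- batteryTests(testBattery())
  m <- matrix(500, 1, 9, dimnames = list("s1", bt$name))
  o <- orientScores(m)
  expect_equal(unname(o[, "reaction_time"]), -500)
  expect_equal(unname(o[, "trail_making"]), -500)
  expect_equal(unname(o[, "pair_matching"]), -500)
  expect_equal(unname(o[, "fluid_intelligence"]), 500)
  expect_error(orientScores(o), class = "cogage_error_already_oriented")
  expect_error(orientScores(m[, 1:5, drop = FALSE]),
               class = "cogage_error_schema")
})

test_that("PC1 explained variance matches the one-factor closed form", {
  # 9 tests with loading 0.55 on g and unit noise: standardized covariance is
  # equicorrelated with rho = .55^2/(.55^2+1); top eigenvalue 1 + 8*rho.
  rho <- 0.55^2 / (0.55^2 + 1)
  analytic <- (1 + 8 * rho) / 9
  set.seed(14)
  oriented <- orientScores(randomScores(5000))
  model <- fitGenericModel(oriented)
  expect_lt(abs(model@explainedVariance - analytic), 0.03)

  # standardization centers inputs: the pooled mean vector projects to 0
  mu <- matrix(colMeans(oriented), 1, dimnames = list(NULL, colnames(oriented)))
  expect_equal(unname(projectGeneric(model, mu)), 0, tolerance = 1e-10)

  # zero-variance column is a named degenerate-input error
  bad <- oriented
  bad[, "numeric_memory"] <- 1
  err <- tryCatch(fitGenericModel(bad), error = identity)
  expect_s3_class(err, "cogage_error_degenerate")
  expect_match(conditionMessage(err), "numeric_memory")
})

test_that("projection is linear, symmetric, and sign-flip invariant", {
  set.seed(15)
  oriented <- orientScores(randomScores(200))
  model <- fitGenericModel(oriented)
  proj <- projectGeneric(model, oriented)
  # two subjects summing to twice the mean vector project to exact negatives
  mu <- colMeans(oriented)
  a <- oriented[1, ]
  b <- 2 * mu - a
  pair <- rbind(a, b)
  colnames(pair) <- colnames(oriented)
  pp <- projectGeneric(model, pair)
  expect_equal(unname(pp[1]), -unname(pp[2]), tolerance = 1e-10)

  flipped <- model
  flipped@loadings <- -model@loadings
  flipped@sign <- -model@sign
  expect_equal(projectGeneric(flipped, oriented), proj)
  expect_error(projectGeneric(model, oriented[, 1:4, drop = FALSE]),
               class = "cogage_error_schema")
})

test_that("z-scoring matches its defining arithmetic", {
  ref <- c(mean = 10, sd = 2)
  expect_equal(zScore(10, ref), 0)
  expect_equal(zScore(12, ref), 1)
  expect_equal(zScore(10 + 0.67 * 2, ref), 0.67)
  expect_error(zScore(1, c(mean = 0, sd = 0)),
               class = "cogage_error_degenerate")
})

test_that("generic stage applies both strict dual-reference thresholds", {
  selfRef <- c(mean = 0, sd = 1)
  # z_self = score; z_mid = score - 0.7 under this middle reference
  midRef <- c(mean = 0.7, sd = 1)
  res <- classifyGeneric(c(a = 0.8, b = 0.8, c = 0.5, d = 0.67),
                         selfRef, c(mean = 0.7, sd = 1))
  expect_equal(unname(res$pass), c(TRUE, TRUE, FALSE, FALSE))
  res2 <- classifyGeneric(c(a = 0.8), selfRef, c(mean = 0.9, sd = 1))
  expect_false(res2$pass[1]) # z_mid = -0.1 fails "exceeding 0"
  # threshold exactness: z equal to the cut fails
  expect_false(classifyGeneric(c(x = 0.67), selfRef, midRef)$pass[1])
  expect_equal(nrow(classifyGeneric(numeric(0), selfRef, midRef)), 0L)
})

test_that("specific stage requires all four tests to clear both thresholds", {
  bat <- testBattery()
  tests <- specificTests(bat)
  selfRef <- lapply(setNames(tests, tests), function(t) c(mean = 0, sd = 1))
  midRef <- lapply(setNames(tests, tests), function(t) c(mean = 0.6, sd = 1))
  m <- matrix(0.1, 2, 9, dimnames = list(c("s1", "s2"), batteryTests(bat)$name))
  # s1: z_self = 0.1 > 0, z_mid = -0.5 > -0.67 on all four -> pass
  # s2: one test at z_self = -0.01 -> fail
  m[2, tests[1]] <- -0.01
  res <- classifySpecific(m, bat, selfRef, midRef)
  expect_true(res$pass[1])
  expect_false(res$pass[2])
  # one test with z_mid = -0.7 -> fail
  midRef2 <- midRef
  midRef2[[tests[2]]] <- c(mean = 0.8, sd = 1) # z_mid = 0.1 - 0.8 = -0.7
  expect_false(classifySpecific(m[1, , drop = FALSE], bat, selfRef, midRef2)$pass[1])
  expect_error(
    classifySpecific(m, bat, selfRef[-1], midRef),
    class = "cogage_error_schema"
  )
})

test_that("cascade audit counts are conserved and stages are nested", {
  co <- simulateCohort(smallDesign(nMiddle = 400, nOlder = 400, seed = 8))
  cls <- classifyCohort(co)
  sc <- stageCounts(cls)
  expect_equal(unname(sc["nFinalSca"] + sc["nFinalNonSca"]),
               unname(sc["nOlderInput"]))
  expect_lte(sc["nFinalSca"], sc["nAfterGeneric"])
  expect_lte(sc["nAfterGeneric"], sc["nOlderInput"])
  subj <- subjectResults(cls)
  # final label is the conjunction of the generic and specific stages
  passAll <- subj$genericPass &
    Reduce(`&`, lapply(specificTests(testBattery()),
                       function(t) subj[[paste0("pass_", t)]]))
  expect_equal(unname(subj$label == "SCA"), unname(!is.na(passAll) & passAll))
  # specific stage never evaluated for generic-stage failures
  expect_true(all(is.na(subj$zSelf_fluid_intelligence[!subj$genericPass])))
})

test_that("a subject clearing every threshold by construction is labelled SCA", {
  set.seed(31)
  n <- 120
  scores <- randomScores(n)
  stratum <- rep(c("middle", "older"), each = 60)
  # hand the last older subject the best native-direction score on every test
  bt <- batteryTests(testBattery())
  for (j in seq_len(9)) {
    scores[n, j] <- if (bt$direction[j] == "lower_better") {
      min(scores[-n, j]) - 5
    } else {
      max(scores[-n, j]) + 5
    }
  }
  co <- scoreCohort(scores, stratum)
  cls <- classifyCohort(co)
  expect_equal(unname(scaLabels(cls)[["S120"]]), "SCA")
})

test_that("degenerate references are rejected with a named error", {
  set.seed(32)
  scores <- randomScores(60)
  # all older subjects identical: older generic reference has sd 0
  scores[31:60, ] <- rep(colMeans(scores[1:30, , drop = FALSE]), each = 30)
  co <- scoreCohort(scores, rep(c("middle", "older"), each = 30))
  err <- tryCatch(classifyCohort(co), error = identity)
  expect_s3_class(err, "cogage_error_degenerate")
  expect_match(conditionMessage(err), "generic")
  # missing stratum is an input error
  co2 <- scoreCohort(randomScores(30), rep("older", 30))
  expect_error(classifyCohort(co2), class = "cogage_error_input")
})

test_that("with references fixed, improving any score never revokes a pass", {
  set.seed(33)
  bat <- testBattery()
  tests <- specificTests(bat)
  selfRef <- lapply(setNames(tests, tests),
                    function(t) c(mean = rnorm(1), sd = runif(1, 0.5, 2)))
  midRef <- lapply(setNames(tests, tests),
                   function(t) c(mean = rnorm(1), sd = runif(1, 0.5, 2)))
  m <- matrix(rnorm(50 * 9), 50, 9,
              dimnames = list(NULL, batteryTests(bat)$name))
  before <- classifySpecific(m, bat, selfRef, midRef)$pass
  for (t in tests) {
    m2 <- m
    m2[, t] <- m2[, t] + runif(50, 0, 3)
    after <- classifySpecific(m2, bat, selfRef, midRef)$pass
    expect_true(all(after[before])) # TRUE can only stay TRUE
  }
  gen <- rnorm(50)
  gBefore <- classifyGeneric(gen, c(mean = 0, sd = 1), c(mean = 0, sd = 1))$pass
  gAfter <- classifyGeneric(gen + runif(50, 0, 2),
                            c(mean = 0, sd = 1), c(mean = 0, sd = 1))$pass
  expect_true(all(gAfter[gBefore]))
})
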
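test_that("K-squared statistic matches an independent reference implementation", {
  # expected values frozen from scipy.stats.normaltest / skewtest /
  # kurtosistest on the same vectors
  x1 <- c(0.1, -1.2, 0.5, 2.3, -0.7, 1.1, -0.3, 0.8, -1.5, 0.2,
          0.9, -0.4, 1.7, -2.1, 0.6, 0.0, -0.9, 1.3, -0.2, 0.4,
          2.0, -1.1, 0.7, -0.6, 1.5, -0.8, 0.3, 1.0, -1.3, 0.55)
  r1 <- dagostinoK2(x1)
  expect_equal(r1$statistic, 0.3842086219569048, tolerance = 1e-10)
  expect_equal(r1$p.value, 0.8252207844145417, tolerance = 1e-10)
  expect_equal(r1$z.skew, -0.09808091345764695, tolerance = 1e-10)
  expect_equal(r1$z.kurtosis, -0.6120365645712831, tolerance = 1e-10)
  r2 <- dagostinoK2(exp(x1))
  expect_equal(r2$statistic, 25.48635175435581, tolerance = 1e-10)
  expect_equal(r2$p.value, 2.922193932147196e-06, tolerance = 1e-8)
  expect_error(dagostinoK2(rnorm(5)), class = "cogage_error_input")
})

test_that("routing follows scale and the per-group normality rule", {
  expect_equal(routeTest(factor(c("a", "b", "a", "b")),
                         c(1, 1, 2, 2), "nominal")$test, "chi_square")
  # calibration: two normal groups accepted with probability ~ (1 - alpha)^2
  set.seed(50)
  picks <- replicate(200, {
    routeTest(rnorm(400), rep(c("g1", "g2"), each = 200))$test
  })
  frac <- mean(picks == "anova")
  expect_lt(abs(frac - 0.95^2), 3 * sqrt(0.9025 * 0.0975 / 200) + 0.01)
  # a clearly skewed group is sent to the rank test with high probability
  set.seed(51)
  picks2 <- replicate(50, {
    routeTest(c(rexp(200), rnorm(200)), rep(c("g1", "g2"), each = 200))$test
  })
  expect_gte(mean(picks2 == "mann_whitney"), 0.95)
  # routing is invariant to label order
  set.seed(52)
  v <- c(rexp(60), rnorm(60))
  l <- rep(c("x", "y"), each = 60)
  expect_equal(routeTest(v, l)$test, routeTest(v, rev(l))$test)
  expect_error(routeTest(rnorm(5), rep("only", 5)),
               class = "cogage_error_input")
})

test_that("two-group ANOVA agrees with hand formulas and library oracles", {
  v <- c(1, 2, 3, 4, 5, 6)
  l <- rep(c("a", "b"), each = 3)
  res <- anovaTwoGroup(v, l)
  expect_equal(res$statistic, 13.5, tolerance = 1e-12) # t = 3/sqrt(2/3)
  # cross-checks: F = t^2 and the stock one-way ANOVA
  tt <- t.test(v ~ l, var.equal = TRUE)
  expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(res$p.value, tt$p.value, tolerance = 1e-12)
  ow <- oneway.test(v ~ as.factor(l), var.equal = TRUE)
  expect_equal(res$statistic, unname(ow$statistic), tolerance = 1e-12)
  expect_equal(res$p.value, ow$p.value, tolerance = 1e-12)

  same <- anovaTwoGroup(c(1, 2, 3, 1, 2, 3), l)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  swapped <- anovaTwoGroup(v, rev(l))
  expect_equal(swapped$statistic, res$statistic)
  expect_equal(swapped$p.value, res$p.value)
  expect_error(anovaTwoGroup(c(1, 1, 2, 2), rep(c("a", "b"), each = 2)),
               class = "cogage_error_degenerate")
})

test_that("Mann-Whitney U counts pairs and matches exhaustive permutation", {
  expect_equal(bruteU(c(1, 2), c(3, 4)), 0)
  expect_equal(mannWhitney(c(1, 2, 3, 4), rep(c("x", "y"), each = 2))$statistic, 0)
  expect_equal(mannWhitney(c(1, 3, 2, 4), rep(c("x", "y"), each = 2))$statistic, 1)
  # perfect overlap: U = n1 n2 / 2 (midranks), p ~ 1
  tie <- mannWhitney(c(1, 2, 3, 1, 2, 3), rep(c("x", "y"), each = 3))
  expect_equal(tie$statistic, 4.5)
  expect_gte(tie$p.value, 0.9)

  # exact p equals the full-permutation p on tie-free instances, n1 = n2 <= 5
  set.seed(60)
  for (n in 3:5) {
    for (rep in 1:8) {
      x <- round(rnorm(n), 6)
      y <- round(rnorm(n) + runif(1, -1, 1), 6)
      got <- mannWhitney(c(x, y), rep(c("x", "y"), c(n, n)))
      expect_equal(got$statistic, bruteU(x, y))
      expect_equal(got$p.value, permutationP(x, y), tolerance = 1e-12)
    }
  }
})

test_that("chi-square matches hand computation and flags sparse tables", {
  res <- chiSquareTest(matrix(c(10, 20, 20, 10), 2))
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-10)
  expect_equal(res$df, 1)
  flat <- chiSquareTest(matrix(c(15, 15, 15, 15), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p.value, 1)
  m <- matrix(c(10, 20, 20, 10), 2)
  expect_equal(chiSquareTest(m[, 2:1])$statistic, res$statistic)
  # zero-margin level collapsed with a warning
  expect_warning(
    z <- chiSquareTest(matrix(c(10, 0, 20, 20, 0, 10), 3)),
    class = "cogage_warning_collapsed"
  )
  expect_equal(z$statistic, 20 / 3, tolerance = 1e-10)
  expect_warning(chiSquareTest(matrix(c(2, 3, 4, 1), 2)),
                 class = "cogage_warning_small_expected")
})

test_that("BH adjustment reproduces the step-up rule within families", {
  # hand enumeration at q = 0.01, m = 4: cuts 0.0025/0.005/0.0075/0.01
  res <- fdrBH(c(0.001, 0.008, 0.02, 0.9), "T1")
  expect_equal(res$q, c(0.004, 0.016, 0.8 / 30, 0.9), tolerance = 1e-12)
  expect_equal(res$significant, c(TRUE, FALSE, FALSE, FALSE))
  allOne <- fdrBH(rep(1, 5), "rsfMRI")
  expect_true(all(allOne$q == 1) && !any(allOne$significant))
  expect_error(fdrBH(0.5, "not_a_family"), class = "cogage_error_config")
  expect_error(fdrBH(1.5, "T1"), class = "cogage_error_input")

  # q >= p always; adjustment is family-local
  set.seed(70)
  p <- runif(40)
  fams <- rep(c("T1", "dMRI_tract"), each = 20)
  res2 <- fdrBH(p, fams)
  expect_true(all(res2$q >= res2$p))
  expect_equal(res2$q[fams == "T1"], fdrBH(p[1:20], "T1")$q)
})

test_that("the batch harness finds planted effects and flags bad rows", {
  set.seed(80)
  n <- 500
  labels <- factor(rep(c("SCA", "nonSCA"), each = n), c("SCA", "nonSCA"))
  dat <- list(
    planted = c(rnorm(n, 0.6), rnorm(n)),
    null1 = rnorm(2 * n),
    null2 = rnorm(2 * n),
    walking = factor(sample(c("slow", "brisk"), 2 * n, replace = TRUE)),
    broken = rep(1, 2 * n)
  )
  specs <- data.frame(
    name = names(dat),
    family = c("dMRI_skeleton", "dMRI_skeleton", "rsfMRI",
               "demographic", "T1"),
    scale = c("continuous", "continuous", "continuous", "nominal",
              "continuous")
  )
  cmp <- compareGroups(dat, labels, specs)
  expect_equal(nrow(cmp), 5L)
  row <- cmp[cmp$variable == "planted", ]
  expect_true(row$significant)
  expect_equal(row$direction, 1) # SCA mean higher
  expect_equal(cmp[cmp$variable == "walking", "test"], "chi_square")
  bad <- cmp[cmp$variable == "broken", ]
  expect_true(is.na(bad$p))
  expect_match(bad$note, "variance")
  # empty variable list gives an empty report
  expect_equal(nrow(compareGroups(list(), labels)), 0L)
})

test_that("the follow-up check separates similar and shifted variables", {
  set.seed(81)
  n <- 500
  cmp <- S4Vectors::DataFrame(
    variable = c("same", "shifted"), family = "dMRI_skeleton",
    scale = "continuous", test = "anova", statistic = c(30, 30),
    p = c(1e-6, 1e-6), direction = 1, q = c(1e-5, 1e-5),
    significant = c(TRUE, TRUE), note = NA_character_
  )
  labels <- factor(rep(c("SCA", "middle"), each = n), c("SCA", "middle"))
  dat <- list(
    same = rnorm(2 * n),                   # SCA and middle coincide
    shifted = c(rnorm(n, 1.0), rnorm(n))   # planted d = 1.0
  )
  fu <- followupMiddle(cmp, dat, labels)
  expect_true(fu$similarToMiddle[fu$variable == "same"])
  expect_false(fu$similarToMiddle[fu$variable == "shifted"])
  # missing variable is flagged, not fatal
  fu2 <- followupMiddle(cmp, dat["same"], labels)
  expect_match(fu2$note[fu2$variable == "shifted"], "absent")
  # only primary-significant variables appear
  cmp$significant <- c(FALSE, FALSE)
  expect_equal(nrow(followupMiddle(cmp, dat, labels)), 0L)
})
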
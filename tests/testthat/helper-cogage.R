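# Shared fixtures and independent oracles for the suite.

# Pooled-SD Cohen's d between two samples.
cohensD <- function(x, y) {
  sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
               (length(x) + length(y) - 2))
  (mean(x) - mean(y)) / sp
}

# Mann-Whitney U of x (pairs x_i > y_j, ties counted half) by direct
# enumeration -- independent of any rank-based implementation.
bruteU <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# Two-sided permutation p-value of the Mann-Whitney U over *all* label
# assignments (exhaustive, no ties assumed symmetric null distribution).
permutationP <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  m <- n1 * length(y) / 2
  obs <- abs(bruteU(x, y) - m)
  picks <- utils::combn(length(pool), n1)
  us <- apply(picks, 2, function(i) bruteU(pool[i], pool[-i]))
  mean(abs(us - m) >= obs - 1e-12)
}

# Small cohort with planted-effect knobs, shared across tests.
smallDesign <- function(nMiddle = 100, nOlder = 100, seed = 1, ...) {
  syntheticDesign(
    nMiddle = nMiddle, nOlder = nOlder,
    idpSpec = idpSpec(n = c(4L, 4L, 4L, 4L)),
    seed = seed, ...
  )
}

# Hand-built two-strata cohort with explicit battery scores (native
# direction) and no IDPs; `scores` is subjects x 9 named by test.
scoreCohort <- function(scores, stratum, age = NULL) {
  n <- nrow(scores)
  if (is.null(age)) age <- ifelse(stratum == "older", 70, 55)
  cd <- S4Vectors::DataFrame(
    stratum = stratum, age = age, scores,
    row.names = sprintf("S%03d", seq_len(n)), check.names = FALSE
  )
  subjectCohort(
    idps = matrix(numeric(0), 0, n, dimnames = list(NULL, rownames(cd))),
    colData = cd
  )
}

# Random native-direction score matrix under the one-factor law.
randomScores <- function(n, loading = 0.55, noise = 1, g = rnorm(n)) {
  bt <- batteryTests(testBattery())
  m <- sapply(seq_len(9), function(j) {
    y <- loading * g + rnorm(n, 0, noise)
    if (bt$direction[j] == "lower_better") -y else y
  })
  colnames(m) <- bt$name
  m
}
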
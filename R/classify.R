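#' Orient battery scores so that higher always means better
#'
#' The raw battery mixes counts of correct answers with durations and error
#' counts. Scores of `lower_better` tests are negated, `higher_better`
#' scores pass through, so every downstream threshold can read `>` as
#' "better than". The result carries an `oriented` attribute; orienting an
#' already-oriented matrix is an error, not a silent double negation.
#'
#' @param scores numeric matrix (subjects x tests) with test-name columns,
#'   or a [SubjectCohort-class] from which the battery scores are extracted.
#' @param battery a [TestBattery-class].
#' @return the oriented matrix with `attr(, "oriented") = TRUE`.
#' @export
orientScores <- function(scores, battery = testBattery()) {
  if (is(scores, "SubjectCohort")) {
    scores <- cognitiveScores(scores, battery)
  }
  if (isTRUE(attr(scores, "oriented"))) {
    cogageError("already_oriented", "scores are already oriented")
  }
  bt <- batteryTests(battery)
  missing <- setdiff(bt$name, colnames(scores))
  if (length(missing) > 0) {
    cogageError("schema", paste("missing test column(s):",
                                paste(missing, collapse = ", ")))
  }
  out <- scores[, bt$name, drop = FALSE]
  flip <- bt$name[bt$direction == "lower_better"]
  out[, flip] <- -out[, flip]
  attr(out, "oriented") <- TRUE
  out
}

#' Fit the generic cognitive score model
#'
#' Standardizes each oriented test score using the pooled mean and SD of the
#' fitting sample (middle-aged and older subjects together), extracts the
#' first principal component, and orients it so the projection correlates
#' positively with the mean standardized score (higher = better cognition).
#' The component is always PC1; its explained-variance fraction is recorded
#' and a warning is raised if it falls below 0.15, a sign that a single
#' general factor summarizes the battery poorly.
#'
#' @param oriented oriented score matrix from [orientScores()], pooled over
#'   both strata; complete cases only, at least 10 subjects.
#' @return a [GenericScoreModel-class].
#' @export
fitGenericModel <- function(oriented) {
  if (nrow(oriented) < 10L) {
    cogageError("input", "at least 10 subjects are required to fit the model")
  }
  if (anyNA(oriented)) {
    cogageError("input", "oriented scores contain missing values")
  }
  sds <- apply(oriented, 2, stats::sd)
  if (any(sds == 0)) {
    cogageError("degenerate", paste(
      "zero-variance test column(s):",
      paste(colnames(oriented)[sds == 0], collapse = ", ")
    ))
  }
  pc <- stats::prcomp(oriented, center = TRUE, scale. = TRUE)
  loadings <- pc$rotation[, 1L]
  evr <- pc$sdev[1L]^2 / sum(pc$sdev^2)
  scaled <- scale(oriented, center = pc$center, scale = pc$scale)
  s <- stats::cov(drop(scaled %*% loadings), rowMeans(scaled))
  sgn <- if (s < 0) -1 else 1
  if (evr < 0.15) {
    cogageWarning("low_variance", sprintf(
      "first component explains only %.1f%% of battery variance", 100 * evr
    ))
  }
  new("GenericScoreModel",
    loadings = loadings, sign = sgn, explainedVariance = evr,
    center = pc$center, scale = pc$scale
  )
}

#' Project subjects onto the generic cognitive score
#'
#' Applies the model's stored per-test standardization and loading vector to
#' an oriented score matrix, returning one scalar generic score per subject.
#' Flipping the stored loading vector together with its sign leaves the
#' projection unchanged.
#'
#' @param model a [GenericScoreModel-class].
#' @param oriented oriented score matrix; columns must match the model's
#'   test set.
#' @return named numeric vector of generic scores.
#' @export
projectGeneric <- function(model, oriented) {
  nm <- names(model@loadings)
  if (!all(nm %in% colnames(oriented))) {
    cogageError("schema", "oriented score columns do not match the fitted model")
  }
  scaled <- scale(oriented[, nm, drop = FALSE],
                  center = model@center, scale = model@scale)
  out <- model@sign * drop(scaled %*% model@loadings)
  names(out) <- rownames(oriented)
  out
}

#' Z-standardize against a reference
#'
#' `(x - mean) / sd` against an explicit reference mean and SD. Used for the
#' dual-reference standardization of the cascade: every score is
#' standardized once against the older group's own statistics and once
#' against the middle-aged group's.
#'
#' @param values numeric vector.
#' @param ref numeric `c(mean, sd)` (or a list with `mean`/`sd`), as from
#'   [referenceStats()].
#' @return numeric vector of Z-scores.
#' @examples
#' zScore(c(5, 7), ref = c(mean = 5, sd = 2))
#' @export
zScore <- function(values, ref) {
  m <- unname(ref[["mean"]] %||% ref[[1L]])
  s <- unname(ref[["sd"]] %||% ref[[2L]])
  if (!is.finite(s) || s <= 0) {
    cogageError("degenerate", "reference SD must be positive")
  }
  (values - m) / s
}

#' @rdname zScore
#' @details `referenceStats()` computes the `(mean, sd)` pair of a sample,
#'   erroring (with the offending score named) when the SD is zero.
#' @param name label used in error messages.
#' @export
referenceStats <- function(values, name = "score") {
  s <- stats::sd(values)
  if (!is.finite(s) || s <= 0) {
    cogageError("degenerate", sprintf("reference SD for '%s' is not positive", name))
  }
  c(mean = mean(values), sd = s)
}

#' Generic-stage pass decision
#'
#' An older subject passes the generic stage when its generic cognitive
#' score lies strictly in the upper quartile of the older distribution
#' (self-referenced Z > 0.67) *and* strictly above the middle-aged mean
#' (middle-referenced Z > 0). Both Z values are retained for audit.
#'
#' @param generic generic scores of the older subjects.
#' @param selfRef,midRef `(mean, sd)` references computed on the older and
#'   middle-aged generic score distributions.
#' @param thresholds numeric `c(self, mid)`; strict lower bounds.
#' @return a [S4Vectors::DataFrame] with `zSelf`, `zMid`, `pass`.
#' @export
classifyGeneric <- function(generic, selfRef, midRef,
                            thresholds = c(self = 0.67, mid = 0)) {
  zs <- zScore(generic, selfRef)
  zm <- zScore(generic, midRef)
  S4Vectors::DataFrame(
    zSelf = zs, zMid = zm,
    pass = zs > thresholds[["self"]] & zm > thresholds[["mid"]],
    row.names = names(generic)
  )
}

#' Specific-stage pass decision
#'
#' Applies the per-test criteria to the four specific tests: an oriented
#' score must lie strictly above the older-group mean (self-referenced
#' Z > 0) and strictly above -0.67 when standardized against the
#' middle-aged group, on *all four* tests.
#'
#' @param oriented oriented score matrix of the subjects under evaluation.
#' @param battery a [TestBattery-class]; its `specificTests` are evaluated.
#' @param selfRef,midRef named lists of per-test `(mean, sd)` references
#'   covering all four specific tests.
#' @param thresholds numeric `c(self, mid)`; strict lower bounds.
#' @return a [S4Vectors::DataFrame] with per-test `zSelf_*`, `zMid_*`,
#'   `pass_*` columns and the conjunction `pass`.
#' @export
classifySpecific <- function(oriented, battery, selfRef, midRef,
                             thresholds = c(self = 0, mid = -0.67)) {
  tests <- specificTests(battery)
  missing <- setdiff(tests, intersect(names(selfRef), names(midRef)))
  if (length(missing) > 0) {
    cogageError("schema", paste("references missing specific test(s):",
                                paste(missing, collapse = ", ")))
  }
  out <- S4Vectors::DataFrame(matrix(nrow = nrow(oriented), ncol = 0),
                              row.names = rownames(oriented))
  pass <- rep(TRUE, nrow(oriented))
  for (t in tests) {
    zs <- zScore(oriented[, t], selfRef[[t]])
    zm <- zScore(oriented[, t], midRef[[t]])
    p <- zs > thresholds[["self"]] & zm > thresholds[["mid"]]
    out[[paste0("zSelf_", t)]] <- zs
    out[[paste0("zMid_", t)]] <- zm
    out[[paste0("pass_", t)]] <- p
    pass <- pass & p
  }
  out$pass <- pass
  out
}

#' Default cascade thresholds
#'
#' The generic stage retains older subjects with self-referenced Z
#' strictly above 0.67 (the printed upper-quartile cut; the exact 0.75
#' normal quantile is 0.6745) and middle-referenced Z strictly above 0;
#' the specific stage requires self-referenced Z strictly above 0 and
#' middle-referenced Z strictly above -0.67 on all four specific tests.
#'
#' @return named list of the four thresholds.
#' @export
scaThresholds <- function() {
  list(genericSelf = 0.67, genericMid = 0, specificSelf = 0, specificMid = -0.67)
}

#' Classify a cohort into successful / non-successful cognitive aging
#'
#' End-to-end threshold cascade: orient the battery, fit the generic score
#' model on the pooled (middle-aged + older) complete-case sample, project
#' all subjects, apply the generic two-threshold stage to the older
#' stratum, then the four-test specific stage to the generic-stage
#' survivors. Subjects failing the generic stage are labelled `nonSCA`
#' without specific-stage evaluation (their specific-stage columns are
#' `NA`). Reference statistics are always computed on the full older and
#' middle-aged strata.
#'
#' @param cohort a [SubjectCohort-class] containing both strata.
#' @param battery a [TestBattery-class].
#' @param thresholds list as from [scaThresholds()].
#' @return a [ScaClassification-class] with per-subject audit columns and
#'   per-stage retention counts.
#' @examples
#' cohort <- simulateCohort(syntheticDesign(nMiddle = 300, nOlder = 300, seed = 7))
#' cls <- classifyCohort(cohort)
#' stageCounts(cls)
#' @export
classifyCohort <- function(cohort, battery = testBattery(),
                           thresholds = scaThresholds()) {
  scores <- cognitiveScores(cohort, battery)
  stratum <- SummarizedExperiment::colData(cohort)$stratum
  keep <- stats::complete.cases(scores)
  nDropped <- sum(!keep)
  scores <- scores[keep, , drop = FALSE]
  stratum <- stratum[keep]
  if (!any(stratum == "older") || !any(stratum == "middle")) {
    cogageError("input", "both strata must be present with complete battery data")
  }

  oriented <- orientScores(scores, battery)
  model <- fitGenericModel(oriented)
  generic <- projectGeneric(model, oriented)

  older <- stratum == "older"
  selfRefG <- referenceStats(generic[older], "generic")
  midRefG <- referenceStats(generic[!older], "generic")
  gRes <- classifyGeneric(generic[older], selfRefG, midRefG,
    thresholds = c(self = thresholds$genericSelf, mid = thresholds$genericMid))

  tests <- specificTests(battery)
  selfRefT <- lapply(stats::setNames(tests, tests), function(t) {
    referenceStats(oriented[older, t], t)
  })
  midRefT <- lapply(stats::setNames(tests, tests), function(t) {
    referenceStats(oriented[!older, t], t)
  })

  nOlder <- sum(older)
  subj <- S4Vectors::DataFrame(
    zSelfGeneric = gRes$zSelf, zMidGeneric = gRes$zMid,
    genericPass = gRes$pass, row.names = rownames(gRes)
  )
  specCols <- as.vector(t(outer(c("zSelf_", "zMid_", "pass_"), tests, paste0)))
  for (cc in specCols) {
    subj[[cc]] <- if (startsWith(cc, "pass_")) rep(NA, nOlder) else rep(NA_real_, nOlder)
  }
  label <- rep("nonSCA", nOlder)

  surv <- which(gRes$pass)
  if (length(surv) > 0) {
    sRes <- classifySpecific(
      oriented[older, , drop = FALSE][surv, , drop = FALSE], battery,
      selfRefT, midRefT,
      thresholds = c(self = thresholds$specificSelf, mid = thresholds$specificMid)
    )
    for (cc in setdiff(colnames(sRes), "pass")) subj[[cc]][surv] <- sRes[[cc]]
    label[surv][sRes$pass] <- "SCA"
  }
  subj$label <- label

  counts <- c(
    nOlderInput = nOlder, nAfterGeneric = length(surv),
    nFinalSca = sum(label == "SCA"), nFinalNonSca = sum(label == "nonSCA")
  )
  new("ScaClassification",
    subjects = subj, stageCounts = stats::setNames(as.integer(counts), names(counts)),
    model = model,
    references = list(
      generic = list(self = selfRefG, middle = midRefG),
      tests = list(self = selfRefT, middle = midRefT)
    ),
    thresholds = thresholds, nDropped = as.integer(nDropped)
  )
}

#' @rdname ScaClassification-class
#' @aliases stageCounts
#' @export
setMethod("stageCounts", "ScaClassification", function(x) {
  stats::setNames(x@stageCounts,
    c("nOlderInput", "nAfterGeneric", "nFinalSca", "nFinalNonSca"))
})

#' @rdname ScaClassification-class
#' @aliases subjectResults
#' @export
setMethod("subjectResults", "ScaClassification", function(x) x@subjects)

#' @rdname ScaClassification-class
#' @aliases scaLabels
#' @export
setMethod("scaLabels", "ScaClassification", function(x) {
  stats::setNames(x@subjects$label, rownames(x@subjects))
})

#' @rdname ScaClassification-class
#' @aliases genericModel
#' @export
setMethod("genericModel", "ScaClassification", function(x) x@model)

setMethod("show", "ScaClassification", function(object) {
  sc <- stageCounts(object)
  cat("ScaClassification\n")
  cat(sprintf("  older subjects     : %d (%d dropped, incomplete battery)\n",
              sc["nOlderInput"], object@nDropped))
  cat(sprintf("  after generic stage: %d\n", sc["nAfterGeneric"]))
  cat(sprintf("  final SCA / nonSCA : %d / %d\n",
              sc["nFinalSca"], sc["nFinalNonSca"]))
  cat(sprintf("  PC1 explained variance: %.1f%%\n",
              100 * object@model@explainedVariance))
})
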
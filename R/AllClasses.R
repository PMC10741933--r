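#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom S4Vectors DFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Cognitive test battery
#'
#' Describes the nine-test neuropsychological battery: test name, the
#' biobank-style numeric field identifier used as a column alias in phenotype
#' files, the cognitive domain assessed, and the direction in which raw scores
#' improve (`"higher_better"` for counts of correct answers,
#' `"lower_better"` for durations and error counts). A four-test subset
#' (`specificTests`) drives the second, per-test stage of the classifier.
#'
#' @slot tests `data.frame` with columns `name`, `fieldId`, `domain`,
#'   `direction`; exactly nine rows, unique names.
#' @slot specificTests character vector of four test names, a subset of
#'   `tests$name`.
#'
#' @seealso [testBattery()] for the default battery.
#' @exportClass TestBattery
setClass("TestBattery",
  slots = c(tests = "data.frame", specificTests = "character")
)

setValidity("TestBattery", function(object) {
  t <- object@tests
  need <- c("name", "fieldId", "domain", "direction")
  if (!all(need %in% names(t))) {
    return(paste("tests must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(t) != 9L) return("a battery has exactly 9 tests")
  if (anyDuplicated(t$name)) return("test names must be unique")
  if (!all(t$direction %in% c("higher_better", "lower_better"))) {
    return("direction must be 'higher_better' or 'lower_better'")
  }
  if (length(object@specificTests) != 4L) {
    return("specificTests must name exactly 4 tests")
  }
  if (!all(object@specificTests %in% t$name)) {
    return("specificTests must be a subset of the battery test names")
  }
  TRUE
})

#' Generic cognitive score model
#'
#' The first principal component of the per-test standardized, oriented
#' battery, fitted on the pooled middle-aged + older sample. Projection of a
#' subject's standardized score vector onto `loadings`, multiplied by `sign`,
#' is the subject's generic cognitive score. `sign` is chosen so that the
#' score correlates positively with the mean standardized oriented score,
#' i.e. higher = better cognition.
#'
#' @slot loadings named numeric, unit Euclidean norm; one weight per test.
#' @slot sign `+1` or `-1`, orientation of the component.
#' @slot explainedVariance fraction of total variance captured by the
#'   retained component, in `[0, 1]`.
#' @slot center,scale named numerics: pooled per-test mean and standard
#'   deviation used to standardize inputs before projection.
#'
#' @exportClass GenericScoreModel
setClass("GenericScoreModel",
  slots = c(
    loadings = "numeric", sign = "numeric",
    explainedVariance = "numeric", center = "numeric", scale = "numeric"
  )
)

setValidity("GenericScoreModel", function(object) {
  if (abs(sqrt(sum(object@loadings^2)) - 1) > 1e-6) {
    return("loadings must have unit Euclidean norm")
  }
  if (!object@sign %in% c(-1, 1)) return("sign must be +1 or -1")
  ev <- object@explainedVariance
  if (length(ev) != 1L || ev < 0 || ev > 1) {
    return("explainedVariance must be a single value in [0, 1]")
  }
  if (any(object@scale <= 0)) return("all scale entries must be positive")
  if (!identical(names(object@loadings), names(object@center)) ||
      !identical(names(object@loadings), names(object@scale))) {
    return("loadings, center and scale must share the same test names")
  }
  TRUE
})

#' Per-subject phenotype container
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one cohort: the
#' `"idps"` assay is a variables-by-subjects matrix of image-derived
#' phenotypes with per-variable metadata in `rowData` (`family`, `scale`,
#' `volumetric`), and `colData` carries the per-subject stratum, age, sex,
#' raw cognitive scores, the five confounds plus the T1 head-size scaling
#' factor, and demographic indicators. `metadata()` records the age cut-off
#' separating the strata and, for simulated cohorts, the generating design.
#'
#' @seealso [simulateCohort()], [readPhenotypeTable()]
#' @exportClass SubjectCohort
setClass("SubjectCohort", contains = "SummarizedExperiment")

setValidity("SubjectCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  if (ncol(object) > 0 &&
      (is.null(colnames(object)) || anyDuplicated(colnames(object)))) {
    return("subject identifiers (colnames) must be present and unique")
  }
  need <- c("stratum", "age")
  if (!all(need %in% names(cd))) {
    return("colData must contain 'stratum' and 'age'")
  }
  if (!all(cd$stratum %in% c("middle", "older"))) {
    return("stratum must be 'middle' or 'older'")
  }
  cutoff <- S4Vectors::metadata(object)$ageCutoff %||% 65
  older <- cd$stratum == "older"
  if (any(cd$age[older] < cutoff) || any(cd$age[!older] >= cutoff)) {
    return(sprintf("stratum labels inconsistent with the age cut-off (%g)", cutoff))
  }
  if ("age_sq" %in% names(cd) && any(cd$age_sq != cd$age^2)) {
    return("age_sq must equal age squared exactly")
  }
  if (nrow(object) > 0) {
    rd <- SummarizedExperiment::rowData(object)
    if (!"family" %in% names(rd)) return("rowData must contain 'family'")
    if (!all(rd$family %in% idpFamilies())) {
      return(paste("rowData$family must be one of:", paste(idpFamilies(), collapse = ", ")))
    }
    if (anyDuplicated(c(rownames(object), names(cd)))) {
      return("variable names duplicated across IDPs and subject-level columns")
    }
  }
  TRUE
})

#' Result of the successful-cognitive-aging threshold cascade
#'
#' Per-subject audit trail and per-stage retention counts for the two-stage
#' classifier: the generic stage (PCA score in the older upper quartile
#' *and* above the middle-aged mean) followed by the four-test specific
#' stage. `subjects` holds, for every older subject, both Z-scores per
#' criterion, stage pass flags, and the final `SCA` / `nonSCA` label.
#'
#' @slot subjects a [S4Vectors::DataFrame] keyed by subject id.
#' @slot stageCounts named integer vector: `nOlderInput`, `nAfterGeneric`,
#'   `nFinalSca`, `nFinalNonSca`.
#' @slot model the fitted [GenericScoreModel-class].
#' @slot references list of per-score `(mean, sd)` reference statistics for
#'   the older (`self`) and middle-aged (`middle`) groups.
#' @slot thresholds list of the four cascade thresholds.
#' @slot nDropped integer, subjects removed for incomplete battery data.
#'
#' @seealso [classifyCohort()]
#' @exportClass ScaClassification
setClass("ScaClassification",
  slots = c(
    subjects = "DFrame", stageCounts = "integer",
    model = "GenericScoreModel", references = "list",
    thresholds = "list", nDropped = "integer"
  )
)

setValidity("ScaClassification", function(object) {
  sc <- object@stageCounts
  need <- c("nOlderInput", "nAfterGeneric", "nFinalSca", "nFinalNonSca")
  if (!identical(names(sc), need)) {
    return(paste("stageCounts must be named:", paste(need, collapse = ", ")))
  }
  if (sc["nFinalSca"] + sc["nFinalNonSca"] != sc["nOlderInput"]) {
    return("nFinalSca + nFinalNonSca must equal nOlderInput")
  }
  if (sc["nFinalSca"] > sc["nAfterGeneric"] ||
      sc["nAfterGeneric"] > sc["nOlderInput"]) {
    return("stage counts must be non-increasing along the cascade")
  }
  lab <- object@subjects$label
  if (!is.null(lab) && !all(lab %in% c("SCA", "nonSCA"))) {
    return("labels must be 'SCA' or 'nonSCA'")
  }
  TRUE
})

#' Confound residualization fit
#'
#' Ordinary least-squares fit of every IDP on the confound design
#' (intercept + centered age, age squared, height, head motion, scanner
#' table position), with the residuals that replace the raw IDPs in group
#' testing. Residuals are orthogonal to every design column.
#'
#' @slot design the centered design matrix (subjects x 6).
#' @slot centers per-column means removed from the non-intercept columns.
#' @slot coefficients 6 x variables coefficient matrix.
#' @slot residuals subjects x variables residual matrix.
#'
#' @seealso [residualizeIdps()]
#' @exportClass ConfoundFit
setClass("ConfoundFit",
  slots = c(
    design = "matrix", centers = "numeric",
    coefficients = "matrix", residuals = "matrix"
  )
)
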
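#' Head-size normalization of volumetric IDPs
#'
#' Multiplies each subject's volumetric measurements by the T1 scaling
#' factor — the volumetric scaling from native head size to standard space —
#' so that two subjects with identical standard-space anatomy but different
#' head sizes obtain equal normalized volumes. Applies only to variables
#' flagged volumetric; thicknesses, diffusion measures and network
#' amplitudes are left untouched.
#'
#' @param volumes numeric vector or variables-x-subjects matrix of
#'   volumetric IDPs.
#' @param scaleFactor per-subject positive T1 scaling factors.
#' @return normalized volumes, same shape as the input.
#' @examples
#' normalizeHeadSize(c(1000, 1000), c(1.0, 1.2))
#' @export
normalizeHeadSize <- function(volumes, scaleFactor) {
  bad <- which(!is.finite(scaleFactor) | scaleFactor <= 0)
  if (length(bad) > 0) {
    nm <- names(scaleFactor)[bad] %||% as.character(bad)
    cogageError("data", paste("non-positive T1 scaling factor for subject(s):",
                              paste(utils::head(nm, 5), collapse = ", ")))
  }
  if (is.matrix(volumes)) {
    sweep(volumes, 2, scaleFactor, "*")
  } else {
    volumes * scaleFactor
  }
}

#' @rdname normalizeHeadSize
#' @details `normalizeCohortHeadSize()` applies the normalization in place
#'   to the volumetric rows of a cohort's IDP assay, using the
#'   `t1_scale_factor` column of `colData`.
#' @param cohort a [SubjectCohort-class].
#' @export
normalizeCohortHeadSize <- function(cohort) {
  vol <- SummarizedExperiment::rowData(cohort)$volumetric
  if (!any(vol)) return(cohort)
  sf <- SummarizedExperiment::colData(cohort)$t1_scale_factor
  if (is.null(sf)) {
    cogageError("schema", "colData lacks 't1_scale_factor'")
  }
  names(sf) <- colnames(cohort)
  a <- SummarizedExperiment::assay(cohort, "idps")
  a[vol, ] <- normalizeHeadSize(a[vol, , drop = FALSE], sf)
  SummarizedExperiment::assay(cohort, "idps") <- a
  cohort
}

#' Build the confound design matrix
#'
#' Intercept plus the five mean-centered covariates: age, age squared
#' (squared before centering), height, head motion, and scanner table
#' position. The design is checked for full column rank; a zero-variance or
#' collinear column is reported by name. Group labels are never part of the
#' design, so deconfounding is blind to classification outcomes.
#'
#' @param cohort a [SubjectCohort-class], or a `data.frame` with columns
#'   `age`, `height`, `head_motion`, `table_position` (and optionally
#'   `age_sq`).
#' @param extra optional character vector of additional `colData` columns to
#'   include as centered covariates (e.g. `"sex"` is deliberately not a
#'   default confound).
#' @return a list with the centered design `matrix`, the removed `centers`,
#'   and the column names; input to [residualizeIdps()].
#' @export
buildConfoundDesign <- function(cohort, extra = character(0)) {
  cd <- if (is(cohort, "SummarizedExperiment")) {
    as.data.frame(SummarizedExperiment::colData(cohort))
  } else {
    as.data.frame(cohort)
  }
  base <- setdiff(confoundNames(), "age_sq")
  missing <- setdiff(base, names(cd))
  if (length(missing) > 0) {
    cogageError("schema", paste("missing confound column(s):",
                                paste(missing, collapse = ", ")))
  }
  cols <- c("age", "age_sq", "height", "head_motion", "table_position", extra)
  raw <- cbind(
    age = cd$age, age_sq = cd$age^2, height = cd$height,
    head_motion = cd$head_motion, table_position = cd$table_position
  )
  for (e in extra) {
    v <- cd[[e]]
    if (is.null(v)) cogageError("schema", paste("missing confound column:", e))
    raw <- cbind(raw, stats::setNames(list(as.numeric(as.factor(v))), e)[[1]])
    colnames(raw)[ncol(raw)] <- e
  }
  centers <- colMeans(raw)
  centered <- sweep(raw, 2, centers, "-")
  X <- cbind(intercept = 1, centered)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[-sort(qrX$pivot[seq_len(qrX$rank)])]
    cogageError("degenerate", paste(
      "confound design is rank deficient; collinear or constant column(s):",
      paste(dropped, collapse = ", ")
    ))
  }
  rownames(X) <- rownames(cd)
  list(matrix = X, centers = centers, columns = colnames(X))
}

#' Residualize IDPs against the confound design
#'
#' Ordinary least-squares fit of each variable on the confound design over
#' the pooled sample (both outcome groups together, so group differences
#' are not absorbed), returning residuals that replace the raw IDPs in all
#' group testing. Residuals are orthogonal to every design column to within
#' 1e-8 relative tolerance and have mean ~0; residualization is idempotent.
#'
#' @param idps numeric matrix, subjects x variables (or variables x
#'   subjects with `transposed = TRUE`), or a named list of vectors.
#' @param design the design from [buildConfoundDesign()].
#' @param transposed set `TRUE` when `idps` is variables x subjects.
#' @return a [ConfoundFit-class] with residuals (subjects x variables) and
#'   per-variable coefficients.
#' @examples
#' cohort <- simulateCohort(syntheticDesign(nMiddle = 40, nOlder = 40, seed = 2))
#' des <- buildConfoundDesign(cohort)
#' fit <- residualizeIdps(idpMatrix(cohort), des, transposed = TRUE)
#' max(abs(crossprod(des$matrix, residualMatrix(fit))))
#' @export
residualizeIdps <- function(idps, design, transposed = FALSE) {
  if (is.list(idps) && !is.matrix(idps)) {
    idps <- do.call(cbind, idps)
  }
  if (transposed) idps <- t(idps)
  X <- design$matrix
  if (nrow(idps) != nrow(X)) {
    cogageError("schema", sprintf(
      "row mismatch: %d subjects in IDPs vs %d in design", nrow(idps), nrow(X)
    ))
  }
  qrX <- qr(X)
  coef <- qr.coef(qrX, idps)
  res <- qr.resid(qrX, idps)
  new("ConfoundFit",
    design = X, centers = design$centers,
    coefficients = coef, residuals = res
  )
}

#' @rdname ConfoundFit-class
#' @aliases residualMatrix
#' @param x a `ConfoundFit`.
#' @export
setMethod("residualMatrix", "ConfoundFit", function(x) x@residuals)

#' @rdname ConfoundFit-class
#' @aliases confoundCoefficients
#' @export
setMethod("confoundCoefficients", "ConfoundFit", function(x) x@coefficients)

#' @rdname residualizeIdps
#' @details `applyResidualization()` adjusts new subjects (e.g. the
#'   middle-aged stratum in the follow-up comparison) with the coefficients
#'   estimated on the fitting sample, without refitting.
#' @param fit a [ConfoundFit-class].
#' @param cohort a [SubjectCohort-class] providing confounds and IDPs for
#'   the new subjects.
#' @export
applyResidualization <- function(fit, cohort) {
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  raw <- cbind(
    age = cd$age, age_sq = cd$age^2, height = cd$height,
    head_motion = cd$head_motion, table_position = cd$table_position
  )
  X <- cbind(intercept = 1, sweep(raw, 2, fit@centers[colnames(raw)], "-"))
  vars <- colnames(fit@coefficients)
  Y <- t(SummarizedExperiment::assay(cohort, "idps")[vars, , drop = FALSE])
  res <- Y - X[, rownames(fit@coefficients), drop = FALSE] %*% fit@coefficients
  rownames(res) <- colnames(cohort)
  res
}

setMethod("show", "ConfoundFit", function(object) {
  cat("ConfoundFit:", ncol(object@residuals), "variables residualized on",
      ncol(object@design), "design columns,",
      nrow(object@residuals), "subjects\n")
})
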
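## Generator constants: confounds enter IDPs after centering/scaling by these
## fixed population values, so confound weights are in SD units.
.confCenters <- c(
  age = 65, age_sq = 65^2, height = 169, head_motion = 0.1, table_position = 0
)
.confScales <- c(
  age = 10, age_sq = 1350, height = 9, head_motion = 0.05, table_position = 5
)

.demoContinuous <- data.frame(
  name = c(
    "grip_strength_left", "grip_strength_right", "time_spent_watching_tv",
    "time_spent_driving", "diastolic_bp", "systolic_bp"
  ),
  mean = c(28, 30, 3, 1.5, 80, 138),
  sd = c(8, 8.5, 1.5, 1.2, 10, 18),
  nonneg = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
  stringsAsFactors = FALSE
)

.demoNominal <- list(
  usual_walking_pace = c(slow = 0.07, steady = 0.52, brisk = 0.41),
  alcohol_intake_frequency = c(
    daily = 0.20, three_four_per_week = 0.25, once_twice_per_week = 0.26,
    one_three_per_month = 0.11, special_occasions = 0.11, never = 0.07
  ),
  drinking_status = c(never = 0.04, previous = 0.04, current = 0.92),
  smoking_status = c(never = 0.55, previous = 0.35, current = 0.10),
  past_tobacco_smoking = c(
    most_days = 0.30, occasionally = 0.12, once_or_twice = 0.23, never = 0.35
  ),
  diabetes = c(no = 0.94, yes = 0.06)
)

#' Default IDP family layout
#'
#' One row per modality family: number of variables, planted standardized
#' effect size of high-latent-cognition membership (in units of the family's
#' residual SD), and residual noise SD. The default layout is a reduced,
#' desk-scale version of the full biobank IDP battery (which has hundreds of
#' variables per family) with no planted effects.
#'
#' @param families family labels; a subset of
#'   `c("T1", "dMRI_skeleton", "dMRI_tract", "rsfMRI")`.
#' @param n,effect,noiseSd recycled per family.
#' @return a `data.frame` usable as the `idpSpec` of [syntheticDesign()].
#' @export
idpSpec <- function(families = c("T1", "dMRI_skeleton", "dMRI_tract", "rsfMRI"),
                    n = c(20L, 20L, 20L, 21L), effect = 0, noiseSd = 1) {
  data.frame(
    family = families,
    n = as.integer(rep_len(n, length(families))),
    effect = rep_len(effect, length(families)),
    noiseSd = rep_len(noiseSd, length(families)),
    stringsAsFactors = FALSE
  )
}

setClass("SyntheticDesign",
  slots = c(
    nMiddle = "integer", nOlder = "integer",
    loadings = "numeric", testNoiseSd = "numeric",
    idpSpec = "data.frame", confoundEffects = "ANY",
    ageMiddle = "integer", ageOlder = "integer", ageCutoff = "numeric",
    olderShift = "numeric", gAgeSlope = "numeric",
    demoEffect = "numeric", demoAssoc = "numeric",
    battery = "TestBattery", seed = "integer"
  )
)

setValidity("SyntheticDesign", function(object) {
  if (object@nMiddle <= 0L || object@nOlder <= 0L) {
    return("stratum sizes must be positive")
  }
  if (any(object@testNoiseSd < 0)) return("test noise SDs must be >= 0")
  if (any(object@idpSpec$noiseSd < 0)) return("IDP noise SDs must be >= 0")
  if (!all(object@idpSpec$family %in% idpFamilies())) {
    return(paste("idpSpec family labels must be one of:",
                 paste(idpFamilies(), collapse = ", ")))
  }
  TRUE
})

#' Specify a synthetic cohort
#'
#' Defines the generative law of a synthetic cohort with the statistical
#' structure the downstream analysis assumes: a single latent
#' general-cognition factor `g` per subject (standard normal within stratum,
#' with a configurable mean shift for the older stratum and an optional
#' within-stratum age slope), nine battery scores `loading * g + noise`
#' emitted in each test's native direction, modality-structured IDP blocks
#' with planted standardized group effects, the five confounds plus a T1
#' head-size scaling factor, and demographic indicators.
#'
#' Defaults reproduce the study conditions the analysis was designed for:
#' strata of 9050 middle-aged and 8022 older subjects split at age 65,
#' uniform loadings of 0.55 with unit residual SD (so the first principal
#' component of the battery explains roughly 30% of the variance), and
#' reduced-dimensionality IDP families with no planted effects.
#'
#' @param nMiddle,nOlder stratum sizes (subjects).
#' @param loadings per-test weights on `g`; length 9, ordered as the battery.
#' @param testNoiseSd per-test residual SD; length 1 or 9.
#' @param idpSpec a `data.frame` as returned by [idpSpec()]: columns
#'   `family`, `n`, `effect`, `noiseSd`. Rows with family `"demographic"`
#'   add continuous demographic indicators instead of assay IDPs.
#' @param confoundEffects per-confound weights (SD units) applied to every
#'   IDP: a named length-5 numeric, or a variables-by-5 matrix for per-IDP
#'   weights. `NULL` for no confound contributions.
#' @param ageMiddle,ageOlder inclusive integer age ranges (years) per stratum.
#' @param ageCutoff years; stratum boundary.
#' @param olderShift mean of `g` in the older stratum (SD units; middle = 0).
#' @param gAgeSlope decline of the mean of `g` per year of age within
#'   stratum (SD units/year).
#' @param demoEffect standardized shift of continuous demographic indicators
#'   for subjects in the upper half of the within-stratum `g` distribution;
#'   single value or named per indicator.
#' @param demoAssoc log-odds tilt per unit `g` toward later levels of each
#'   nominal demographic indicator; single value or named per indicator.
#' @param battery the [TestBattery-class] whose names and directions the
#'   scores follow.
#' @param seed integer; fully determines the generated cohort.
#'
#' @return a `SyntheticDesign` object for [simulateCohort()].
#' @examples
#' des <- syntheticDesign(nMiddle = 50, nOlder = 40, seed = 1)
#' cohort <- simulateCohort(des)
#' table(cohort$stratum)
#' @export
syntheticDesign <- function(nMiddle = 9050, nOlder = 8022,
                            loadings = rep(0.55, 9), testNoiseSd = 1,
                            idpSpec = cogage::idpSpec(),
                            confoundEffects = c(
                              age = -0.2, age_sq = 0, height = 0.05,
                              head_motion = -0.15, table_position = 0.05
                            ),
                            ageMiddle = c(45L, 64L), ageOlder = c(65L, 81L),
                            ageCutoff = 65, olderShift = -0.5,
                            gAgeSlope = 0.03,
                            demoEffect = 0, demoAssoc = 0,
                            battery = testBattery(), seed = 1L) {
  if (nMiddle <= 0 || nOlder <= 0) {
    cogageError("config", "stratum sizes must be positive counts")
  }
  if (!all(idpSpec$family %in% idpFamilies())) {
    bad <- setdiff(unique(idpSpec$family), idpFamilies())
    cogageError("config", paste("unknown IDP family label(s):",
                                paste(bad, collapse = ", ")))
  }
  tests <- batteryTests(battery)$name
  loadings <- stats::setNames(rep_len(loadings, 9L), tests)
  testNoiseSd <- stats::setNames(rep_len(testNoiseSd, 9L), tests)
  if (any(testNoiseSd < 0) || any(idpSpec$noiseSd < 0)) {
    cogageError("config", "noise SDs must be non-negative")
  }
  new("SyntheticDesign",
    nMiddle = as.integer(nMiddle), nOlder = as.integer(nOlder),
    loadings = loadings, testNoiseSd = testNoiseSd,
    idpSpec = idpSpec, confoundEffects = confoundEffects,
    ageMiddle = as.integer(ageMiddle), ageOlder = as.integer(ageOlder),
    ageCutoff = ageCutoff, olderShift = olderShift, gAgeSlope = gAgeSlope,
    demoEffect = demoEffect, demoAssoc = demoAssoc,
    battery = battery, seed = as.integer(seed)
  )
}

.effectFor <- function(spec, name, default = 0) {
  if (length(spec) == 1L && is.null(names(spec))) return(spec)
  if (name %in% names(spec)) spec[[name]] else default
}

.idpNames <- function(idpSpec) {
  used <- integer(0) # per-family counters, continued across spec rows
  out <- character(0)
  for (i in seq_len(nrow(idpSpec))) {
    fam <- idpSpec$family[i]
    n <- idpSpec$n[i]
    if (n == 0L) next
    k <- (used[fam] %||% 0L)
    if (is.na(k)) k <- 0L
    idx <- k + seq_len(n)
    used[fam] <- k + n
    nm <- switch(fam,
      T1 = {
        nVol <- ceiling(n / 2)
        c(sprintf("t1_vol_%03d", idx[seq_len(nVol)]),
          if (n > nVol) sprintf("t1_thick_%03d", idx[-seq_len(nVol)]))
      },
      dMRI_skeleton = sprintf("dmri_skel_%03d", idx),
      dMRI_tract = sprintf("dmri_tract_%03d", idx),
      rsfMRI = sprintf("rsfmri_ic_%02d", idx),
      demographic = sprintf("demo_extra_%03d", idx)
    )
    out <- c(out, nm)
  }
  out
}

#' Generate a synthetic cohort
#'
#' Draws one cohort from the generative law in a [syntheticDesign()]. The
#' output is a pure function of the design (including its seed): identical
#' designs give bit-identical cohorts. [simulateNullCohort()] draws from the
#' same design with every planted IDP and demographic effect forced to zero,
#' so group membership carries no information beyond confound structure --
#' the calibration fixture for false-discovery-rate checks.
#'
#' @param design a `SyntheticDesign`.
#' @return a [SubjectCohort-class]. Latent truth columns (`latent_g`,
#'   `latent_g_high`) are retained in `colData` for oracle checks; they are
#'   not treated as demographic indicators downstream.
#' @export
simulateCohort <- function(design) {
  validObject(design)
  withr::with_seed(design@seed, .simulate(design))
}

#' @rdname simulateCohort
#' @export
simulateNullCohort <- function(design) {
  validObject(design)
  nullSpec <- design@idpSpec
  nullSpec$effect <- 0
  nullDesign <- design
  nullDesign@idpSpec <- nullSpec
  nullDesign@demoEffect <- 0
  nullDesign@demoAssoc <- 0
  simulateCohort(nullDesign)
}

.simulate <- function(design) {
  nM <- design@nMiddle
  nO <- design@nOlder
  n <- nM + nO
  stratum <- rep(c("middle", "older"), c(nM, nO))
  age <- c(
    sample(seq(design@ageMiddle[1], design@ageMiddle[2]), nM, replace = TRUE),
    sample(seq(design@ageOlder[1], design@ageOlder[2]), nO, replace = TRUE)
  )

  ## latent general-cognition factor
  gMean <- ifelse(stratum == "older", design@olderShift, 0) -
    design@gAgeSlope * (age - ifelse(stratum == "older",
                                     design@ageOlder[1], design@ageMiddle[1]))
  g <- stats::rnorm(n, gMean, 1)
  gHigh <- logical(n)
  for (s in c("middle", "older")) {
    i <- stratum == s
    gHigh[i] <- g[i] > stats::median(g[i])
  }

  ## battery scores in native direction
  bt <- batteryTests(design@battery)
  scores <- matrix(NA_real_, n, 9L, dimnames = list(NULL, bt$name))
  for (j in seq_len(9L)) {
    oriented <- design@loadings[j] * g +
      stats::rnorm(n, 0, design@testNoiseSd[j])
    scores[, j] <- if (bt$direction[j] == "lower_better") -oriented else oriented
  }

  ## confounds
  sex <- sample(c("male", "female"), n, replace = TRUE)
  height <- stats::rnorm(n, 169, 9) + ifelse(sex == "male", 6, -6)
  headMotion <- stats::rlnorm(n, log(0.1), 0.4)
  tablePos <- stats::rnorm(n, 0, 5)
  t1Scale <- pmax(stats::rnorm(n, 1.1, 0.12), 0.7)
  confRaw <- cbind(
    age = age, age_sq = age^2, height = height,
    head_motion = headMotion, table_position = tablePos
  )
  confStd <- sweep(sweep(confRaw, 2, .confCenters, "-"), 2, .confScales, "/")

  ## IDP blocks
  spec <- design@idpSpec
  assaySpec <- spec[spec$family != "demographic", , drop = FALSE]
  vars <- .idpNames(assaySpec)
  nVar <- length(vars)
  idps <- matrix(NA_real_, nVar, n, dimnames = list(vars, NULL))
  fam <- character(nVar)
  ce <- design@confoundEffects
  k <- 0L
  for (i in seq_len(nrow(assaySpec))) {
    for (v in seq_len(assaySpec$n[i])) {
      k <- k + 1L
      beta <- if (is.null(ce)) rep(0, 5) else if (is.matrix(ce)) ce[k, ] else ce
      val <- assaySpec$effect[i] * assaySpec$noiseSd[i] * gHigh +
        drop(confStd %*% beta) +
        stats::rnorm(n, 0, assaySpec$noiseSd[i])
      idps[k, ] <- val
      fam[k] <- assaySpec$family[i]
    }
  }
  volumetric <- startsWith(vars, "t1_vol_")
  ## volumetric IDPs are emitted in native space; multiplying by the T1
  ## scaling factor recovers the head-size-normalized value
  idps[volumetric, ] <- sweep(idps[volumetric, , drop = FALSE], 2, t1Scale, "/")

  ## demographics
  demo <- list()
  for (i in seq_len(nrow(.demoContinuous))) {
    d <- .demoContinuous[i, ]
    e <- .effectFor(design@demoEffect, d$name)
    val <- stats::rnorm(n, d$mean, d$sd) + e * d$sd * gHigh
    if (d$nonneg) val <- pmax(val, 0)
    demo[[d$name]] <- val
  }
  for (nm in names(.demoNominal)) {
    p <- .demoNominal[[nm]]
    a <- .effectFor(design@demoAssoc, nm)
    lv <- names(p)
    sc <- seq(-1, 1, length.out = length(lv))
    w <- outer(g * a, sc) + rep(log(p), each = n)
    w <- exp(w - apply(w, 1, max))
    w <- w / rowSums(w)
    u <- stats::runif(n)
    pick <- max.col(u < t(apply(w, 1, cumsum)), ties.method = "first")
    demo[[nm]] <- factor(lv[pick], levels = lv)
  }
  extraSpec <- spec[spec$family == "demographic", , drop = FALSE]
  if (nrow(extraSpec) > 0) {
    en <- .idpNames(extraSpec)
    k <- 0L
    for (i in seq_len(nrow(extraSpec))) {
      for (v in seq_len(extraSpec$n[i])) {
        k <- k + 1L
        demo[[en[k]]] <- extraSpec$effect[i] * extraSpec$noiseSd[i] * gHigh +
          stats::rnorm(n, 0, extraSpec$noiseSd[i])
      }
    }
  }

  cd <- S4Vectors::DataFrame(
    stratum = stratum, age = age, sex = sex,
    scores,
    age_sq = age^2, height = height, head_motion = headMotion,
    table_position = tablePos, t1_scale_factor = t1Scale,
    demo,
    latent_g = g, latent_g_high = gHigh,
    row.names = sprintf("S%06d", seq_len(n)),
    check.names = FALSE
  )
  subjectCohort(
    idps = idps,
    family = fam, volumetric = volumetric,
    colData = cd, ageCutoff = design@ageCutoff,
    metadata = list(design = design, seed = design@seed)
  )
}

#' Assemble a SubjectCohort
#'
#' Low-level constructor wrapping [SummarizedExperiment::SummarizedExperiment]:
#' `idps` (variables x subjects) becomes the `"idps"` assay with per-variable
#' `family` and `volumetric` flags in `rowData`; all subject-level columns
#' (stratum, age, sex, cognitive scores, confounds, demographics) go in
#' `colData`.
#'
#' @param idps numeric matrix, variables x subjects (may have 0 rows).
#' @param family per-variable family label; one of `r paste(idpFamilies(), collapse = ", ")`.
#' @param volumetric logical per variable; volumetric IDPs are the ones
#'   rescaled by [normalizeHeadSize()].
#' @param colData a [S4Vectors::DataFrame] with at least `stratum` and `age`;
#'   row names are the subject identifiers.
#' @param ageCutoff stratum boundary in years.
#' @param metadata extra metadata list.
#' @return a [SubjectCohort-class].
#' @export
subjectCohort <- function(idps, family = character(0),
                          volumetric = logical(length(family)),
                          colData, ageCutoff = 65, metadata = list()) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(idps = idps),
    rowData = S4Vectors::DataFrame(
      family = family, volumetric = volumetric, row.names = rownames(idps)
    ),
    colData = colData,
    metadata = c(list(ageCutoff = ageCutoff), metadata)
  )
  new("SubjectCohort", se)
}

#' @rdname SubjectCohort-class
#' @aliases idpMatrix
#' @export
setMethod("idpMatrix", "SubjectCohort", function(x) {
  SummarizedExperiment::assay(x, "idps")
})

#' @rdname SubjectCohort-class
#' @aliases cognitiveScores
#' @param battery a [TestBattery-class].
#' @param ... passed to methods.
#' @export
setMethod("cognitiveScores", "SubjectCohort", function(x, battery = testBattery()) {
  nm <- batteryTests(battery)$name
  cd <- SummarizedExperiment::colData(x)
  missing <- setdiff(nm, names(cd))
  if (length(missing) > 0) {
    cogageError("schema", paste("missing cognitive test column(s):",
                                paste(missing, collapse = ", ")))
  }
  m <- as.matrix(as.data.frame(cd[, nm, drop = FALSE]))
  rownames(m) <- rownames(cd)
  m
})

#' @rdname SubjectCohort-class
#' @aliases demographics
#' @export
setMethod("demographics", "SubjectCohort", function(x) {
  cd <- SummarizedExperiment::colData(x)
  bt <- batteryTests(testBattery())$name
  reserved <- c(
    "stratum", "age", "sex", bt, confoundNames(), "t1_scale_factor"
  )
  keep <- setdiff(names(cd), c(reserved, grep("^latent_", names(cd), value = TRUE)))
  cd[, keep, drop = FALSE]
})

setMethod("show", "SubjectCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("SubjectCohort:", ncol(object), "subjects,", nrow(object), "IDPs\n")
  cat("  strata  :", sum(cd$stratum == "middle"), "middle /",
      sum(cd$stratum == "older"), "older (cut-off",
      S4Vectors::metadata(object)$ageCutoff %||% 65, "y)\n")
  if (nrow(object) > 0) {
    fam <- table(SummarizedExperiment::rowData(object)$family)
    cat("  families:", paste(names(fam), fam, sep = "=", collapse = ", "), "\n")
  }
})
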
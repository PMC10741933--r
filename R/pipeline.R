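#' Run the full analysis pipeline
#'
#' Orchestrates the whole analysis on one cohort: classify the older
#' stratum into successful / non-successful cognitive aging, head-size
#' normalize and residualize the IDPs against the confound design (fitted
#' on the older stratum, blind to the labels), compare every IDP and
#' demographic indicator between the two groups with per-family FDR
#' control, and re-test the significant variables against the middle-aged
#' stratum. Middle-aged IDPs are adjusted with the coefficients estimated
#' on the older fit.
#'
#' When `outDir` is given, the run artifacts are written there (the
#' directory is created if needed): `classification.csv`,
#' `stage_counts.txt`, `residual_coefficients.csv`, `comparison.csv`,
#' `followup.csv`, `run.log` and `provenance.txt`. Identical cohort /
#' design and seed produce byte-identical files.
#'
#' @param cohort a [SubjectCohort-class]; alternatively supply `design`
#'   (simulated on the fly) or `input` (a phenotype CSV/TSV path).
#' @param design a [syntheticDesign()] specification.
#' @param input path to a phenotype table for [readPhenotypeTable()].
#' @param battery a [TestBattery-class].
#' @param thresholds cascade thresholds, see [scaThresholds()].
#' @param qThreshold per-family FDR level; default 0.01.
#' @param followupAlpha uncorrected level of the follow-up similarity
#'   check; default 0.05.
#' @param routingAlpha normality-rule level; default 0.05.
#' @param outDir optional output directory for run artifacts.
#' @param seed overrides the design seed when simulating.
#' @return invisibly, a list with `cohort`, `classification`,
#'   `confoundFit`, `comparison`, `followup`, and `files` (paths written).
#' @examples
#' res <- runPipeline(design = syntheticDesign(nMiddle = 200, nOlder = 200, seed = 3))
#' stageCounts(res$classification)
#' @export
runPipeline <- function(cohort = NULL, design = NULL, input = NULL,
                        battery = testBattery(),
                        thresholds = scaThresholds(), qThreshold = 0.01,
                        followupAlpha = 0.05, routingAlpha = 0.05,
                        outDir = NULL, seed = NULL) {
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))

  if (is.null(cohort)) {
    if (!is.null(design)) {
      if (!is.null(seed)) design@seed <- as.integer(seed)
      cohort <- simulateCohort(design)
      say("simulate: %d subjects, seed %d", ncol(cohort), design@seed)
    } else if (!is.null(input)) {
      cohort <- readPhenotypeTable(input, battery)
      say("read: %s (%d subjects, %d IDPs)", input, ncol(cohort), nrow(cohort))
    } else {
      cogageError("config", "one of cohort, design or input is required")
    }
  }

  ## stage 1: classification
  cls <- classifyCohort(cohort, battery, thresholds)
  sc <- stageCounts(cls)
  say("classify: %d older -> %d generic-stage -> %d SCA (%d dropped)",
      sc["nOlderInput"], sc["nAfterGeneric"], sc["nFinalSca"], cls@nDropped)

  ## stage 2: head-size normalization + deconfounding (older stratum)
  cohort <- normalizeCohortHeadSize(cohort)
  olderIds <- rownames(subjectResults(cls))
  olderCohort <- cohort[, olderIds]
  confDesign <- buildConfoundDesign(olderCohort)
  fit <- residualizeIdps(idpMatrix(olderCohort), confDesign, transposed = TRUE)
  say("deconfound: %d IDPs residualized on %d design columns",
      ncol(residualMatrix(fit)), ncol(confDesign$matrix))

  ## stage 3: SCA vs nonSCA comparison
  labels <- factor(scaLabels(cls), levels = c("SCA", "nonSCA"))
  rd <- SummarizedExperiment::rowData(cohort)
  demoOlder <- demographics(olderCohort)
  specs <- rbind(
    data.frame(name = rownames(cohort),
               family = as.character(rd$family), scale = "continuous",
               stringsAsFactors = FALSE),
    data.frame(name = names(demoOlder), family = "demographic",
               scale = vapply(as.list(demoOlder), function(v) {
                 if (is.numeric(v)) "continuous" else "nominal"
               }, character(1)),
               stringsAsFactors = FALSE)
  )
  data1 <- c(
    as.list(as.data.frame(residualMatrix(fit))),
    as.list(as.data.frame(demoOlder))
  )
  comparison <- compareGroups(data1, labels, specs, qThreshold = qThreshold,
                              routingAlpha = routingAlpha)
  say("compare: %d variables tested, %d significant at q <= %g",
      nrow(comparison), sum(comparison$significant, na.rm = TRUE), qThreshold)

  ## stage 4: follow-up against the middle-aged stratum
  scaIds <- olderIds[labels == "SCA"]
  midIds <- colnames(cohort)[cohort$stratum == "middle"]
  midRes <- applyResidualization(fit, cohort[, midIds])
  followData <- c(
    as.list(as.data.frame(rbind(
      residualMatrix(fit)[scaIds, , drop = FALSE], midRes
    ))),
    as.list(as.data.frame(rbind(
      demographics(cohort[, scaIds]), demographics(cohort[, midIds])
    )))
  )
  followLabels <- factor(rep(c("SCA", "middle"), c(length(scaIds), length(midIds))),
                         levels = c("SCA", "middle"))
  followup <- followupMiddle(comparison, followData, followLabels,
                             alpha = followupAlpha, routingAlpha = routingAlpha)
  say("followup: %d significant variables re-tested, %d similar to middle-aged",
      nrow(followup), sum(followup$similarToMiddle))

  files <- character(0)
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) {
      dir.create(outDir, recursive = TRUE)
    }
    files <- .writeRunArtifacts(outDir, cls, fit, comparison, followup,
                                cohort, qThreshold, followupAlpha, log)
  }
  invisible(list(
    cohort = cohort, classification = cls, confoundFit = fit,
    comparison = comparison, followup = followup, files = files, log = log
  ))
}

.writeRunArtifacts <- function(outDir, cls, fit, comparison, followup,
                               cohort, qThreshold, followupAlpha, log) {
  p <- function(f) file.path(outDir, f)
  subj <- as.data.frame(subjectResults(cls))
  utils::write.csv(cbind(subject_id = rownames(subj), subj),
                   p("classification.csv"), row.names = FALSE)
  sc <- stageCounts(cls)
  writeLines(paste0(names(sc), ": ", sc), p("stage_counts.txt"))
  co <- as.data.frame(confoundCoefficients(fit))
  utils::write.csv(cbind(term = rownames(co), co),
                   p("residual_coefficients.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(comparison), p("comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(followup), p("followup.csv"),
                   row.names = FALSE)
  writeLines(log, p("run.log"))
  meta <- S4Vectors::metadata(cohort)
  thr <- cls@thresholds
  writeLines(c(
    paste("package_version:", as.character(utils::packageVersion("cogage"))),
    paste("seed:", meta$seed %||% NA),
    paste("age_cutoff:", meta$ageCutoff %||% 65),
    paste("n_subjects:", ncol(cohort)),
    paste("n_idps:", nrow(cohort)),
    paste("threshold_generic_self:", thr$genericSelf),
    paste("threshold_generic_mid:", thr$genericMid),
    paste("threshold_specific_self:", thr$specificSelf),
    paste("threshold_specific_mid:", thr$specificMid),
    paste("fdr_q:", qThreshold),
    paste("followup_alpha:", followupAlpha)
  ), p("provenance.txt"))
  vapply(c("classification.csv", "stage_counts.txt",
           "residual_coefficients.csv", "comparison.csv", "followup.csv",
           "run.log", "provenance.txt"), p, character(1))
}
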
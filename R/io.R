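#' Write a cohort to a CSV fixture
#'
#' One header row and one row per subject. The nine cognitive test columns
#' are written under their biobank-style numeric field-ID aliases (e.g.
#' `20016` for fluid intelligence); subject metadata, confounds,
#' demographics and IDP columns keep their names. A provenance sidecar
#' (`<path>.provenance`) in DCF key-value format records the generating
#' seed and cohort dimensions. The file round-trips losslessly through
#' [readPhenotypeTable()].
#'
#' @param cohort a [SubjectCohort-class].
#' @param path destination CSV path.
#' @param battery the [TestBattery-class] providing field-ID aliases.
#' @param sidecar write the provenance sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
writeCohortCsv <- function(cohort, path, battery = testBattery(),
                           sidecar = TRUE) {
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  bt <- batteryTests(battery)
  present <- intersect(bt$name, names(cd))
  names(cd)[match(present, names(cd))] <-
    bt$fieldId[match(present, bt$name)]
  idps <- SummarizedExperiment::assay(cohort, "idps")
  df <- cbind(
    data.frame(subject_id = colnames(cohort) %||% character(0),
               stringsAsFactors = FALSE),
    cd,
    if (nrow(idps) > 0) as.data.frame(t(idps)) else NULL
  )
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    cogageError("io", paste("cannot write fixture:", conditionMessage(ok)))
  }
  if (sidecar) {
    meta <- S4Vectors::metadata(cohort)
    writeLines(c(
      paste("seed:", meta$seed %||% NA),
      paste("ageCutoff:", meta$ageCutoff %||% 65),
      paste("nSubjects:", ncol(cohort)),
      paste("nIdps:", nrow(idps)),
      paste("generator:", class(meta$design %||% "external")[1])
    ), paste0(path, ".provenance"))
  }
  invisible(path)
}

.familyFromName <- function(nm) {
  ifelse(startsWith(nm, "t1_"), "T1",
    ifelse(startsWith(nm, "dmri_skel_"), "dMRI_skeleton",
      ifelse(startsWith(nm, "dmri_tract_"), "dMRI_tract",
        ifelse(startsWith(nm, "rsfmri_"), "rsfMRI", "demographic"))))
}

#' Read a per-subject phenotype table
#'
#' Reads a CSV/TSV phenotype file (delimiter sniffed from the header line)
#' into a [SubjectCohort-class]. Cognitive test columns are accepted under
#' either their test names or their numeric field-ID aliases; all missing
#' mapped columns are reported in a single schema error. IDP columns are
#' recognized by their family prefixes (`t1_`, `dmri_skel_`, `dmri_tract_`,
#' `rsfmri_`); remaining non-reserved columns become demographic
#' indicators (character columns as factors). The `stratum` column, when
#' absent, is derived from `age` and the cut-off.
#'
#' @param path CSV/TSV file with a header row.
#' @param battery a [TestBattery-class] for field-ID mapping.
#' @param ageCutoff stratum boundary in years.
#' @return a [SubjectCohort-class]; a header-only file yields an empty
#'   cohort without error.
#' @export
readPhenotypeTable <- function(path, battery = testBattery(), ageCutoff = 65) {
  if (!file.exists(path)) {
    cogageError("io", paste("no such file:", path))
  }
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE)

  bt <- batteryTests(battery)
  ## accept field-ID aliases for the nine tests
  idHit <- match(bt$fieldId, names(df))
  names(df)[idHit[!is.na(idHit)]] <- bt$name[!is.na(idHit)]
  needed <- c("age", bt$name)
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    cogageError("schema", paste("missing mapped column(s):",
                                paste(missing, collapse = ", ")))
  }

  numericCols <- intersect(
    c("age", bt$name, confoundNames(), "t1_scale_factor"), names(df)
  )
  for (cc in numericCols) {
    v <- df[[cc]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(parsed) & !is.na(v) & nzchar(trimws(v)))
      if (length(bad) > 0) {
        cogageError("parse", sprintf(
          "non-numeric value in column '%s' at row %d", cc, bad[1L]
        ))
      }
      df[[cc]] <- parsed
    }
  }

  n <- nrow(df)
  ids <- if ("subject_id" %in% names(df)) as.character(df$subject_id) else
    sprintf("S%06d", seq_len(n))
  stratum <- if ("stratum" %in% names(df)) df$stratum else
    ifelse(df$age >= ageCutoff, "older", "middle")

  reserved <- c("subject_id", "stratum", "age", "sex", bt$name,
                confoundNames(), "t1_scale_factor")
  candidates <- setdiff(names(df), reserved)
  idpCols <- candidates[.familyFromName(candidates) != "demographic"]

  idps <- t(as.matrix(df[, idpCols, drop = FALSE]))
  colnames(idps) <- ids
  cdCols <- setdiff(names(df), c("subject_id", "stratum", idpCols))
  cd <- df[, cdCols, drop = FALSE]
  for (cc in names(cd)) {
    if (is.character(cd[[cc]]) && !startsWith(cc, "latent_")) {
      cd[[cc]] <- if (cc == "sex") cd[[cc]] else factor(cd[[cc]])
    }
  }
  cd <- S4Vectors::DataFrame(stratum = stratum, cd, row.names = ids,
                             check.names = FALSE)
  subjectCohort(
    idps = idps,
    family = .familyFromName(idpCols),
    volumetric = startsWith(idpCols, "t1_vol_"),
    colData = cd, ageCutoff = ageCutoff
  )
}
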
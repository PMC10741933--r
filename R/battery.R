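#' Construct a cognitive test battery
#'
#' Returns the default nine-test battery used throughout the package, or a
#' battery with a modified orientation / specific-test subset. Raw scores
#' are stored in each test's native direction: counts of correct answers
#' improve upwards, while durations (reaction time, trail-making) and error
#' counts (pair-matching) improve downwards and are negated by
#' [orientScores()] before any thresholding.
#'
#' The four `specific` tests -- matrix pattern completion, tower
#' rearranging, fluid intelligence and numeric memory -- additionally gate
#' the second classifier stage.
#'
#' @param tests optional `data.frame` with columns `name`, `fieldId`,
#'   `domain`, `direction` overriding the default battery (nine rows).
#' @param specific character vector of four test names for the specific
#'   stage.
#'
#' @return a [TestBattery-class] object.
#' @examples
#' bat <- testBattery()
#' batteryTests(bat)
#' specificTests(bat)
#' @export
testBattery <- function(tests = NULL, specific = NULL) {
  if (is.null(tests)) {
    tests <- data.frame(
      name = c(
        "pair_matching", "numeric_memory", "fluid_intelligence",
        "paired_associate_learning", "matrix_pattern_completion",
        "reaction_time", "symbol_digit_substitution", "tower_rearranging",
        "trail_making"
      ),
      fieldId = c("399", "4282", "20016", "20197", "6373",
                  "20023", "23324", "21004", "6350"),
      domain = c(
        "visual declarative memory", "working memory",
        "verbal and numerical reasoning", "verbal declarative memory",
        "non-verbal reasoning", "processing speed", "processing speed",
        "executive function", "executive function"
      ),
      direction = c(
        "lower_better", "higher_better", "higher_better", "higher_better",
        "higher_better", "lower_better", "higher_better", "higher_better",
        "lower_better"
      ),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(specific)) {
    specific <- c(
      "matrix_pattern_completion", "tower_rearranging",
      "fluid_intelligence", "numeric_memory"
    )
  }
  new("TestBattery", tests = tests, specificTests = specific)
}

#' @rdname TestBattery-class
#' @aliases batteryTests
#' @param x a `TestBattery`.
#' @export
setMethod("batteryTests", "TestBattery", function(x) x@tests)

#' @rdname TestBattery-class
#' @aliases specificTests
#' @export
setMethod("specificTests", "TestBattery", function(x) x@specificTests)

setMethod("show", "TestBattery", function(object) {
  cat("TestBattery with", nrow(object@tests), "tests\n")
  lb <- object@tests$name[object@tests$direction == "lower_better"]
  cat("  lower-is-better:", paste(lb, collapse = ", "), "\n")
  cat("  specific stage :", paste(object@specificTests, collapse = ", "), "\n")
})
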
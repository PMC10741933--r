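## Structured conditions: every user-facing failure carries a stable
## machine-readable code in class `cogage_error_<code>` and field `code`.

cogageError <- function(code, message, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("cogage_error_", code), "cogage_error", "error", "condition"),
    list(message = message, call = call, code = code)
  ))
}

cogageWarning <- function(code, message) {
  warning(structure(
    class = c(paste0("cogage_warning_", code), "cogage_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1), code = code)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## All IDP / demographic variables are adjusted within one of these families.
idpFamilies <- function() {
  c("T1", "dMRI_skeleton", "dMRI_tract", "rsfMRI", "demographic")
}

confoundNames <- function() {
  c("age", "age_sq", "height", "head_motion", "table_position")
}
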
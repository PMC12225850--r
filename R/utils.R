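# Condition helpers: every user-facing error carries a class so callers
# (and the CLI) can distinguish validation, input, configuration, schema
# and derivation failures.

abort_ldl <- function(msg, class) {
  stop(structure(
    class = c(class, "ldlstrat_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_input      <- function(msg) abort_ldl(msg, "ldlstrat_input_error")
stop_validation <- function(msg) abort_ldl(msg, "ldlstrat_validation_error")
stop_config     <- function(msg) abort_ldl(msg, "ldlstrat_config_error")
stop_schema     <- function(msg) abort_ldl(msg, "ldlstrat_schema_error")
stop_derivation <- function(msg) abort_ldl(msg, "ldlstrat_derivation_error")
stop_range      <- function(msg) abort_ldl(msg, "ldlstrat_range_error")

#' Round a proportion to a printed percentage
#'
#' Converts a proportion to a percentage rounded half-away-from-zero to one
#' decimal, the convention used when reporting concordance and
#' reclassification rates in tables.
#'
#' @param p Numeric vector of proportions.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector of percentages.
#' @examples
#' pct(9500 / 11930)  # 79.6
#' @export
pct <- function(p, digits = 1) {
  s <- 10^digits
  sign(p) * floor(abs(p) * 100 * s + 0.5) / s
}

# require named numeric columns, finite, optionally non-negative
check_numeric_field <- function(df, field, non_negative = TRUE, allow_na = FALSE) {
  if (!field %in% names(df)) {
    stop_input(sprintf("required field '%s' is missing", field))
  }
  x <- df[[field]]
  if (!is.numeric(x)) {
    stop_validation(sprintf("field '%s' must be numeric", field))
  }
  bad <- if (allow_na) !is.na(x) & !is.finite(x) else !is.finite(x)
  if (any(bad)) {
    stop_validation(sprintf("field '%s' contains non-finite values", field))
  }
  if (non_negative && any(x < 0, na.rm = TRUE)) {
    stop_validation(sprintf("field '%s' contains negative concentrations", field))
  }
  invisible(x)
}
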
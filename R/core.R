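# Core lipid-panel data model: validation, derived quantities, eligibility
# filtering, and NCEP-ATP III guideline categorization.
#
# A cohort is a plain data.frame with one row per individual and columns
#   id     opaque identifier
#   tc     total cholesterol, mg/dL
#   hdl_c  HDL cholesterol, mg/dL
#   tg     triglycerides, mg/dL
#   ldl_d  directly measured LDL-C, mg/dL (optional; needed for derivation
#          and evaluation, absent for estimation-only inputs)
# All concentrations are mg/dL; mmol/L is not supported.

NCEP_BREAKS <- c(70, 100, 130, 160, 190)
NCEP_LABELS <- c("<70", "70-99", "100-129", "130-159", "160-189", ">=190")

#' Validate a lipid cohort data frame
#'
#' Checks that the required columns (`id`, `tc`, `hdl_c`, `tg`) are present,
#' numeric, finite and non-negative; `ldl_d` is validated when present or
#' when `require_ldl_d = TRUE`.
#'
#' @param cohort A data.frame of lipid panels.
#' @param require_ldl_d Require the directly measured LDL-C column.
#' @return The cohort, invisibly, after validation.
#' @export
validate_cohort <- function(cohort, require_ldl_d = FALSE) {
  if (!is.data.frame(cohort)) stop_input("cohort must be a data.frame")
  if (!"id" %in% names(cohort)) stop_input("required field 'id' is missing")
  for (f in c("tc", "hdl_c", "tg")) check_numeric_field(cohort, f)
  if (require_ldl_d || "ldl_d" %in% names(cohort)) {
    check_numeric_field(cohort, "ldl_d")
  }
  if (anyDuplicated(cohort$id)) stop_input("cohort 'id' values must be unique")
  invisible(cohort)
}

#' Derive non-HDL-C, VLDL-C and the TG/VLDL-C ratio
#'
#' Adds the derived columns `non_hdl = tc - hdl_c`, and — when directly
#' measured LDL-C is available — `vldl_c = non_hdl - ldl_d` and
#' `tg_vldl_ratio = tg / vldl_c`. The ratio is undefined (set to `NA`) for
#' individuals with `vldl_c <= 0`; their count is reported via the
#' `n_undefined_ratio` attribute.
#'
#' @param cohort A lipid cohort data.frame (see [validate_cohort()]).
#' @return The cohort with derived columns appended.
#' @examples
#' derive_panel(data.frame(id = 1, tc = 200, hdl_c = 50, tg = 100, ldl_d = 120))
#' @export
derive_panel <- function(cohort) {
  validate_cohort(cohort)
  cohort$non_hdl <- cohort$tc - cohort$hdl_c
  if ("ldl_d" %in% names(cohort)) {
    cohort$vldl_c <- cohort$non_hdl - cohort$ldl_d
    ratio <- ifelse(cohort$vldl_c > 0, cohort$tg / cohort$vldl_c, NA_real_)
    cohort$tg_vldl_ratio <- ratio
    attr(cohort, "n_undefined_ratio") <- sum(cohort$vldl_c <= 0)
  }
  cohort
}

#' Filter a cohort to the estimation-eligible triglyceride range
#'
#' Drops individuals with `tg >= tg_max` (the Friedewald validity bound,
#' default 400 mg/dL) and individuals with missing required fields, and
#' reports exclusion counts by reason.
#'
#' @param cohort A lipid cohort data.frame.
#' @param tg_max Exclusive upper bound on triglycerides, mg/dL.
#' @return A list with `cohort` (the kept rows) and `report`, a data.frame
#'   of exclusion reasons and counts.
#' @export
filter_eligible <- function(cohort, tg_max = 400) {
  if (!is.data.frame(cohort)) stop_input("cohort must be a data.frame")
  if (nrow(cohort) == 0) {
    return(list(
      cohort = cohort,
      report = data.frame(reason = c("missing_field", "tg_at_or_above_max"),
                          n = c(0L, 0L))
    ))
  }
  complete <- rep(TRUE, nrow(cohort))
  for (f in c("tc", "hdl_c", "tg")) {
    if (!f %in% names(cohort)) stop_input(sprintf("required field '%s' is missing", f))
    complete <- complete & !is.na(cohort[[f]])
  }
  in_range <- complete & cohort$tg < tg_max
  kept <- cohort[in_range, , drop = FALSE]
  validate_cohort(kept)
  list(
    cohort = kept,
    report = data.frame(
      reason = c("missing_field", "tg_at_or_above_max"),
      n = c(sum(!complete), sum(complete & !(cohort$tg < tg_max)))
    )
  )
}

#' NCEP-ATP III guideline category of an LDL-C value
#'
#' Classifies LDL-C (measured or estimated, mg/dL) into the six guideline
#' treatment bands `<70`, `70-99`, `100-129`, `130-159`, `160-189`,
#' `>=190`. Intervals are half-open `[lo, hi)` on unrounded values;
#' negative estimates fall in `<70`.
#'
#' @param ldl Numeric vector of LDL-C values, mg/dL. May be negative
#'   (estimators can undershoot) but must be finite.
#' @return An ordered factor with the six category labels.
#' @seealso [ncep_index()] for the 0-based ordinal.
#' @examples
#' ncep_category(c(69.99, 70, 190, -12))
#' @export
ncep_category <- function(ldl) {
  idx <- ncep_index(ldl)
  factor(NCEP_LABELS[idx + 1L], levels = NCEP_LABELS, ordered = TRUE)
}

#' Ordinal NCEP-ATP III category index
#'
#' @param ldl Numeric vector of LDL-C values, mg/dL.
#' @return Integer vector in 0..5 (0 = `<70`, 5 = `>=190`).
#' @export
ncep_index <- function(ldl) {
  if (!is.numeric(ldl)) stop_validation("ldl must be numeric")
  if (any(!is.finite(ldl))) stop_validation("ldl contains non-finite values")
  findInterval(ldl, NCEP_BREAKS)
}

#' Category labels of the NCEP-ATP III guideline bands
#' @return Character vector of the six labels, lowest first.
#' @export
ncep_labels <- function() NCEP_LABELS

#' Read / write a cohort CSV
#'
#' The cohort dialect is a UTF-8, decimal-point CSV with header
#' `id,tc,hdl_c,tg[,ldl_d]`; [write_cohort()] can append the derived
#' columns `non_hdl,vldl_c,tg_vldl_ratio`.
#'
#' @param path File path.
#' @return For `read_cohort`, a validated cohort data.frame.
#' @export
read_cohort <- function(path) {
  cohort <- read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(cohort)
  cohort
}

#' @rdname read_cohort
#' @param cohort A lipid cohort data.frame.
#' @param derived Also write the derived columns (computing them if needed).
#' @export
write_cohort <- function(cohort, path, derived = FALSE) {
  validate_cohort(cohort)
  cols <- intersect(c("id", "tc", "hdl_c", "tg", "ldl_d"), names(cohort))
  if (derived) {
    cohort <- derive_panel(cohort)
    cols <- c(cols, intersect(c("non_hdl", "vldl_c", "tg_vldl_ratio"), names(cohort)))
  }
  write.csv(cohort[, cols, drop = FALSE], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
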
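# LDL-C estimation equations.
#
# Both estimators share the form  estimate = non-HDL-C - TG / AF :
# Friedewald fixes AF at 5, the stratified (Martin-Hopkins-style) estimator
# looks AF up in a ratio table by TG and non-HDL-C. Negative estimates are
# flagged, never clipped.

#' Friedewald LDL-C estimate
#'
#' `estimate = tc - hdl_c - tg / 5` (all mg/dL). Identical, on every input,
#' to the stratified estimator with a constant AF of 5.
#'
#' @param cohort A lipid cohort data.frame.
#' @param warn_tg Warn when any `tg >= 400` mg/dL (outside the formula's
#'   advised validity range).
#' @return A data.frame of estimate records: `id`, `method`
#'   (`"LDL-C_F"`), `estimate` (mg/dL), `negative` flag.
#' @examples
#' estimate_friedewald(data.frame(id = 1, tc = 200, hdl_c = 50, tg = 100))
#' @export
estimate_friedewald <- function(cohort, warn_tg = TRUE) {
  validate_cohort(cohort)
  if (warn_tg && any(cohort$tg >= 400)) {
    warning("some tg >= 400 mg/dL: Friedewald estimates are unreliable there",
            call. = FALSE)
  }
  est <- cohort$tc - cohort$hdl_c - cohort$tg / 5
  data.frame(id = cohort$id, method = "LDL-C_F",
             estimate = est, negative = est < 0)
}

#' Stratified (Martin-Hopkins-style) LDL-C estimate
#'
#' `estimate = non_hdl - tg / af`, with the adjustable factor `af` looked
#' up in `table` by the individual's TG (and non-HDL-C, for combined
#' schemes) stratum.
#'
#' @param cohort A lipid cohort data.frame.
#' @param table A `ratio_table`.
#' @param label Method label for the records; defaults to
#'   [method_label()] of the table.
#' @return A data.frame of estimate records (as [estimate_friedewald()]).
#' @export
estimate_martin_hopkins <- function(cohort, table, label = NULL) {
  validate_cohort(cohort)
  stopifnot(inherits(table, "ratio_table"))
  non_hdl <- cohort$tc - cohort$hdl_c
  af <- lookup_af(table, cohort$tg, non_hdl)
  est <- non_hdl - cohort$tg / af
  data.frame(id = cohort$id,
             method = if (is.null(label)) method_label(table) else label,
             estimate = est, negative = est < 0)
}
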
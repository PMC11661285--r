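# Brain-BMI gap: raw gap, regression-to-the-mean bias correction fitted on a
# reference cohort and transferred frozen to all others, group summaries.

#' Raw gap between predicted and measured phenotype
#'
#' @param predicted,measured paired finite numeric vectors.
#' @return `predicted - measured`, elementwise.
#' @export
compute_gap <- function(predicted, measured) {
  if (length(predicted) != length(measured)) stop("length mismatch")
  predicted - measured
}

#' Fit the linear bias correction of the raw gap on measured BMI
#'
#' Brain-based BMI predictions over-estimate at the low end and
#' under-estimate at the high end of the BMI range; the raw gap is therefore
#' regressed on measured BMI (ordinary least squares) in a reference cohort,
#' and that fit is subtracted everywhere.  By OLS orthogonality the corrected
#' gap in the fitting cohort has mean zero and zero correlation with
#' measured BMI.
#'
#' @param gap_raw raw gaps in the reference cohort.
#' @param measured measured BMI in the reference cohort.
#' @param cohort_id label of the fitting cohort (bookkeeping).
#' @return Object of class `gap_correction` with intercept `a`, slope `b`,
#'   `cohort_id` and `n`.
#' @export
fit_gap_correction <- function(gap_raw, measured, cohort_id = "reference") {
  if (length(gap_raw) < 3) stop("need at least 3 subjects")
  if (stats::var(measured) == 0) stop("zero BMI variance")
  fit <- stats::lm.fit(cbind(1, measured), gap_raw)
  structure(list(a = unname(fit$coefficients[1]), b = unname(fit$coefficients[2]),
                 cohort_id = cohort_id, n = length(gap_raw)),
            class = "gap_correction")
}

#' Apply a frozen gap correction
#'
#' The coefficients are never refitted on the target cohort, so genuine
#' group-level deviations survive the correction.
#'
#' @param correction a [fit_gap_correction()] result.
#' @param gap_raw,measured target-cohort raw gaps and measured BMI.
#' @return Corrected gaps `gap_raw - (a + b * measured)`.
#' @export
apply_gap_correction <- function(correction, gap_raw, measured) {
  stopifnot(inherits(correction, "gap_correction"))
  gap_raw - (correction$a + correction$b * measured)
}

#' Assemble a per-subject gap table
#'
#' @param id,group subject identifiers and group labels.
#' @param measured,predicted measured and brain-predicted BMI.
#' @param correction a fitted `gap_correction`.
#' @return data.frame with `gap_raw` and `gap_corrected` columns.
#' @export
gap_table <- function(id, group, measured, predicted, correction) {
  raw <- compute_gap(predicted, measured)
  data.frame(id = id, group = group, bmi_measured = measured,
             bmi_predicted = predicted, gap_raw = raw,
             gap_corrected = apply_gap_correction(correction, raw, measured),
             stringsAsFactors = FALSE)
}

#' Per-group gap summary (mean, SD, n; raw and corrected)
#'
#' @param gt a [gap_table()].
#' @return data.frame with one row per non-empty group.
#' @export
summarize_gap_by_group <- function(gt) {
  stop_if_not_cols(gt, c("group", "gap_raw", "gap_corrected"), "gap table")
  groups <- unique(gt$group)
  empty <- vapply(groups, function(g) sum(gt$group == g) == 0, logical(1))
  if (any(empty)) warning("empty group(s) omitted")
  do.call(rbind, lapply(groups[!empty], function(g) {
    sub <- gt[gt$group == g, ]
    data.frame(group = g, n = nrow(sub),
               mean_raw = mean(sub$gap_raw),
               sd_raw = if (nrow(sub) > 1) stats::sd(sub$gap_raw) else NA_real_,
               mean_corrected = mean(sub$gap_corrected),
               sd_corrected = if (nrow(sub) > 1) stats::sd(sub$gap_corrected) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}
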
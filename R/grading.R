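# Evaluator-based severity: Nurnberger-Muller grades (0-3) from multiple
# blinded evaluators, the 0-15 Cellulite Severity Scale with its
# Mild/Moderate/Severe classes, and percent-of-baseline normalization.

#' Aggregate evaluator grades
#'
#' Averages the 0-3 cellulite grades given by multiple blinded evaluators for
#' each (participant, thigh, week) cell, reporting the mean and the standard
#' error of the mean over evaluators (0 when a cell has a single evaluator).
#' Cells with no grades are simply absent from the output, never imputed.
#'
#' @param records data.frame with columns `participant`, `thigh`, `week`,
#'   `evaluator`, `grade` (integers 0-3); one row per evaluator per cell.
#' @return data.frame with columns `participant`, `thigh`, `week`,
#'   `n_evaluators`, `mean_grade`, `sem`.
#' @export
aggregate_grades <- function(records) {
  need <- c("participant", "thigh", "week", "evaluator", "grade")
  if (!all(need %in% names(records)))
    cm_stop(paste("`records` must have columns:",
                  paste(need, collapse = ", ")), "cm_invalid_input")
  if (any(!records$grade %in% 0:3))
    cm_stop("grades must be integers in 0..3.", "cm_invalid_input")
  key <- records[c("participant", "thigh", "week", "evaluator")]
  if (anyDuplicated(key))
    cm_stop("duplicate (participant, thigh, week, evaluator) records.",
            "cm_invalid_input")
  agg <- stats::aggregate(grade ~ participant + thigh + week, data = records,
                          FUN = function(g)
                            c(n = length(g), mean = mean(g),
                              sem = if (length(g) > 1)
                                stats::sd(g) / sqrt(length(g)) else 0))
  out <- data.frame(agg[c("participant", "thigh", "week")],
                    n_evaluators = as.integer(agg$grade[, "n"]),
                    mean_grade = agg$grade[, "mean"],
                    sem = agg$grade[, "sem"])
  out[order(out$participant, out$thigh, out$week), , drop = FALSE]
}

#' Classify a Cellulite Severity Scale value
#'
#' Maps a 0-15 CSS value to its severity class: Mild for values up to 5,
#' Moderate above 5 up to 10, Severe above 10. The printed class bands cover
#' 1-15; boundaries are closed upward so that non-integer cohort means (e.g.
#' 12.9) classify deterministically, and 0 is labelled Mild.
#'
#' @param css numeric vector of CSS values in `[0, 15]`.
#' @return ordered factor with levels Mild < Moderate < Severe.
#' @export
classify_css <- function(css) {
  if (any(!is.finite(css)) || any(css < 0) || any(css > 15))
    cm_stop("CSS values must lie in [0, 15].", "cm_invalid_input")
  cls <- ifelse(css <= 5, "Mild", ifelse(css <= 10, "Moderate", "Severe"))
  factor(cls, levels = c("Mild", "Moderate", "Severe"), ordered = TRUE)
}

#' Normalize longitudinal values to baseline
#'
#' Expresses each participant-thigh series as a percentage of its own
#' baseline (week 0) value, so the baseline maps to exactly 100 and all
#' statistical testing can be performed on within-participant relative
#' change. Series whose baseline is missing or non-positive cannot be
#' normalized; their records are dropped with a warning.
#'
#' @param data data.frame with columns `participant`, `thigh`, `week`,
#'   `value` (additional columns are preserved).
#' @param baseline_week the week defining 100%; default 0.
#' @return the input rows that could be normalized, with an added
#'   `pct_baseline` column.
#' @export
normalize_to_baseline <- function(data, baseline_week = 0) {
  need <- c("participant", "thigh", "week", "value")
  if (!all(need %in% names(data)))
    cm_stop(paste("`data` must have columns:", paste(need, collapse = ", ")),
            "cm_invalid_input")
  key <- interaction(data$participant, data$thigh, drop = TRUE)
  base <- data$value[data$week == baseline_week]
  base_key <- key[data$week == baseline_week]
  b <- base[match(key, base_key)]
  bad <- is.na(b) | b <= 0
  if (any(bad)) {
    dropped <- unique(key[bad])
    warning(sprintf(
      "dropping %d record(s) from %d series with missing or non-positive baseline: %s",
      sum(bad), length(dropped), paste(head(dropped, 5), collapse = ", ")))
  }
  out <- data[!bad, , drop = FALSE]
  out$pct_baseline <- 100 * out$value / b[!bad]
  out
}
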
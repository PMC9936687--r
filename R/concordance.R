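# Triage test performance: confusion counts, metric suite, binomial CIs.
#
# Convention (fixed): the dispatcher's urgent label is the "test positive",
# the reference-standard urgent label is the "condition positive".  So
#   TP = EMD urgent & EMS urgent     FP = EMD urgent & EMS non-urgent
#   FN = EMD non-urgent & EMS urgent TN = EMD non-urgent & EMS non-urgent.

#' Confusion counts for the urgency dichotomy
#'
#' @param tp,fp,tn,fn non-negative cell counts.
#' @return a `confusion_counts` object.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  cells <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop_input("confusion cells must be non-negative integers")
  cells <- as.list(stats::setNames(as.integer(cells), names(cells)))
  structure(cells, class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts: TP %d, FP %d, TN %d, FN %d (n = %d)>\n",
              x$tp, x$fp, x$tn, x$fn, confusion_total(x)))
  invisible(x)
}

#' @rdname confusion_counts
#' @param x a `confusion_counts` object.
#' @export
confusion_total <- function(x) x$tp + x$fp + x$tn + x$fn

#' Confusion cell of each record
#'
#' @param emd_label,ems_label character vectors of `"urgent"`/`"non_urgent"`.
#' @return character vector over `"TP"`, `"FP"`, `"TN"`, `"FN"`.
#' @export
confusion_cell <- function(emd_label, ems_label) {
  check_labels <- function(x, what) {
    if (!all(x %in% c("urgent", "non_urgent")))
      stop_input(what, " labels must be 'urgent' or 'non_urgent'")
  }
  check_labels(emd_label, "EMD"); check_labels(ems_label, "EMS")
  ifelse(emd_label == "urgent",
         ifelse(ems_label == "urgent", "TP", "FP"),
         ifelse(ems_label == "urgent", "FN", "TN"))
}

#' Build confusion counts from paired labels
#'
#' @inheritParams confusion_cell
#' @return a `confusion_counts` object; the four cells sum to the number of
#'   label pairs.
#' @export
build_confusion <- function(emd_label, ems_label) {
  if (length(emd_label) != length(ems_label))
    stop_input("label vectors must have equal length")
  cell <- confusion_cell(emd_label, ems_label)
  tab <- table(factor(cell, levels = c("TP", "FP", "TN", "FN")))
  confusion_counts(tp = tab[["TP"]], fp = tab[["FP"]],
                   tn = tab[["TN"]], fn = tab[["FN"]])
}

#' Wald confidence interval for a binomial proportion, in percent
#'
#' Normal-approximation interval `p +/- z * sqrt(p(1-p)/n)`, clamped to
#' `[0, 100]`. This is the interval that reproduces the published triage
#' confidence bounds; the Wilson score interval is available via
#' [wilson_ci()] for sparse cells.
#'
#' @param numerator,denominator counts with
#'   `0 <= numerator <= denominator`, `denominator > 0`.
#' @param z critical value (1.96 for a 95% interval).
#' @return numeric vector `c(low, high)` in percent; `c(NA, NA)` when the
#'   denominator is zero.
#' @export
wald_ci <- function(numerator, denominator, z = 1.96) {
  if (denominator == 0) return(c(low = NA_real_, high = NA_real_))
  if (numerator < 0 || numerator > denominator)
    stop_input("numerator must lie in [0, denominator]")
  p <- numerator / denominator
  half <- z * sqrt(p * (1 - p) / denominator)
  c(low = max(0, p - half), high = min(1, p + half)) * 100
}

#' Wilson score confidence interval, in percent
#'
#' @inheritParams wald_ci
#' @return numeric vector `c(low, high)` in percent.
#' @export
wilson_ci <- function(numerator, denominator, z = 1.96) {
  if (denominator == 0) return(c(low = NA_real_, high = NA_real_))
  if (numerator < 0 || numerator > denominator)
    stop_input("numerator must lie in [0, denominator]")
  p <- numerator / denominator
  n <- denominator
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(low = max(0, centre - half), high = min(1, centre + half)) * 100
}

metric_definitions <- function(c) {
  list(
    efficiency   = c(c$tp + c$tn, confusion_total(c)),
    sensitivity  = c(c$tp, c$tp + c$fn),
    specificity  = c(c$tn, c$tn + c$fp),
    ppv          = c(c$tp, c$tp + c$fp),
    npv          = c(c$tn, c$tn + c$fn),
    over_triage  = c(c$fp, c$tp + c$fp),
    under_triage = c(c$fn, c$tn + c$fn)
  )
}

#' Triage test-performance metrics with confidence intervals
#'
#' Computes, from a confusion matrix of the urgency dichotomy:
#' efficiency `(TP+TN)/n`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, positive and negative predictive values, over-triage
#' (`100 - PPV`: urgent dispatches not urgent on scene) and under-triage
#' (`100 - NPV`: non-urgent dispatches urgent on scene). All values are
#' percentages at full precision; rounding happens only in
#' [render_tables()]. A metric whose denominator is zero (e.g. sensitivity
#' in a category where no record was urgent on scene) is `NA`, rendered as
#' `"N.A."`.
#'
#' @param confusion a `confusion_counts` object with positive total.
#' @param ci_method `"wald"` (default; matches the published intervals) or
#'   `"wilson"`.
#' @param conf_level confidence level for the intervals.
#' @return data frame with one row per metric: `metric`, `numerator`,
#'   `denominator`, `point_percent`, `ci_low_percent`, `ci_high_percent`.
#' @export
compute_metrics <- function(confusion, ci_method = c("wald", "wilson"),
                            conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  if (confusion_total(confusion) == 0)
    stop_input("cannot compute metrics on an empty confusion matrix")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci_fun <- switch(ci_method, wald = wald_ci, wilson = wilson_ci)
  defs <- metric_definitions(confusion)
  rows <- lapply(names(defs), function(m) {
    num <- defs[[m]][1]; den <- defs[[m]][2]
    if (den == 0) {
      data.frame(metric = m, numerator = num, denominator = den,
                 point_percent = NA_real_, ci_low_percent = NA_real_,
                 ci_high_percent = NA_real_, stringsAsFactors = FALSE)
    } else {
      ci <- ci_fun(num, den, z)
      data.frame(metric = m, numerator = num, denominator = den,
                 point_percent = 100 * num / den,
                 ci_low_percent = ci[["low"]], ci_high_percent = ci[["high"]],
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Priority-by-urgency crosstabulation
#'
#' The 4x2 table of the dispatcher's raw A/B/C/D priority against the
#' reference-standard urgency label, as published alongside the dichotomised
#' metrics.
#'
#' @param emd_priority character vector of `"A"`-`"D"`.
#' @param ems_label character vector of `"urgent"`/`"non_urgent"`.
#' @return 4x2 integer matrix, rows `A`-`D`, columns `urgent`,
#'   `non_urgent`.
#' @export
build_crosstab <- function(emd_priority, ems_label) {
  bad <- !emd_priority %in% dispatch_priorities()
  if (any(bad)) stop_input("invalid dispatch priorities in crosstab input")
  tab <- table(factor(emd_priority, levels = dispatch_priorities()),
               factor(ems_label, levels = c("urgent", "non_urgent")))
  m <- matrix(as.integer(tab), nrow = 4,
              dimnames = list(emd_priority = dispatch_priorities(),
                              ems_label = c("urgent", "non_urgent")))
  m
}

#' Collapse a 4x2 priority crosstab to confusion counts
#'
#' Applies the A/B vs C/D dichotomy to the rows of [build_crosstab()]'s
#' output (or any matrix shaped like it).
#'
#' @param crosstab 4x2 matrix with rows `A`-`D` and columns `urgent`,
#'   `non_urgent`.
#' @return a `confusion_counts` object.
#' @export
crosstab_to_confusion <- function(crosstab) {
  stopifnot(all(dispatch_priorities() %in% rownames(crosstab)),
            all(c("urgent", "non_urgent") %in% colnames(crosstab)))
  ab <- crosstab[c("A", "B"), , drop = FALSE]
  cd <- crosstab[c("C", "D"), , drop = FALSE]
  confusion_counts(tp = sum(ab[, "urgent"]), fp = sum(ab[, "non_urgent"]),
                   tn = sum(cd[, "non_urgent"]), fn = sum(cd[, "urgent"]))
}
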
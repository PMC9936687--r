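# Per-dispatch-category summaries and across-category statistics:
# chi-square association, Kruskal-Wallis on the TP/FP/TN/FN consistency
# variable, and Dunn's Bonferroni-corrected pairwise post hoc test.

#' Default coding of the consistency variable
#'
#' The across-category tests treat each record's confusion cell as an
#' ordinal "consistency" score. The source analysis does not state its
#' coding; the default follows the conventional TP, FP, TN, FN listing
#' order and is an explicit parameter everywhere it is used.
#'
#' @return named numeric vector mapping `TP`, `FP`, `TN`, `FN` to scores.
#' @export
default_consistency_coding <- function() c(TP = 1, FP = 2, TN = 3, FN = 4)

check_classified <- function(classified) {
  if (!all(c("ems_label", "emd_priority") %in% names(classified)))
    stop_contract("records must be classified first (classify_ems_urgency())")
}

#' Summarise concordance by dispatch category
#'
#' Builds one summary row per dispatch category: record count, dispatcher-
#' side urgent/non-urgent counts, the four confusion cells, and the full
#' metric suite (percent, `NA` where a denominator vanishes, e.g. in
#' categories where only A/B or only C/D dispatch priorities occur).
#' Categories at or below `min_n` records are still summarised but flagged
#' ineligible for the across-category tests (strict inequality: a category
#' needs *more than* `min_n` dispatches).
#'
#' @param classified a classified `dispatch_register`
#'   (see [classify_ems_urgency()]).
#' @param min_n eligibility threshold for across-category tests; default 50.
#' @param ci_method passed to [compute_metrics()].
#' @return data frame, one row per category (largest first), with columns
#'   `category`, `n`, `eligible`, `emd_urgent_n`, `emd_non_urgent_n`, `tp`,
#'   `fp`, `tn`, `fn`, and one percent column per metric
#'   (`efficiency` ... `under_triage`) plus `<metric>_ci_low`/`_ci_high`.
#' @export
summarize_by_category <- function(classified, min_n = 50,
                                  ci_method = c("wald", "wilson")) {
  ci_method <- match.arg(ci_method)
  check_classified(classified)
  emd <- emd_labels(classified)
  cell <- confusion_cell(emd, classified$ems_label)
  key <- category_key(classified$category)
  # canonical display label: first-seen spelling of each key
  first <- !duplicated(key)
  display <- stats::setNames(normalize_category(classified$category)[first], key[first])

  rows <- lapply(split(seq_along(key), key), function(idx) {
    tab <- table(factor(cell[idx], levels = c("TP", "FP", "TN", "FN")))
    conf <- confusion_counts(tp = tab[["TP"]], fp = tab[["FP"]],
                             tn = tab[["TN"]], fn = tab[["FN"]])
    met <- compute_metrics(conf, ci_method = ci_method)
    pt <- stats::setNames(met$point_percent, met$metric)
    lo <- stats::setNames(met$ci_low_percent, paste0(met$metric, "_ci_low"))
    hi <- stats::setNames(met$ci_high_percent, paste0(met$metric, "_ci_high"))
    n <- length(idx)
    data.frame(category = display[[key[idx][1]]], n = n,
               eligible = n > min_n,
               emd_urgent_n = sum(emd[idx] == "urgent"),
               emd_non_urgent_n = sum(emd[idx] == "non_urgent"),
               tp = conf$tp, fp = conf$fp, tn = conf$tn, fn = conf$fn,
               t(pt), t(lo), t(hi),
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chi-square test of association on a count table
#'
#' Pearson chi-square without continuity correction, as applied to the
#' priority-by-urgency crosstabulation.
#'
#' @param table an r x c matrix of counts, r, c >= 2.
#' @return list (class `triage_test_result`) with `test_name`, `statistic`,
#'   `df`, `p_value`.
#' @export
chi_square_association <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2)
    stop_input("chi-square needs at least a 2x2 table")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop_input("chi-square table has an empty row or column margin")
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  test_result("chi_square", statistic = unname(ht$statistic),
              df = unname(ht$parameter), p_value = ht$p.value)
}

consistency_scores <- function(classified, coding) {
  if (anyDuplicated(coding) || !all(c("TP", "FP", "TN", "FN") %in% names(coding)))
    stop_input("coding must map TP, FP, TN, FN to distinct scores")
  cell <- confusion_cell(emd_labels(classified), classified$ems_label)
  unname(coding[cell])
}

eligible_subset <- function(classified, min_n) {
  key <- category_key(classified$category)
  n_by <- table(key)
  keep <- key %in% names(n_by)[n_by > min_n]
  list(idx = which(keep), key = key[keep])
}

#' Kruskal-Wallis test of consistency across dispatch categories
#'
#' Tests whether the distribution of the record-level consistency variable
#' (the TP/FP/TN/FN cell, scored via `coding`) differs across the dispatch
#' categories with more than `min_n` records. The H statistic is
#' tie-corrected; degrees of freedom are (number of eligible categories - 1).
#'
#' @inheritParams summarize_by_category
#' @param coding named scores for the four cells,
#'   see [default_consistency_coding()].
#' @return a `triage_test_result` with `statistic` (H), `df`, `p_value`, and
#'   `n_groups`.
#' @export
kruskal_wallis_consistency <- function(classified, min_n = 50,
                                       coding = default_consistency_coding()) {
  check_classified(classified)
  el <- eligible_subset(classified, min_n)
  k <- length(unique(el$key))
  if (k < 2)
    stop_input("need at least 2 categories above the size threshold (have ", k, ")")
  score <- consistency_scores(classified, coding)[el$idx]
  ht <- stats::kruskal.test(score, factor(el$key))
  res <- test_result("kruskal_wallis", statistic = unname(ht$statistic),
                     df = unname(ht$parameter), p_value = ht$p.value)
  res$n_groups <- k
  res
}

#' Dunn's pairwise post hoc comparisons with Bonferroni correction
#'
#' After a Kruskal-Wallis test, compares every unordered pair of eligible
#' dispatch categories with Dunn's rank-based z-test (tie-corrected, on the
#' mean ranks of the pooled ranking). p-values are two-sided and
#' Bonferroni-adjusted over all pairs.
#'
#' @inheritParams kruskal_wallis_consistency
#' @param alpha significance threshold applied to the adjusted p-values.
#' @return data frame with one row per pair: `category_1`, `category_2`,
#'   `z`, `p_value`, `adjusted_p`, `significant`.
#' @export
pairwise_posthoc <- function(classified, min_n = 50,
                             coding = default_consistency_coding(),
                             alpha = 0.05) {
  check_classified(classified)
  el <- eligible_subset(classified, min_n)
  groups <- factor(el$key)
  k <- nlevels(groups)
  if (k < 2)
    stop_input("need at least 2 categories above the size threshold (have ", k, ")")
  score <- consistency_scores(classified, coding)[el$idx]
  # first-seen display labels
  disp_all <- normalize_category(classified$category)[el$idx]
  display <- stats::setNames(disp_all[!duplicated(el$key)], el$key[!duplicated(el$key)])

  N <- length(score)
  r <- rank(score)
  mean_rank <- tapply(r, groups, mean)
  n_g <- tabulate(groups)
  ties <- table(score)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  base_var <- N * (N + 1) / 12 - tie_term

  pairs <- utils::combn(levels(groups), 2)
  z <- apply(pairs, 2, function(p) {
    i <- match(p[1], levels(groups)); j <- match(p[2], levels(groups))
    (mean_rank[[p[1]]] - mean_rank[[p[2]]]) /
      sqrt(base_var * (1 / n_g[i] + 1 / n_g[j]))
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  p_adj <- stats::p.adjust(p_raw, method = "bonferroni")
  out <- data.frame(category_1 = unname(display[pairs[1, ]]),
                    category_2 = unname(display[pairs[2, ]]),
                    z = z, p_value = p_raw, adjusted_p = p_adj,
                    significant = p_adj < alpha,
                    stringsAsFactors = FALSE)
  out[order(out$adjusted_p), , drop = FALSE]
}

test_result <- function(test_name, statistic, df = NA_real_, p_value,
                        adjusted_p = NULL) {
  structure(list(test_name = test_name, statistic = statistic, df = df,
                 p_value = p_value, adjusted_p = adjusted_p),
            class = "triage_test_result")
}

#' @export
print.triage_test_result <- function(x, ...) {
  cat(sprintf("<%s: statistic = %.4g, df = %s, p = %.3g>\n", x$test_name,
              x$statistic, ifelse(is.na(x$df), "-", format(x$df)), x$p_value))
  invisible(x)
}
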
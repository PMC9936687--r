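# End-to-end pipeline and report rendering: read/generate -> exclude ->
# classify -> confusion -> metrics -> category statistics, then tables in
# the published layouts (text, CSV, JSON).

#' Run the full concordance pipeline
#'
#' Executes every analysis stage on a register read from CSV or generated
#' synthetically, and collects the results into an `analysis_report`:
#' exclusion tally, overall metric suite with confidence intervals, the 4x2
#' priority-by-urgency crosstab with its chi-square test, per-category
#' summaries, the Kruskal-Wallis consistency test across eligible
#' categories, and Dunn's Bonferroni-corrected pairwise post hoc results.
#'
#' @param input path to a register CSV, a `dispatch_register`, or a
#'   `generator_config` (the register is then generated in-run).
#' @param min_category_n eligibility threshold for across-category tests
#'   (strict: a category needs more than this many records).
#' @param ci_method `"wald"` or `"wilson"`.
#' @param coding consistency-variable coding,
#'   see [default_consistency_coding()].
#' @param cd_ab_transport passed to [classify_ems_urgency()].
#' @param schema passed to [read_register()] when `input` is a path.
#' @return an `analysis_report` list with elements `overall`, `crosstab`,
#'   `confusion`, `categories`, `tests` (`chi_square`, `kruskal_wallis`,
#'   `pairwise`), `exclusions`, `rule_fired`, `classified`, and
#'   `provenance`.
#' @export
run_pipeline <- function(input, min_category_n = 50,
                         ci_method = c("wald", "wilson"),
                         coding = default_consistency_coding(),
                         cd_ab_transport = c("urgent", "non_urgent"),
                         schema = default_schema()) {
  ci_method <- match.arg(ci_method)
  cd_ab_transport <- match.arg(cd_ab_transport)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_input("[", name, "] ", conditionMessage(e))
    })
  }

  src <- list()
  if (inherits(input, "generator_config")) {
    register <- stage("generate", generate_register(input))
    src <- list(source = "synthetic", seed = input$seed,
                n_dispatches = input$n_dispatches)
  } else if (inherits(input, "dispatch_register")) {
    register <- input
    src <- list(source = "in-memory")
  } else if (is.character(input) && length(input) == 1) {
    register <- stage("read", read_register(input, schema = schema))
    src <- list(source = "file", path = input)
  } else {
    stop_input("input must be a file path, a dispatch_register, ",
               "or a generator_config")
  }

  split <- stage("exclude", apply_exclusions(register))
  if (nrow(split$included) == 0) stop_input("[exclude] no analysable dispatches")

  classified <- stage("classify",
                      classify_ems_urgency(split$included,
                                           cd_ab_transport = cd_ab_transport))
  emd <- emd_labels(classified)
  confusion <- stage("confusion", build_confusion(emd, classified$ems_label))
  overall <- stage("metrics", compute_metrics(confusion, ci_method = ci_method))
  crosstab <- stage("crosstab",
                    build_crosstab(classified$emd_priority, classified$ems_label))
  categories <- stage("categories",
                      summarize_by_category(classified, min_n = min_category_n,
                                            ci_method = ci_method))
  # priorities absent from the data contribute empty crosstab rows; the
  # association test runs on the populated ones
  chi_rows <- crosstab[rowSums(crosstab) > 0, , drop = FALSE]
  chi <- if (nrow(chi_rows) >= 2 && all(colSums(chi_rows) > 0))
    stage("chi_square", chi_square_association(chi_rows))
  else NULL
  n_eligible <- sum(categories$eligible)
  kw <- if (n_eligible >= 2)
    stage("kruskal_wallis",
          kruskal_wallis_consistency(classified, min_n = min_category_n,
                                     coding = coding))
  else NULL
  pw <- if (n_eligible >= 2)
    stage("pairwise", pairwise_posthoc(classified, min_n = min_category_n,
                                       coding = coding))
  else NULL

  structure(list(
    overall = overall,
    crosstab = crosstab,
    confusion = confusion,
    categories = categories,
    tests = list(chi_square = chi, kruskal_wallis = kw, pairwise = pw),
    exclusions = split$tally,
    rule_fired = table(classified$rule_fired),
    classified = classified,
    provenance = c(src, list(
      n_total = nrow(register), n_included = nrow(split$included),
      min_category_n = min_category_n, ci_method = ci_method,
      cd_ab_transport = cd_ab_transport, coding = coding,
      package_version = as.character(utils::packageVersion("emstriage"))))),
    class = "analysis_report")
}

fmt_pct <- function(x) ifelse(is.na(x), "N.A.",
                              sprintf("%d", as.integer(round_half_up(x))))
fmt_ci <- function(lo, hi) ifelse(is.na(lo), "N.A.",
                                  sprintf("%.1f-%.1f", round_half_up(lo, 1),
                                          round_half_up(hi, 1)))

metric_display_order <- function() {
  c("over_triage", "under_triage", "efficiency", "sensitivity",
    "specificity", "ppv", "npv")
}

render_overall_text <- function(report) {
  m <- report$overall
  lines <- c("Overall triage test performance",
             sprintf("  %-13s %5s   %-13s (n/N)", "metric", "%", "95% CI"))
  for (nm in metric_display_order()) {
    r <- m[m$metric == nm, ]
    lines <- c(lines, sprintf("  %-13s %5s   %-13s (%d/%d)", nm,
                              fmt_pct(r$point_percent),
                              fmt_ci(r$ci_low_percent, r$ci_high_percent),
                              r$numerator, r$denominator))
  }
  lines
}

render_crosstab_text <- function(report) {
  ct <- report$crosstab
  n <- sum(ct)
  row_tot <- rowSums(ct)
  lines <- c("Dispatch priority vs on-scene urgency",
             sprintf("  %-12s %-16s %-16s %s", "EMD priority", "urgent % (n)",
                     "non-urgent % (n)", "total % (n)"))
  for (p in rownames(ct)) {
    lines <- c(lines, sprintf(
      "  %-12s %-16s %-16s %s", p,
      sprintf("%s (%d)", fmt_pct(100 * ct[p, "urgent"] / row_tot[p]), ct[p, "urgent"]),
      sprintf("%s (%d)", fmt_pct(100 * ct[p, "non_urgent"] / row_tot[p]), ct[p, "non_urgent"]),
      sprintf("%s (%d)", fmt_pct(100 * row_tot[p] / n), row_tot[p])))
  }
  col_tot <- colSums(ct)
  lines <- c(lines, sprintf(
    "  %-12s %-16s %-16s (%d)", "Total",
    sprintf("%s (%d)", fmt_pct(100 * col_tot["urgent"] / n), col_tot["urgent"]),
    sprintf("%s (%d)", fmt_pct(100 * col_tot["non_urgent"] / n), col_tot["non_urgent"]),
    n))
  m <- report$overall
  ot <- m[m$metric == "over_triage", ]
  ut <- m[m$metric == "under_triage", ]
  c(lines,
    sprintf("  Over-triage %s%% (95%% CI %s); Under-triage %s%% (95%% CI %s)",
            fmt_pct(ot$point_percent), fmt_ci(ot$ci_low_percent, ot$ci_high_percent),
            fmt_pct(ut$point_percent), fmt_ci(ut$ci_low_percent, ut$ci_high_percent)))
}

category_table <- function(report) {
  cats <- report$categories
  cols <- metric_display_order()
  out <- data.frame(category = cats$category, n = cats$n,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (nm in cols) out[[nm]] <- fmt_pct(cats[[nm]])
  ord <- order(-ifelse(is.na(cats$over_triage), -1, cats$over_triage), cats$category)
  out[ord, , drop = FALSE]
}

render_categories_text <- function(report) {
  tab <- category_table(report)
  widths <- pmax(nchar(names(tab)), apply(tab, 2, function(x) max(nchar(x), 0)))
  fmt_row <- function(vals) paste0("  ", paste(mapply(formatC, vals,
                                                      width = widths,
                                                      MoreArgs = list(flag = "-")),
                                               collapse = "  "))
  c("Per-category consistency (percent, N.A. where undefined)",
    fmt_row(names(tab)),
    apply(tab, 1, fmt_row))
}

#' Render the report tables
#'
#' Renders the three headline tables (overall metrics, the 4x2 crosstab,
#' and the per-category table in the published column order, sorted by
#' over-triage). Percentages are rounded half-up to integers and interval
#' bounds to one decimal *only here*; undefined cells print as `"N.A."`.
#' Output is deterministic: the same report renders byte-identically.
#'
#' @param report an `analysis_report` from [run_pipeline()].
#' @param format `"text"` (all three tables), `"csv"` (the per-category
#'   table), or `"json"` (the full report, machine-readable, full
#'   precision).
#' @return character scalar containing the rendered output.
#' @export
render_tables <- function(report, format = c("text", "csv", "json")) {
  if (!inherits(report, "analysis_report"))
    stop_input("report must be an analysis_report")
  format <- match.arg(format)
  if (format == "text") {
    return(paste(c(render_overall_text(report), "",
                   render_crosstab_text(report), "",
                   render_categories_text(report)), collapse = "\n"))
  }
  if (format == "csv") {
    tc <- textConnection("out", "w", local = TRUE)
    utils::write.csv(category_table(report), tc, row.names = FALSE, quote = TRUE)
    close(tc)
    return(paste(out, collapse = "\n"))
  }
  # json: full precision, stable structure
  tests <- report$tests
  payload <- list(
    overall = report$overall,
    crosstab = list(counts = unclass(report$crosstab),
                    emd_priority = rownames(report$crosstab),
                    ems_label = colnames(report$crosstab)),
    confusion = unclass(report$confusion),
    categories = report$categories,
    tests = list(
      chi_square = unclass(tests$chi_square),
      kruskal_wallis = if (!is.null(tests$kruskal_wallis)) unclass(tests$kruskal_wallis),
      pairwise = tests$pairwise),
    exclusions = as.list(report$exclusions),
    provenance = report$provenance)
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                null = "null", na = "null", pretty = TRUE))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(render_tables(x, "text"), "\n")
  chi <- x$tests$chi_square
  if (!is.null(chi))
    cat(sprintf("\nChi-square: X2 = %.1f, df = %d, p %s\n", chi$statistic,
                chi$df, format.pval(chi$p_value, eps = 0.001)))
  kw <- x$tests$kruskal_wallis
  if (!is.null(kw))
    cat(sprintf("Kruskal-Wallis: H = %.1f, df = %d, p %s (%d categories)\n",
                kw$statistic, kw$df, format.pval(kw$p_value, eps = 0.001),
                kw$n_groups))
  if (!is.null(x$tests$pairwise))
    cat(sprintf("Pairwise post hoc: %d comparisons, %d significant after Bonferroni\n",
                nrow(x$tests$pairwise), sum(x$tests$pairwise$significant)))
  excl <- x$exclusions
  cat(sprintf("Records: %d analysed, %d excluded\n",
              x$provenance$n_included, sum(excl)))
  invisible(x)
}
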
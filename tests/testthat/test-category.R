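# Per-category summaries and the across-category statistics.

test_that("category summaries partition the overall confusion", {
  reg <- generate_register(default_generator_config(n_dispatches = 2000, seed = 3))
  classified <- classify_ems_urgency(apply_exclusions(reg)$included)
  cats <- summarize_by_category(classified)
  overall <- build_confusion(emd_labels(classified), classified$ems_label)
  expect_equal(sum(cats$tp), overall$tp)
  expect_equal(sum(cats$fp), overall$fp)
  expect_equal(sum(cats$tn), overall$tn)
  expect_equal(sum(cats$fn), overall$fn)
  expect_equal(sum(cats$n), nrow(classified))
  expect_equal(cats$n, cats$emd_urgent_n + cats$emd_non_urgent_n)
  expect_equal(cats$n, cats$tp + cats$fp + cats$tn + cats$fn)
  # per-row metric identities where defined
  def <- !is.na(cats$ppv)
  expect_equal(cats$over_triage[def] + cats$ppv[def], rep(100, sum(def)))
  def <- !is.na(cats$npv)
  expect_equal(cats$under_triage[def] + cats$npv[def], rep(100, sum(def)))
})

test_that("the size filter is strict and single-stratum categories yield N.A.", {
  cells <- list(
    "At bar" = c(TP = 10, FP = 10, TN = 25, FN = 5),      # n = 50: excluded
    "Above bar" = c(TP = 10, FP = 10, TN = 26, FN = 5),   # n = 51: included
    "Only urgent" = c(TP = 30, FP = 31, TN = 0, FN = 0),  # no C/D dispatches
    "Only non urgent" = c(TP = 0, FP = 0, TN = 50, FN = 11))
  classified <- register_from_cells(cells)
  cats <- summarize_by_category(classified, min_n = 50)
  expect_equal(setNames(cats$eligible, cats$category)[names(cells)],
               c("At bar" = FALSE, "Above bar" = TRUE,
                 "Only urgent" = TRUE, "Only non urgent" = TRUE))
  # only A/B dispatches: TN = FN = 0, so NPV and under-triage are undefined
  # while specificity is a defined 0
  ou <- cats[cats$category == "Only urgent", ]
  expect_true(is.na(ou$npv) && is.na(ou$under_triage))
  expect_equal(ou$specificity, 0)
  expect_equal(ou$sensitivity, 100)
  # only C/D dispatches: TP = FP = 0, so PPV and over-triage are undefined
  # while sensitivity is a defined 0
  on <- cats[cats$category == "Only non urgent", ]
  expect_true(is.na(on$ppv) && is.na(on$over_triage))
  expect_equal(on$sensitivity, 0)
  expect_equal(on$specificity, 100)
})

test_that("category labels match case-insensitively after whitespace cleanup", {
  reg <- dispatch_register(
    category = c("Hospital transport", "hospital  transport", "HOSPITAL TRANSPORT",
                 "Fall"),
    emd_priority = "C", paramedic_assessment = "non_urgent")
  cats <- summarize_by_category(classify_ems_urgency(reg), min_n = 0)
  expect_equal(nrow(cats), 2)
  expect_equal(cats$n[cats$category == "Hospital transport"], 3)
})

test_that("chi-square matches the direct formula and detects no association", {
  # identical rows -> zero statistic, p = 1
  flat <- chi_square_association(matrix(c(30, 30, 70, 70), nrow = 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_equal(flat$df, 1)

  set.seed(99)
  for (i in 1:10) {
    tab <- matrix(rpois(6, 40) + 1, nrow = 3)
    res <- chi_square_association(tab)
    expect_equal(res$statistic, oracle_chisq_stat(tab), tolerance = 1e-10)
    expect_equal(res$df, 2)
    # invariant under row/column permutation
    perm <- chi_square_association(tab[sample(3), sample(2)])
    expect_equal(perm$statistic, res$statistic, tolerance = 1e-10)
  }
  expect_error(chi_square_association(matrix(c(0, 0, 5, 5), nrow = 2)),
               "margin")
  expect_error(chi_square_association(matrix(1:3, nrow = 1)), "2x2")
})

test_that("Kruskal-Wallis on the consistency variable matches a rank oracle", {
  cells <- list(
    "Cat A" = c(TP = 20, FP = 10, TN = 30, FN = 2),
    "Cat B" = c(TP = 5, FP = 25, TN = 28, FN = 4),
    "Cat C" = c(TP = 12, FP = 12, TN = 40, FN = 0))
  classified <- register_from_cells(cells)
  res <- kruskal_wallis_consistency(classified, min_n = 10)
  coding <- default_consistency_coding()
  cell <- confusion_cell(emd_labels(classified), classified$ems_label)
  H <- oracle_kw_stat(unname(coding[cell]), classified$category)
  expect_equal(res$statistic, H, tolerance = 1e-10)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, stats::pchisq(H, 2, lower.tail = FALSE))
})

test_that("identical category compositions give a null Kruskal-Wallis result", {
  same <- c(TP = 15, FP = 10, TN = 30, FN = 5)
  classified <- register_from_cells(list(X = same, Y = same, Z = same))
  res <- kruskal_wallis_consistency(classified, min_n = 10)
  expect_equal(res$statistic, 0, tolerance = 1e-10)
  expect_equal(res$p_value, 1, tolerance = 1e-10)

  one_cat <- register_from_cells(list(X = same))
  expect_error(kruskal_wallis_consistency(one_cat, min_n = 10), "at least 2")
  expect_error(kruskal_wallis_consistency(classified, min_n = 10,
                                          coding = c(TP = 1, FP = 1, TN = 2, FN = 3)),
               "distinct")
})

test_that("pairwise post hoc enumerates all pairs with Bonferroni inflation", {
  set.seed(5)
  cells <- lapply(1:6, function(i)
    c(TP = sample(5:20, 1), FP = sample(5:20, 1),
      TN = sample(20:40, 1), FN = sample(0:5, 1)))
  names(cells) <- paste("Cat", 1:6)
  classified <- register_from_cells(cells)
  pw <- pairwise_posthoc(classified, min_n = 10)
  expect_equal(nrow(pw), choose(6, 2))
  expect_true(all(pw$adjusted_p >= pw$p_value - 1e-12))
  expect_true(all(pw$adjusted_p <= 1))
  expect_equal(pw$adjusted_p, pmin(1, pw$p_value * choose(6, 2)))
})

test_that("Dunn's z agrees with Kruskal-Wallis in the two-group case", {
  cells <- list(
    "Cat A" = c(TP = 20, FP = 15, TN = 30, FN = 2),
    "Cat B" = c(TP = 4, FP = 30, TN = 20, FN = 9))
  classified <- register_from_cells(cells)
  pw <- pairwise_posthoc(classified, min_n = 10)
  kw <- kruskal_wallis_consistency(classified, min_n = 10)
  # for k = 2 the tie-corrected Dunn z satisfies z^2 = H
  expect_equal(pw$z[1]^2, kw$statistic, tolerance = 1e-8)
})

test_that("an extreme category is flagged against every other category", {
  normal <- c(TP = 20, FP = 20, TN = 60, FN = 0)
  cells <- list("Plain 1" = normal, "Plain 2" = normal, "Plain 3" = normal,
                "All missed" = c(TP = 0, FP = 0, TN = 0, FN = 100))
  classified <- register_from_cells(cells)
  pw <- pairwise_posthoc(classified, min_n = 10)
  flagged <- pw[pw$significant, ]
  expect_true(nrow(flagged) >= 3)
  expect_true(all(flagged$category_1 == "All missed" |
                  flagged$category_2 == "All missed"))
})
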
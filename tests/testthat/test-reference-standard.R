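# The rule-based reference standard: significant-treatment criterion and
# the stratified urgency classification, checked against brute-force
# oracles on exhaustive field grids.

test_that("treatment criteria are condition-AND-intervention conjunctions", {
  expect_true(has_significant_treatment(
    rec(spo2_percent = 92, bronchodilator = TRUE)))
  expect_false(has_significant_treatment(
    rec(spo2_percent = 92, bronchodilator = FALSE)))
  expect_false(has_significant_treatment(
    rec(spo2_percent = 97, bronchodilator = TRUE)))
  # airway management and CPR are sufficient alone
  expect_true(has_significant_treatment(rec(cpr = TRUE)))
  expect_true(has_significant_treatment(rec(airway_management = TRUE)))
  # a missing vital can never satisfy its criterion
  expect_false(has_significant_treatment(rec(bronchodilator = TRUE)))
  expect_false(has_significant_treatment(rec(iv_glucose = TRUE)))
  expect_false(has_significant_treatment(rec(oxygen = TRUE)))
})

test_that("treatment thresholds are strict at their boundaries", {
  expect_true(has_significant_treatment(
    rec(spo2_percent = 94.9, bronchodilator = TRUE)))
  expect_false(has_significant_treatment(
    rec(spo2_percent = 95, bronchodilator = TRUE)))
  expect_true(has_significant_treatment(
    rec(blood_glucose_mmol_l = 3.99, iv_glucose = TRUE)))
  expect_false(has_significant_treatment(
    rec(blood_glucose_mmol_l = 4, iv_glucose = TRUE)))
  expect_false(has_significant_treatment(
    rec(spco_percent = 5, oxygen = TRUE)))
  expect_true(has_significant_treatment(
    rec(spco_percent = 5.01, oxygen = TRUE)))
})

test_that("treatment criterion matches the brute-force oracle exhaustively", {
  g <- expand.grid(spo2 = c(92, 96, NA), bronch = c(FALSE, TRUE),
                   conv = c(FALSE, TRUE), anticonv = c(FALSE, TRUE),
                   allergy = c(FALSE, TRUE), epi = c(FALSE, TRUE),
                   airway = c(FALSE, TRUE), cpr = c(FALSE, TRUE),
                   gluc = c(3.99, 4, NA), ivgluc = c(FALSE, TRUE),
                   spco = c(5, 5.01, NA), oxy = c(FALSE, TRUE),
                   od = c(FALSE, TRUE), anti = c(FALSE, TRUE))
  reg <- dispatch_register(
    category = "Grid", emd_priority = "B",
    spo2_percent = g$spo2, bronchodilator = g$bronch,
    convulsion = g$conv, anticonvulsant = g$anticonv,
    allergic_reaction = g$allergy, epinephrine = g$epi,
    airway_management = g$airway, cpr = g$cpr,
    blood_glucose_mmol_l = g$gluc, iv_glucose = g$ivgluc,
    spco_percent = g$spco, oxygen = g$oxy,
    overdose_or_poisoning = g$od, antidote = g$anti)
  got <- has_significant_treatment(reg)
  want <- mapply(oracle_significant_treatment,
                 g$spo2, g$bronch, g$conv, g$anticonv, g$allergy, g$epi,
                 g$airway, g$cpr, g$gluc, g$ivgluc, g$spco, g$oxy,
                 g$od, g$anti)
  expect_identical(got, unname(want))
})

test_that("classification follows the stratified rules on canonical cases", {
  cases <- list(
    # paramedic assessment overrides everything
    list(rec(emd_priority = "C", paramedic_assessment = "urgent"),
         "urgent", "paramedic_override"),
    # A/B conveyed with A/B priority
    list(rec(emd_priority = "B", transported = TRUE, transport_priority = "A"),
         "urgent", "ab_transport_ab"),
    # A/B with no urgency marker, even when conveyed C/D
    list(rec(emd_priority = "A", transported = TRUE, transport_priority = "C"),
         "non_urgent", "ab_default_non_urgent"),
    # deceased on A/B is urgent, on C/D non-urgent
    list(rec(emd_priority = "A", deceased = TRUE), "urgent", "ab_deceased"),
    list(rec(emd_priority = "C", deceased = TRUE),
         "non_urgent", "cd_default_non_urgent"),
    # C/D, no conveyance, epinephrine for allergic reaction
    list(rec(emd_priority = "D", allergic_reaction = TRUE, epinephrine = TRUE),
         "urgent", "cd_treatment_no_transport"),
    # C/D conveyed with A/B priority: urgent under the default convention
    list(rec(emd_priority = "C", transported = TRUE, transport_priority = "B"),
         "urgent", "cd_transport_ab"),
    # C/D conveyed C/D with significant treatment stays non-urgent
    list(rec(emd_priority = "C", transported = TRUE, transport_priority = "D",
             cpr = TRUE), "non_urgent", "cd_default_non_urgent"))
  for (cs in cases) {
    out <- classify_ems_urgency(cs[[1]])
    expect_equal(out$ems_label, cs[[2]], label = cs[[3]])
    expect_equal(out$rule_fired, cs[[3]])
  }
})

test_that("classification agrees with the flat-conditional oracle on the rule grid", {
  gr <- rule_grid_register()
  for (convention in c("urgent", "non_urgent")) {
    out <- classify_ems_urgency(gr$register, cd_ab_transport = convention)
    want <- mapply(oracle_classify, gr$grid$priority, gr$grid$paramedic,
                   gr$grid$transport != "none",
                   ifelse(gr$grid$transport == "none", NA, gr$grid$transport),
                   gr$grid$deceased, gr$grid$treated,
                   MoreArgs = list(cd_ab = convention))
    expect_identical(out$ems_label, unname(want))
    # exactly one rule fires per record
    expect_false(any(is.na(out$rule_fired)))
    expect_true(all(out$rule_fired %in% classification_rules()))
  }
})

test_that("the two C/D-conveyed-A/B conventions differ only on that cell", {
  gr <- rule_grid_register()
  default <- classify_ems_urgency(gr$register, cd_ab_transport = "urgent")
  literal <- classify_ems_urgency(gr$register, cd_ab_transport = "non_urgent")
  differs <- default$ems_label != literal$ems_label
  expect_true(all(default$rule_fired[differs] == "cd_transport_ab"))
  expect_true(any(differs))
})

test_that("a documented paramedic assessment is immune to every other field", {
  gr <- rule_grid_register()
  documented <- gr$grid$paramedic != "not_documented"
  out <- classify_ems_urgency(gr$register)
  expect_identical(out$ems_label[documented], gr$grid$paramedic[documented])
  expect_true(all(out$rule_fired[documented] == "paramedic_override"))
})

test_that("adding significant treatment never downgrades an undocumented record", {
  gr <- rule_grid_register()
  undoc <- gr$grid$paramedic == "not_documented"
  base <- gr$register[undoc & !gr$grid$treated, ]
  treated <- base
  treated$cpr <- TRUE
  before <- classify_ems_urgency(emstriage:::new_register(base))$ems_label
  after <- classify_ems_urgency(emstriage:::new_register(treated))$ems_label
  expect_false(any(before == "urgent" & after == "non_urgent"))
})

test_that("classification refuses excluded records", {
  reg <- dispatch_register(category = "Fall", emd_priority = "C",
                           status = "cancelled")
  expect_error(classify_ems_urgency(reg), "apply_exclusions")
})
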
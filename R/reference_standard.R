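# Rule-based reference standard: the on-scene (EMS-side) urgency label
# constructed from the paramedic's voluntary assessment, conveyance priority,
# death on scene, and the significant-treatment criteria.

#' Rule identifiers of the reference standard
#'
#' The classifier records, per record, the first rule satisfied in its fixed
#' evaluation order. `paramedic_override` fires whenever the paramedic
#' documented an urgency assessment (documentation was voluntary, so this is
#' not always available). The remaining rules are stratified by the dispatch
#' side: lights-and-siren dispatches (A/B) versus non-urgent dispatches (C/D).
#'
#' @return character vector of rule identifiers.
#' @export
classification_rules <- function() {
  c("paramedic_override",
    "ab_transport_ab",        # A/B dispatch, conveyed with A/B priority -> urgent
    "ab_deceased",            # A/B dispatch, patient deceased           -> urgent
    "ab_significant_treatment",# A/B dispatch, significant treatment     -> urgent
    "ab_default_non_urgent",  # A/B dispatch, none of the above          -> non-urgent
    "cd_transport_ab",        # C/D dispatch, conveyed with A/B priority (see below)
    "cd_treatment_no_transport",# C/D dispatch, no conveyance, significant treatment -> urgent
    "cd_default_non_urgent")  # C/D dispatch otherwise (incl. deceased)  -> non-urgent
}

#' Significant-treatment criterion
#'
#' A dispatch counts as having received significant treatment when at least
#' one of eight condition-plus-intervention conjunctions holds:
#'
#' 1. SpO2 < 95 % and bronchodilators given;
#' 2. convulsion and an anticonvulsant given;
#' 3. allergic reaction and epinephrine given;
#' 4. any airway management (sufficient alone);
#' 5. CPR (sufficient alone);
#' 6. blood glucose < 4 mmol/L and IV glucose given;
#' 7. SpCO > 5 % and oxygen given;
#' 8. overdose or poisoning and an antidote given.
#'
#' A missing vital sign can never satisfy its criterion: "not measured" is
#' distinct from any numeric value, so e.g. oxygen given without a recorded
#' SpCO does not count.
#'
#' @param register a `dispatch_register` (or any data frame with the clinical
#'   and intervention columns).
#' @return logical vector, one element per record.
#' @export
has_significant_treatment <- function(register) {
  r <- register
  spo2_low <- !is.na(r$spo2_percent) & r$spo2_percent < 95
  gluc_low <- !is.na(r$blood_glucose_mmol_l) & r$blood_glucose_mmol_l < 4
  spco_high <- !is.na(r$spco_percent) & r$spco_percent > 5
  (spo2_low & r$bronchodilator) |
    (r$convulsion & r$anticonvulsant) |
    (r$allergic_reaction & r$epinephrine) |
    r$airway_management |
    r$cpr |
    (gluc_low & r$iv_glucose) |
    (spco_high & r$oxygen) |
    (r$overdose_or_poisoning & r$antidote)
}

#' Classify on-scene urgency (reference standard)
#'
#' Assigns every included record the binary EMS-side urgency label, together
#' with the rule that produced it. Evaluation order:
#'
#' 1. If the paramedic documented an assessment, that assessment is the label
#'    (`paramedic_override`) and nothing else is consulted.
#' 2. For A/B (lights-and-siren) dispatches: urgent if conveyed with A/B
#'    priority, or the patient had deceased, or significant treatment was
#'    given (regardless of conveyance); otherwise non-urgent.
#' 3. For C/D dispatches: urgent if conveyed with A/B priority (an upgrade of
#'    the response on scene — see `cd_ab_transport` below), or if not conveyed
#'    but significant treatment was given; otherwise non-urgent. A deceased
#'    patient on a C/D dispatch is non-urgent, as is conveyance with C/D
#'    priority even when treatment was given (the treatment rule for this
#'    stratum requires no conveyance).
#'
#' The classification of a C/D dispatch conveyed with A/B priority is
#' genuinely ambiguous in the criteria's tabular form; the default treats it
#' as urgent (so such records become false negatives of the dispatcher),
#' which matches how the study population's false negatives are described.
#' Set `cd_ab_transport = "non_urgent"` for the alternative literal reading.
#'
#' @param register a `dispatch_register`; every record must have status
#'   `"completed_patient_confronted"` (run [apply_exclusions()] first).
#' @param cd_ab_transport how to label a C/D dispatch conveyed with A/B
#'   priority (no paramedic assessment documented): `"urgent"` (default) or
#'   `"non_urgent"`.
#' @return the register with three columns appended: `ems_label`
#'   (`"urgent"`/`"non_urgent"`), `rule_fired` (see
#'   [classification_rules()]), and `significant_treatment` (logical).
#' @export
classify_ems_urgency <- function(register, cd_ab_transport = c("urgent", "non_urgent")) {
  cd_ab_transport <- match.arg(cd_ab_transport)
  if (any(register$status != "completed_patient_confronted"))
    stop_contract("classify_ems_urgency() requires included records only; ",
                  "run apply_exclusions() first (",
                  sum(register$status != "completed_patient_confronted"),
                  " excluded record(s) present)")
  n <- nrow(register)
  sig <- has_significant_treatment(register)
  emd_urgent <- dichotomise_emd(register$emd_priority) == "urgent"
  transport_ab <- register$transported &
    register$transport_priority %in% c("A", "B")
  documented <- register$paramedic_assessment != "not_documented"

  label <- rep(NA_character_, n)
  rule <- rep(NA_character_, n)

  # (1) paramedic primacy
  label[documented] <- register$paramedic_assessment[documented]
  rule[documented] <- "paramedic_override"

  todo <- !documented
  # (2) A/B stratum, urgent conditions in fixed order, then default
  ab <- todo & emd_urgent
  hit <- ab & transport_ab
  label[hit] <- "urgent"; rule[hit] <- "ab_transport_ab"
  open <- ab & is.na(label)
  hit <- open & register$deceased
  label[hit] <- "urgent"; rule[hit] <- "ab_deceased"
  open <- ab & is.na(label)
  hit <- open & sig
  label[hit] <- "urgent"; rule[hit] <- "ab_significant_treatment"
  open <- ab & is.na(label)
  label[open] <- "non_urgent"; rule[open] <- "ab_default_non_urgent"

  # (3) C/D stratum
  cd <- todo & !emd_urgent
  hit <- cd & transport_ab
  label[hit] <- cd_ab_transport; rule[hit] <- "cd_transport_ab"
  open <- cd & is.na(label)
  hit <- open & !register$transported & sig
  label[hit] <- "urgent"; rule[hit] <- "cd_treatment_no_transport"
  open <- cd & is.na(label)
  label[open] <- "non_urgent"; rule[open] <- "cd_default_non_urgent"

  out <- as.data.frame(register)
  out$ems_label <- label
  out$rule_fired <- rule
  out$significant_treatment <- sig
  new_register(out, parse_report = parse_report(register))
}

#' Dispatcher-side labels for a classified register
#'
#' Convenience accessor: the EMD dichotomy of each record's dispatch
#' priority, aligned with the `ems_label` column of
#' [classify_ems_urgency()]'s output.
#'
#' @param classified a classified `dispatch_register`.
#' @return character vector of `"urgent"` / `"non_urgent"`.
#' @export
emd_labels <- function(classified) dichotomise_emd(classified$emd_priority)
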
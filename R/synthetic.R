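# Seeded synthetic dispatch-register generator.
#
# Real Finnish dispatch-register extracts are restricted, so the package
# ships the aggregate profile of a one-month regional register (category
# frequencies and per-category dispatcher/on-scene urgency counts) and a
# generator that materialises record-level registers with that structure.
# Generation is latent-label-first: the on-scene urgency label is sampled
# from the profile's conditional distribution and the clinical fields are
# then constructed to satisfy exactly one reference-standard rule for that
# label, so the classifier provably recovers the latent label (the
# generator's defining contract, checked in the tests).

#' Aggregate register profile used for generator defaults
#'
#' Per-category counts from a one-month regional EMS dispatch register
#' (6153 dispatches in the 26 categories with more than 50 dispatches; the
#' register's remaining 263 dispatches fell in 29 rarer categories that are
#' not profiled): total `n`, dispatcher-urgent count `emd_urgent_n`, and the
#' confusion cells `tp`, `fp`, `tn`, `fn` of the dispatcher dichotomy
#' against the on-scene reference standard. `Psychiatric symptom` has no
#' urgent dispatch priority available; `Unconscious` and `Unspecific
#' symptoms` have no non-urgent one.
#'
#' @return data frame with one row per dispatch category.
#' @export
register_profile <- function() {
  profile <- utils::read.csv(text = "category;n;emd_urgent_n;tp;fp;tn;fn
General weakness;984;139;26;113;827;18
Fall;882;159;34;125;709;14
Chest pain;631;516;105;411;110;5
Breathing difficulty;407;186;53;133;211;10
Psychiatric symptom;325;0;0;0;306;19
Rhythm disorder;314;83;16;67;229;2
Stroke;306;250;65;185;54;2
Abdominal pain;286;34;11;23;247;5
Hospital transport;253;120;84;36;117;16
Poisoning;224;84;42;42;128;12
Back pain;183;9;2;7;171;3
Limb pain;144;9;2;7;134;1
Nausea, diarrhoea, constipation;140;3;2;1;134;3
Convulsion;137;85;31;54;50;2
Headache;110;46;7;39;62;2
Traffic accident, bicycle etc.;109;44;14;30;65;0
Unconscious;99;99;42;57;0;0
Traffic accident, small;97;54;9;45;42;1
Impact/hit;76;46;9;37;30;0
Unspecific symptoms;75;75;9;66;0;0
Blood glucose problem;75;19;6;13;53;3
Cut;67;23;7;16;44;0
Allergic reaction;65;45;9;36;20;0
Body pain;59;4;0;4;51;4
Assault;54;4;0;4;50;0
Cardiac arrest;51;48;44;4;3;0",
    sep = ";", stringsAsFactors = FALSE)
  stopifnot(all(profile$tp + profile$fp == profile$emd_urgent_n),
            all(profile$tn + profile$fn == profile$n - profile$emd_urgent_n))
  profile
}

#' Reference priority-by-urgency crosstab of the profiled register
#'
#' The full 4x2 crosstabulation of the same one-month register (all 6416
#' analysed dispatches, including the rare categories absent from
#' [register_profile()]): dispatcher priority A-D against the on-scene
#' reference-standard urgency.
#'
#' @return 4x2 integer matrix in the layout of [build_crosstab()].
#' @export
reference_crosstab <- function() {
  matrix(c(188L, 500L, 99L, 27L,
           153L, 1500L, 2161L, 1788L), nrow = 4,
         dimnames = list(emd_priority = dispatch_priorities(),
                         ems_label = c("urgent", "non_urgent")))
}

# Construction-rule catalogue: which field patterns realise each
# (dispatch stratum, target label) combination.
construction_rules <- function(cd_ab_transport) {
  rules <- list(
    ab_urgent = c("ab_transport_ab", "ab_deceased", "ab_significant_treatment"),
    ab_non_urgent = c("ab_nonurgent_transport_cd", "ab_nonurgent_no_transport"),
    cd_urgent = "cd_treatment_no_transport",
    cd_non_urgent = c("cd_transport_cd", "cd_no_transport", "cd_deceased")
  )
  if (cd_ab_transport == "urgent") {
    rules$cd_urgent <- c("cd_transport_ab", rules$cd_urgent)
  } else {
    rules$cd_non_urgent <- c(rules$cd_non_urgent, "cd_transport_ab")
  }
  rules
}

#' Generator configuration
#'
#' Assembles and validates the configuration of [generate_register()].
#' [default_generator_config()] derives every distributional parameter from
#' [register_profile()] and [reference_crosstab()]: category weights
#' proportional to profiled category sizes, per-category probabilities of an
#' urgent dispatch, conditional probabilities of on-scene urgency given the
#' dispatch stratum (all as count ratios, not rounded percentages), the A
#' share within A/B (341/2341) and C share within C/D (2260/4075), and an
#' exclusion rate of 829/7245 — the register's rate of cancelled, aborted,
#' not-confronted, first-responder and invalid-data missions — so that the
#' default `n_dispatches = 7245` yields about 6416 analysable records.
#'
#' @param n_dispatches total records to generate, including excluded ones.
#' @param category_weights named probabilities summing to 1.
#' @param emd_urgent_given_category named probability of an A/B dispatch per
#'   category.
#' @param ems_urgent_given_emd_urgent,ems_urgent_given_emd_non_urgent named
#'   conditional probabilities of an urgent on-scene label; `NA` allowed for
#'   a stratum a category can never occupy.
#' @param paramedic_documentation_rate probability that the paramedic
#'   documented an on-scene urgency assessment (documentation is voluntary;
#'   default 0.3, a package convention since no rate is published).
#' @param exclusion_rate probability that a record is excluded
#'   (cancelled/aborted/not confronted/first responder/invalid data).
#' @param a_within_ab,c_within_cd probability of priority A within an urgent
#'   dispatch, and of C within a non-urgent one.
#' @param rule_weights optional named non-negative weights over the
#'   construction rules (see [classification_rules()] analogues in the
#'   generated `rule` attribute); default uniform within each
#'   (stratum, label) combination.
#' @param cd_ab_transport passed through to [classify_ems_urgency()]'s
#'   convention; controls which label a C/D dispatch conveyed with A/B
#'   priority realises.
#' @param seed integer seed; generation is reproducible for a fixed seed.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_dispatches, category_weights,
                             emd_urgent_given_category,
                             ems_urgent_given_emd_urgent,
                             ems_urgent_given_emd_non_urgent,
                             paramedic_documentation_rate = 0.3,
                             exclusion_rate = 0,
                             a_within_ab = 0.5, c_within_cd = 0.5,
                             rule_weights = NULL,
                             cd_ab_transport = c("urgent", "non_urgent"),
                             seed = 20210801L) {
  cd_ab_transport <- match.arg(cd_ab_transport)
  cats <- names(category_weights)
  if (is.null(cats) || anyDuplicated(cats))
    stop_input("category_weights must be uniquely named")
  if (abs(sum(category_weights) - 1) > 1e-9)
    stop_input("category_weights must sum to 1 (got ", sum(category_weights), ")")
  for (nm in c("emd_urgent_given_category", "ems_urgent_given_emd_urgent",
               "ems_urgent_given_emd_non_urgent")) {
    v <- get(nm)
    if (!all(cats %in% names(v)))
      stop_input(nm, " must cover every category in category_weights")
    ok <- is.na(v) | (v >= 0 & v <= 1)
    if (!all(ok)) stop_input(nm, " must lie in [0, 1]")
  }
  probs <- c(paramedic_documentation_rate, exclusion_rate, a_within_ab, c_within_cd)
  if (any(probs < 0 | probs > 1)) stop_input("rates must lie in [0, 1]")
  structure(list(
    n_dispatches = as.integer(n_dispatches),
    category_weights = category_weights,
    emd_urgent_given_category = emd_urgent_given_category[cats],
    ems_urgent_given_emd_urgent = ems_urgent_given_emd_urgent[cats],
    ems_urgent_given_emd_non_urgent = ems_urgent_given_emd_non_urgent[cats],
    paramedic_documentation_rate = paramedic_documentation_rate,
    exclusion_rate = exclusion_rate,
    a_within_ab = a_within_ab, c_within_cd = c_within_cd,
    rule_weights = rule_weights, cd_ab_transport = cd_ab_transport,
    seed = as.integer(seed)), class = "generator_config")
}

#' @rdname generator_config
#' @export
default_generator_config <- function(n_dispatches = 7245, seed = 20210801L,
                                     paramedic_documentation_rate = 0.3,
                                     exclusion_rate = 829 / 7245,
                                     cd_ab_transport = "urgent",
                                     rule_weights = NULL) {
  p <- register_profile()
  w <- stats::setNames(p$n / sum(p$n), p$category)
  nu <- p$n - p$emd_urgent_n
  generator_config(
    n_dispatches = n_dispatches,
    category_weights = w,
    emd_urgent_given_category = stats::setNames(p$emd_urgent_n / p$n, p$category),
    ems_urgent_given_emd_urgent =
      stats::setNames(ifelse(p$emd_urgent_n > 0, p$tp / p$emd_urgent_n, NA_real_),
                      p$category),
    ems_urgent_given_emd_non_urgent =
      stats::setNames(ifelse(nu > 0, p$fn / nu, NA_real_), p$category),
    paramedic_documentation_rate = paramedic_documentation_rate,
    exclusion_rate = exclusion_rate,
    a_within_ab = 341 / 2341, c_within_cd = 2260 / 4075,
    rule_weights = rule_weights, cd_ab_transport = cd_ab_transport,
    seed = seed)
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(paste0("<generator_config: %d dispatches, %d categories, ",
                     "exclusion rate %.3f, seed %d>\n"),
              x$n_dispatches, length(x$category_weights), x$exclusion_rate,
              x$seed))
  invisible(x)
}

sample_rule <- function(combo, candidates, n, rule_weights) {
  w <- rep(1, length(candidates))
  if (!is.null(rule_weights)) {
    ov <- rule_weights[candidates]
    w[!is.na(ov)] <- ov[!is.na(ov)]
  }
  if (sum(w) <= 0)
    stop_input("no applicable construction rule for combination '", combo,
               "': all rule weights are zero")
  if (length(candidates) == 1) rep(candidates, n)
  else sample(candidates, n, replace = TRUE, prob = w)
}

treatment_criteria <- function() {
  c("spo2_bronchodilator", "convulsion_anticonvulsant", "allergy_epinephrine",
    "airway_management", "cpr", "glucose_iv_glucose", "spco_oxygen",
    "overdose_antidote")
}

#' Generate a synthetic dispatch register
#'
#' Samples `n_dispatches` records under `config`: category, exclusion
#' status, dispatch priority (urgent/non-urgent dichotomy, then the A-vs-B
#' or C-vs-D letter), then the latent on-scene urgency label from the
#' per-category conditional distribution. With probability
#' `paramedic_documentation_rate` the label is realised as a documented
#' paramedic assessment; the remaining clinical fields are always
#' constructed to satisfy exactly one reference-standard rule for the
#' latent label, drawn uniformly (or per `rule_weights`) from the rules
#' applicable to the record's (stratum, label) combination. Vitals are
#' sampled away from the decision thresholds (SpO2 on \[85, 92\], glucose on
#' \[1.5, 3.5\] mmol/L, SpCO on \[6, 15\] %) so classification is never a
#' rounding question.
#'
#' @param config a `generator_config`.
#' @return a `dispatch_register` with attributes `generator_config` (the
#'   config used) and `latent` (data frame `record_id`, `latent_label`,
#'   `construction_rule` for included records — the ground truth the
#'   classifier must recover).
#' @export
generate_register <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_dispatches
  cats <- names(config$category_weights)

  category <- sample(cats, n, replace = TRUE, prob = config$category_weights)
  excluded <- stats::runif(n) < config$exclusion_rate
  status <- rep("completed_patient_confronted", n)
  status[excluded] <- sample(excluded_statuses(), sum(excluded), replace = TRUE)

  p_urgent <- config$emd_urgent_given_category[category]
  emd_urgent <- stats::runif(n) < p_urgent
  emd_priority <- ifelse(emd_urgent,
                         ifelse(stats::runif(n) < config$a_within_ab, "A", "B"),
                         ifelse(stats::runif(n) < config$c_within_cd, "C", "D"))

  p_ems <- ifelse(emd_urgent,
                  config$ems_urgent_given_emd_urgent[category],
                  config$ems_urgent_given_emd_non_urgent[category])
  undefined <- !excluded & is.na(p_ems)
  if (any(undefined)) {
    i <- which(undefined)[1]
    stop_input("no on-scene urgency distribution for category '", category[i],
               "' with ", ifelse(emd_urgent[i], "urgent", "non-urgent"),
               " dispatch: the profile marks this combination unavailable")
  }
  ems_urgent <- !is.na(p_ems) & stats::runif(n) < p_ems
  label <- ifelse(ems_urgent, "urgent", "non_urgent")

  documented <- stats::runif(n) < config$paramedic_documentation_rate

  # assign a construction rule per included record
  rules <- construction_rules(config$cd_ab_transport)
  combo <- paste0(ifelse(emd_urgent, "ab", "cd"), "_",
                  ifelse(ems_urgent, "urgent", "non_urgent"))
  rule <- rep(NA_character_, n)
  for (cb in unique(combo[!excluded])) {
    idx <- which(!excluded & combo == cb)
    rule[idx] <- sample_rule(cb, rules[[cb]], length(idx), config$rule_weights)
  }

  # materialise fields
  reg <- dispatch_register(category = category, emd_priority = emd_priority,
                           status = status)
  df <- as.data.frame(reg)
  df$paramedic_assessment[!excluded & documented] <- label[!excluded & documented]

  set_transport <- function(idx, pri) {
    df$transported[idx] <<- TRUE
    df$transport_priority[idx] <<- pri
  }
  idx <- which(rule %in% c("ab_transport_ab", "cd_transport_ab"))
  set_transport(idx, ifelse(stats::runif(length(idx)) < config$a_within_ab, "A", "B"))
  idx <- which(rule %in% c("ab_nonurgent_transport_cd", "cd_transport_cd"))
  set_transport(idx, ifelse(stats::runif(length(idx)) < config$c_within_cd, "C", "D"))
  idx <- which(rule %in% c("ab_deceased", "cd_deceased"))
  df$deceased[idx] <- TRUE

  treat <- which(rule %in% c("ab_significant_treatment", "cd_treatment_no_transport"))
  if (length(treat)) {
    crit <- sample(treatment_criteria(), length(treat), replace = TRUE)
    assign_crit <- function(name, fields) {
      i <- treat[crit == name]
      for (f in names(fields)) {
        v <- fields[[f]]
        df[[f]][i] <<- if (is.function(v)) v(length(i)) else v
      }
    }
    assign_crit("spo2_bronchodilator",
                list(spo2_percent = function(k) stats::runif(k, 85, 92),
                     bronchodilator = TRUE))
    assign_crit("convulsion_anticonvulsant",
                list(convulsion = TRUE, anticonvulsant = TRUE))
    assign_crit("allergy_epinephrine",
                list(allergic_reaction = TRUE, epinephrine = TRUE))
    assign_crit("airway_management", list(airway_management = TRUE))
    assign_crit("cpr", list(cpr = TRUE))
    assign_crit("glucose_iv_glucose",
                list(blood_glucose_mmol_l = function(k) stats::runif(k, 1.5, 3.5),
                     iv_glucose = TRUE))
    assign_crit("spco_oxygen",
                list(spco_percent = function(k) stats::runif(k, 6, 15),
                     oxygen = TRUE))
    assign_crit("overdose_antidote",
                list(overdose_or_poisoning = TRUE, antidote = TRUE))
  }

  out <- validate_register(new_register(df))
  attr(out, "generator_config") <- config
  attr(out, "latent") <- data.frame(
    record_id = df$record_id[!excluded],
    latent_label = label[!excluded],
    construction_rule = rule[!excluded],
    stringsAsFactors = FALSE)
  out
}

#' Latent ground-truth labels of a generated register
#'
#' @param register output of [generate_register()].
#' @return data frame `record_id`, `latent_label`, `construction_rule` for
#'   the included (analysable) records.
#' @export
latent_labels <- function(register) {
  lat <- attr(register, "latent")
  if (is.null(lat)) stop_input("register carries no latent labels; ",
                               "was it produced by generate_register()?")
  lat
}
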
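# Independent brute-force oracles, transcribed flat from the urgency
# criteria and from the textbook statistic formulas.  These deliberately
# share no code with the package implementations they check.

# Significant treatment: the eight condition-plus-intervention conjunctions,
# one if-clause each, evaluated on scalar fields.
oracle_significant_treatment <- function(spo2, bronch, conv, anticonv,
                                         allergy, epi, airway, cpr,
                                         gluc, ivgluc, spco, oxy, od, anti) {
  if (!is.na(spo2) && spo2 < 95 && bronch) return(TRUE)
  if (conv && anticonv) return(TRUE)
  if (allergy && epi) return(TRUE)
  if (airway) return(TRUE)
  if (cpr) return(TRUE)
  if (!is.na(gluc) && gluc < 4 && ivgluc) return(TRUE)
  if (!is.na(spco) && spco > 5 && oxy) return(TRUE)
  if (od && anti) return(TRUE)
  FALSE
}

# Urgency label: flat nested conditionals straight off the criteria table.
oracle_classify <- function(priority, paramedic, transported, transport_pri,
                            deceased, sig, cd_ab = "urgent") {
  if (paramedic != "not_documented") return(paramedic)
  transported_ab <- transported && transport_pri %in% c("A", "B")
  if (priority %in% c("A", "B")) {
    if (transported_ab) return("urgent")
    if (deceased) return("urgent")
    if (sig) return("urgent")
    return("non_urgent")
  }
  if (transported_ab) return(cd_ab)
  if (!transported && sig) return("urgent")
  "non_urgent"
}

# Pearson chi-square by the definition sum((O-E)^2/E).
oracle_chisq_stat <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Tie-corrected Kruskal-Wallis H from rank sums.
oracle_kw_stat <- function(score, group) {
  N <- length(score)
  r <- rank(score)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, group, function(x) length(x) * mean(x)^2)) - 3 * (N + 1)
  ties <- table(score)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Exhaustive record grid over the rule-level fields (transport state x
# paramedic x priority x deceased x treatment), as a register plus the
# scalar columns the oracle consumes.
rule_grid_register <- function() {
  g <- expand.grid(priority = c("A", "B", "C", "D"),
                   paramedic = c("urgent", "non_urgent", "not_documented"),
                   transport = c("none", "A", "B", "C", "D"),
                   deceased = c(FALSE, TRUE),
                   treated = c(FALSE, TRUE),
                   stringsAsFactors = FALSE)
  reg <- dispatch_register(
    category = "Grid", emd_priority = g$priority,
    paramedic_assessment = g$paramedic,
    transported = g$transport != "none",
    transport_priority = ifelse(g$transport == "none", NA, g$transport),
    deceased = g$deceased,
    cpr = g$treated)          # CPR alone realises significant treatment
  list(grid = g, register = reg)
}
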
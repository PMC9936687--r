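# Builders for small in-memory registers used across the test files.

# One-row register with sensible defaults, any field overridable.
rec <- function(..., category = "Chest pain", emd_priority = "B") {
  dispatch_register(category = category, emd_priority = emd_priority, ...)
}

# Register realising a given 4x2 priority-by-urgency crosstab by letting the
# paramedic assessment carry the on-scene label (override rule), so the
# classified register reproduces the crosstab exactly.
register_from_crosstab <- function(crosstab, category = "Mixed") {
  pri <- rep(rep(rownames(crosstab), ncol(crosstab)), as.vector(crosstab))
  lab <- rep(rep(colnames(crosstab), each = nrow(crosstab)), as.vector(crosstab))
  dispatch_register(category = category, emd_priority = pri,
                    paramedic_assessment = lab)
}

# Classified register with a prescribed per-category cell composition.
# `cells` is a named list: category -> c(TP = , FP = , TN = , FN = ).
register_from_cells <- function(cells) {
  cat <- character(0); pri <- character(0); lab <- character(0)
  for (nm in names(cells)) {
    k <- cells[[nm]]
    cat <- c(cat, rep(nm, sum(k)))
    pri <- c(pri, rep(c("A", "B", "C", "C"),
                      c(k[["TP"]], k[["FP"]], k[["TN"]], k[["FN"]])))
    lab <- c(lab, rep(c("urgent", "non_urgent", "non_urgent", "urgent"),
                      c(k[["TP"]], k[["FP"]], k[["TN"]], k[["FN"]])))
  }
  reg <- dispatch_register(category = cat, emd_priority = pri,
                           paramedic_assessment = lab)
  classify_ems_urgency(reg)
}

random_confusion <- function() {
  confusion_counts(tp = sample(0:200, 1), fp = sample(0:200, 1),
                   tn = sample(1:500, 1), fn = sample(0:100, 1))
}
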
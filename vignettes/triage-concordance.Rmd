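---
title: "Methods: dispatch-priority concordance against an on-scene reference standard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dispatch-priority concordance against an on-scene reference standard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emstriage)
```

## The measurement problem

Telephone triage assigns each ambulance mission a dispatch priority (A/B =
lights-and-siren, C/D = non-urgent response) before anyone has seen the
patient. `emstriage` treats that assignment as a binary diagnostic test —
A/B positive, C/D negative — and evaluates it against a reference standard
constructed from the on-scene record. Neither side uses a severity score
(Finnish paramedics do not routinely score NACA or METTS), so the reference
standard is a fixed rule set over fields any electronic EMS record
contains.

## The reference standard

Each analysed record receives exactly one urgent/non-urgent label, from the
first matching step:

1. **Paramedic primacy.** If the crew documented an on-scene urgency
   assessment, that assessment is the label, unconditionally. Documentation
   is voluntary, so this rule covers only part of the register.
2. **A/B dispatches** are urgent if the patient was conveyed with A/B
   priority, or had deceased, or received *significant treatment*
   (regardless of conveyance); otherwise non-urgent.
3. **C/D dispatches** are urgent if conveyed with A/B priority, or if not
   conveyed but given significant treatment; otherwise non-urgent —
   including conveyance with C/D priority (even with treatment, since that
   stratum's treatment rule requires no conveyance) and death on scene
   (on a C/D dispatch an expected death is the usual explanation).

*Significant treatment* is a disjunction of eight condition-plus-
intervention conjunctions: SpO2 < 95 % with bronchodilators; convulsion
with an anticonvulsant; allergic reaction with epinephrine; any airway
management; CPR; blood glucose < 4 mmol/L with IV glucose; SpCO > 5 % with
oxygen; overdose/poisoning with an antidote. Two are single-sided (airway
management, CPR); the rest require both the condition and the treatment, so
**a missing vital sign can never fire its criterion** — "not measured" is
an explicit state distinct from any value, and oxygen given without a
recorded SpCO does not count. Thresholds are strict (`< 95`, `< 4`, `> 5`).

Within each stratum the urgent-triggering conditions are tested in the
fixed order above and the trace records the first rule satisfied. The order
only affects the trace, not the label: the urgent conditions are
individually sufficient, non-urgent is their complement.

### The one genuinely ambiguous cell

A C/D dispatch conveyed with A/B priority sits between two readings: the
conveyance upgrade marks the case urgent (so the dispatcher scored a false
negative), or the literal non-urgent stratum keeps it non-urgent. The
package defaults to **urgent** (`cd_ab_transport = "urgent"`), which is the
reading under which urgent conveyance after a non-urgent dispatch counts
against the dispatcher; the alternative is a switch on
`classify_ems_urgency()` and the generator, and the two conventions differ
on no other cell (tested). Note the caveat that conveyance priority in the
Finnish system can be raised for non-medical (fleet-availability) reasons,
which makes this cell noisy in real data no matter the convention.

## Test-performance metrics

With the dispatcher urgent as test positive and the reference standard
urgent as condition positive: efficiency (TP+TN)/n, sensitivity TP/(TP+FN),
specificity TN/(TN+FP), PPV TP/(TP+FP), NPV TN/(TN+FN), over-triage
100−PPV, under-triage 100−NPV. The identities over-triage + PPV = 100 and
under-triage + NPV = 100 hold exactly at full precision and are asserted in
the tests. A metric whose denominator is empty — e.g. NPV in a category
whose protocol admits only A/B priorities — is `NA`, rendered `"N.A."`,
never 0.

**Confidence intervals** default to the Wald normal approximation
`p ± z·sqrt(p(1−p)/n)` with z = 1.96, clamped to [0, 100]. Wald is the
method that reproduces, at one-decimal rounding, all the interval bounds
the profiled register's audit reports (e.g. sensitivity 82.0–87.0 from
688/814; under-triage 2.6–3.6 from 126/4075), which is how the otherwise
unnamed method was identified; the Wilson score interval
(`ci_method = "wilson"`, cross-checked against `prop.test`) is preferable
for the small single-digit cells of minor categories. One profiled overall
value does not recompute: the register's printed specificity of 71 %
(69.3–71.1) against TN/(TN+FP) = 3949/5602 = 70.5 % (Wald 69.3–71.7); the
upper bound being below the rounded point estimate marks it as a
typographical slip, and the package reports the recomputed value.

**Rounding** is commercial half-up (`round_half_up()`), integers for
points and one decimal for bounds, applied *only* in `render_tables()` /
the acceptance summaries; everything upstream carries full precision.

## Across-category comparison

Categories are free-text labels matched case-insensitively after
whitespace normalisation (register exports spell the same category
inconsistently, e.g. hospital transport/transfer). A category enters the
across-category tests when it has **more than 50** dispatches — strict,
so n = 51 qualifies and n = 50 does not.

The chi-square test runs on the 4×2 priority-by-urgency crosstab (rows
with zero margin, i.e. priorities absent from a small register, are
dropped first). The Kruskal–Wallis H test (tie-corrected) runs on the
**record-level** consistency variable: each record's confusion cell scored
by an injective coding, default TP = 1, FP = 2, TN = 3, FN = 4 (the
conventional listing order; the coding is a documented parameter, not an
empirical fact — any injective coding gives the same H because the
statistic depends only on ranks of the four distinct values in the same
order pattern, but the parameter keeps that choice explicit). Record-level
scoring is the only reading under which the degrees of freedom equal
(number of eligible categories − 1), e.g. 25 for 26 categories. The post
hoc is **Dunn's z-test** on pooled mean ranks with the same tie
correction, Bonferroni-adjusted over all k(k−1)/2 pairs — the conventional
companion of Kruskal–Wallis in SPSS-style workflows; it is hand-implemented
here and verified in the tests via the two-group identity z² = H and a
forced extreme-category construction.

## The synthetic register generator

Register-level health data are restricted, so the generator emulates the
aggregate profile the audit of a one-month regional register makes public:
26 dispatch categories (6153 dispatches) with, per category, the share of
urgent dispatches and the confusion-cell composition. Defaults
(`default_generator_config()`):

* `n_dispatches = 7245` with `exclusion_rate = 829/7245` (cancelled,
  aborted, patient not confronted, first responder, invalid data), giving
  ≈ 6416 analysable records — the audit's scale;
* category weights ∝ profiled sizes; per-category P(A/B dispatch) and
  P(urgent on scene | dispatch stratum) as **count ratios**, not the
  rounded printed percentages, so cells stay internally consistent;
* `a_within_ab = 341/2341` and `c_within_cd = 2260/4075` from the
  crosstab margins (the letter split is sampled independently of the
  on-scene label within each dichotomy — see limitations);
* `paramedic_documentation_rate = 0.3`: documentation was voluntary and no
  rate is published; 0.3 is a package convention, stated as such;
* `seed = 20210801` (the profiled register's collection month) — fixed so
  a default generation is reproducible.

Generation is **latent-label-first**: category, exclusion, dispatch
stratum and letter, then the latent on-scene label, then fields
constructed to satisfy exactly one reference-standard rule for that
(stratum, label) combination, drawn uniformly over the applicable rules
(overridable via `rule_weights`; a combination whose rules are all zeroed
raises an error naming it). With probability 0.3 the label is additionally
realised as a documented paramedic assessment. Vitals are sampled away
from thresholds — SpO2 on [85, 92] %, glucose on [1.5, 3.5] mmol/L, SpCO
on [6, 15] % — so classification is never a floating-point boundary
question; threshold-adjacent cases are exercised by dedicated fixtures in
the tests instead. The defining contract, tested on every generated
register, is that `classify_ems_urgency()` recovers 100 % of latent labels
for included records.

### What the generator does and does not emulate

It reproduces: category frequencies, per-category dispatch-priority and
on-scene-urgency composition, the exclusion rate, and record-level fields
sufficient to exercise every classifier branch. It does **not** reproduce:
the 29 rare unprofiled categories (so its overall confusion expectation is
the profiled-cell sum (629, 1555, 3847, 122)/6153, slightly different from
the full register's (688, 1653, 3949, 126)/6416); the different on-scene
urgency rates of A-row vs B-row dispatches *within* the urgent dichotomy
(the real register's A dispatches were urgent on scene far more often than
B); the true frequencies of individual treatment criteria (uniform over
applicable rules by default); timestamps, geography, crew or seasonal
structure. Passing tests therefore demonstrate the pipeline's correctness
and its statistical behaviour under the profiled composition — not
calibration of any real dispatch protocol.

Because category counts are multinomial, the smallest profiled category
(Cardiac arrest, 51 of 6153) has an expected synthetic count of ≈ 53 at
the default scale and clears the >50 eligibility bar only at some seeds;
analyses that need all 26 categories eligible (e.g. checking the
Kruskal–Wallis df of 25) use a larger register — the tests use 25 000
dispatches, where the smallest expected count is ≈ 183 and eligibility of
all 26 is near-certain.

## Numerical and degenerate-input choices

* Malformed CSV rows are retained with status `invalid_data` and a parse
  report (row, field, reason), then excluded like any other non-analysed
  mission — the exclusion count stays auditable; only a missing mandatory
  column or an unreadable file errors.
* An empty analysed set is an error ("no analysable dispatches"), not an
  empty report.
* Confusion cells are validated non-negative integers; metrics on an
  all-zero matrix error.
* Register round-trips are bit-exact: vitals are written with the shortest
  decimal representation that parses back to the identical double.
* Problem sizes in the shipped tests: exhaustive classifier grids (240 and
  ~55 000 combinations), registers of 400–3000 records for property
  checks, the 7245-dispatch study scale for distributional checks, and one
  25 000-dispatch register for the all-categories-eligible analyses; the
  full suite runs in well under a minute.

## Known limitations

* The reference standard inherits the biases of its inputs: conveyance
  priority can be non-medical, paramedic documentation is voluntary and
  possibly selective, and treatment criteria ignore treatments outside the
  eight conjunctions.
* Wald intervals misbehave at very small n or extreme p (they clamp at 0
  and 100); use Wilson for category-level work with single-digit cells.
* The generator's conditional-independence assumptions (letter split and
  documentation independent of everything else given the dichotomy) are
  conveniences, not register facts.
* Category labels are matched syntactically; semantically duplicate
  categories (renamed protocols) must be harmonised upstream.
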
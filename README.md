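# emstriage

Tools for auditing emergency-medical-dispatch (EMD) telephone triage against
what ambulance crews actually find on scene.

## The problem

Finnish Emergency Response Centres assign every ambulance mission a dispatch
priority — A (suspected life threat), B (urgent), C (semi-urgent, reach
within 30 min) or D (non-urgent, within 2 h); A and B are lights-and-siren
responses. Whether those telephone assessments are right can only be judged
against the on-scene picture. `emstriage` implements that audit for
dispatch-register extracts:

* a **rule-based reference standard** that dichotomises each completed
  dispatch into *urgent* / *non-urgent* from the on-scene record — the
  paramedic's (voluntary) documented assessment first, otherwise conveyance
  priority, death on scene, and eight "significant treatment"
  condition-plus-intervention criteria (e.g. SpO2 < 95 % *and*
  bronchodilators given; CPR or airway management alone suffice);
* the **triage test-performance suite** against that standard, treating an
  urgent (A/B) dispatch as the test positive:

  | metric | definition |
  |---|---|
  | efficiency | (TP + TN) / n |
  | sensitivity | TP / (TP + FN) |
  | specificity | TN / (TN + FP) |
  | PPV, NPV | TP / (TP + FP), TN / (TN + FN) |
  | over-triage | 100 − PPV |
  | under-triage | 100 − NPV |

  each as a percentage with a 95 % binomial confidence interval (Wald by
  default, Wilson optionally);
* **per-category analysis**: summaries per dispatch category (Chest pain,
  Fall, ...), Pearson chi-square on the priority-by-urgency crosstab,
  Kruskal–Wallis on the record-level TP/FP/TN/FN consistency variable
  across categories with more than 50 dispatches, and Dunn's
  Bonferroni-corrected pairwise post hoc comparisons;
* a **seeded synthetic register generator**: real register extracts are
  restricted health data, so the package ships the aggregate profile of a
  one-month regional register (26 categories, 6153 dispatches) and
  generates record-level registers with that statistical structure. Labels
  are generated latent-first and the clinical fields constructed to satisfy
  exactly one reference-standard rule, so the classifier provably recovers
  every latent label.

Intended users: EMS quality-assurance teams, prehospital-care researchers,
and anyone validating a dispatch protocol against on-scene criteria.

## Worked example

The package ships the published 4×2 crosstab of the profiled register
(dispatcher priority × on-scene urgency for 6416 analysed dispatches), so
the headline audit reproduces at the keyboard:

```r
library(emstriage)
conf <- crosstab_to_confusion(reference_crosstab())
conf
#> <confusion_counts: TP 688, FP 1653, TN 3949, FN 126 (n = 6416)>
compute_metrics(conf)
#>         metric numerator denominator point_percent ci_low_percent ci_high_percent
#> 1   efficiency      4637        6416         72.27          71.18           73.37
#> 2  sensitivity       688         814         84.52          82.04           87.01
#> 3  specificity      3949        5602         70.49          69.30           71.69
#> 4          ppv       688        2341         29.39          27.54           31.23
#> 5          npv      3949        4075         96.91          96.38           97.44
#> 6  over_triage      1653        2341         70.61          68.77           72.46
#> 7 under_triage       126        4075          3.09           2.56            3.62
```

Reading: 72 % of dispatches got concordant urgency assessments; the
dispatcher caught 85 % of on-scene-urgent cases (sensitivity), but 71 % of
urgent dispatches were not urgent on scene (over-triage), while only 3 % of
non-urgent dispatches hid an urgent patient (under-triage).

The full pipeline on a synthetic register — generate, exclude
cancelled/aborted/invalid missions, classify, summarise — is one call:

```r
report <- run_pipeline(default_generator_config(seed = 20210801))
report$confusion
#> <confusion_counts: TP 677, FP 1584, TN 4048, FN 123 (n = 6432)>
report$tests$chi_square
#> <chi_square: statistic = 981.1, df = 3, p = 2.21e-212>
cat(render_tables(report, "text"))   # the three report tables; also "csv", "json"
```

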
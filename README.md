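# echodml

Double machine learning for echocardiogram appointment-urgency triage.

Echocardiography laboratories must decide which appointment requests to
serve within days and which can wait. An appointment is operationally
*urgent* when it takes place within two days of being scheduled. The
variables that plausibly drive urgency — administrative routing,
comorbidity flags, referral diagnoses — influence one another as well as
the outcome, so naive contrasts and regularized machine-learning fits
give biased effect estimates. `echodml` estimates each variable's effect
with cross-fitted **double machine learning (DML)** for the partially
linear model

```
Y = W θ₀ + g₀(X) + U,   E[U | W, X] = 0
W = m₀(X) + V,          E[V | X]   = 0
```

where `W` is one 0/1 design column (the treatment), `X` are the columns
of the other variable groups, and the nuisances `g₀`, `m₀` are fitted by
machine-learning classifiers on training folds and evaluated out-of-fold.
The effect estimate is the no-intercept regression of outcome residuals
on treatment residuals, `θ̂ = Σ V̂ᵢỸᵢ / Σ V̂ᵢ²`, with a sandwich standard
error, normal-reference t-value and p-value, and 95% confidence interval;
5-fold cross-fitting is repeated 10 times and aggregated by the median.

Because real scheduling data are private, the package ships a synthetic
cohort generator with the full published variable taxonomy (14
administrative variables, 29 comorbidity flags, 20 referral-diagnosis
flags) and a known confounded causal structure; every stage of the
pipeline is validated against it (parameter recovery, confidence-interval
coverage, type-I error, root-n consistency, debiasing). Seven learner
families (naive Bayes, class-weighted logistic regression, a small neural
network, decision tree, random forest, gradient boosting, linear SVM)
back both the nuisance models and a repeated-CV prediction benchmark that
compares direct classifiers with the DML-based urgency predictor.

## Worked example

```r
library(echodml)

schema <- default_schema()                      # 14/29/20 variable taxonomy
plr    <- plr_spec("Mets", theta0 = 0.5,        # planted effect on the Mets flag
                   target_prevalence = 0.2, n_records = 3000, seed = 7)
cohort <- generate_cohort(schema, plr) |> label_urgency()
design <- encode_dummies(cohort)
design
#> <urgency_design> 3000 rows, 99 columns (administration: 50, comorbidity: 29, referral: 20)
#>   outcome: urgent (prevalence 0.193)

fits <- estimate_effects(design, "comorbidity",
                         learner = learner_spec("gradient_boosting",
                                                n_trees = 60, learn_rate = 0.2),
                         plan = crossfit_plan(n_folds = 5, n_repetitions = 2,
                                              seed = 7))
report <- build_effect_report(fits)
report
#> <effect_report> 2 of 29 treatments significant at p < 0.05
#>   comorbidity: 2
head(report$significant[, c("treatment", "estimate", "std.error",
                            "statistic", "p.value")])
#> # A tibble: 2 × 5
#>   treatment estimate std.error statistic   p.value
#>   <chr>        <dbl>     <dbl>     <dbl>     <dbl>
#> 1 Mets        0.159     0.0407      3.91 0.0000923
#> 2 PHTN       -0.0884    0.0244     -3.62 0.000299
```

The planted treatment (`Mets`, metastatic cancer) is recovered as the
top-ranked significant effect. Its coefficient, 0.159, is on the
*probability scale* of the binary urgency outcome: carrying the flag
raises the urgent probability by about 16 percentage points at these
settings (the planted 0.5 is on the latent score scale; the thresholded
outcome compresses it). `PHTN` appears through its correlation with the
nuisance structure at this sample size and illustrates why the full
table, not only the significant view, should be read.

`autoplot(fits)` draws the forest plot of effects with CI whiskers;
`run_dml_benchmark(design, default_learners(), group = "comorbidity")`
produces the 8-row accuracy/precision/recall/F1 comparison table;
`tidy()` and `glance()` work on fitted objects. A command-line interface
wrapping the same functions ships in `inst/cli/echodml`
(`simulate`, `estimate`, `benchmark`, `report` subcommands).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's main pipeline from scratch: it simulates a
default-schema cohort at the given seed, labels urgency with the two-day
rule, dummy-codes the design, estimates all 29 comorbidity effects with
cross-fitted gradient-boosting DML, and writes the significance-ranked
effect tables next to the JSON report.

## Layout

- `R/` — schema + synthetic cohort generator, dummy-coding and treatment
  partitioning, learner adapters (with in-package tree / forest /
  boosting / MLP / SVM engines), the DML core, benchmark and reporting,
  plots, CLI.
- `vignettes/methods.Rmd` — model, assumptions, generator design,
  numerical choices, known limitations.
- `inst/extdata/default-config.yaml` — every tunable default, pinned.
- `tests/testthat/` — unit, property and acceptance tiers.
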
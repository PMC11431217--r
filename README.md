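# heatvalid

Validation machinery for ICD-10 **case-finding algorithms for acute heat
illness (AHI)** in emergency-department (ED) administrative data.

Administrative ICD-10 codes are assigned for billing, and their accuracy for
surveillance of heat-related illness is not a given. The standard way to
quantify it is a chart-review validation study: define a code set, define a
gold standard on the clinical record, sample charts, and estimate the
algorithm's operating characteristics. `heatvalid` implements that study as
a reusable, tested pipeline:

* **Code-set matching** — normalized ICD-10 codes with category-prefix
  capture (`N17` matches `N170`–`N179`); the bundled AHI algorithm has 23
  include codes (X30, X32, T670–T679, E860/E868, N17, R508/R509,
  M628/T296/G210, E87/E875, R55) and documents W92 (man-made heat) as
  excluded.
* **Gold standard** — a chart is AHI-positive iff it documents
  patient-reported heat exposure **and** ≥ 1 heat-related complaint.
* **Two-stage sampling** — PPV from an enriched random sample of
  algorithm-positive charts; sensitivity, specificity and NPV from an
  independent random sample of the whole coded cohort, cross-classified
  into a 2×2 table (TP/FP/FN/TN). The stages are never pooled.
* **Inference** — for each proportion `p̂ = k/n`, the Wald interval
  `p̂ ± z·√(p̂(1−p̂)/n)` and the continuity-corrected Wilson score interval
  (bounds solving `|p̂ − p| − 1/(2n) = z·√(p(1−p)/n)`), both always
  reported; unweighted Cohen's kappa `(p_o − p_e)/(1 − p_e)` from duplicate
  abstraction; closed-form sample sizes
  `n = ⌈z²P(1−P)/d²⌉` (PPV) and the prevalence-inflated Sn/Sp versions.
* **Temperature-day classification** — fixed Ontario heat-warning bands
  (< 20 °C cool, ≥ 31 °C hot) or per-year quartile bands.
* **Synthetic cohort generator** — encounters with latent AHI truth,
  imperfect coding and documentation, demographics, and per-year
  May–September daily maximum temperatures, fully seed-deterministic, so
  the pipeline runs without any real health records.

## Worked example

Closed-form pieces first — the worked 2×2 example (1 true positive, 0 false
positives, 3 false negatives, 960 true negatives) and the planning formulas:

```r
library(heatvalid)

metrics_from_table(two_by_two(tp = 1, fp = 0, fn = 3, tn = 960))
#> sensitivity specificity         ppv         npv
#>   0.2500000   1.0000000   1.0000000   0.9968847

wald_interval(1, 4)
#> <proportion_estimate> wald, n = 4
#>   25.0% ± 42.4% (95% CI: 0.0% to 67.4%)

sample_size_ppv(0.80, 0.10)$n_required      # stage-A size
#> [1] 62
sample_size_sn_sp(0.40, 0.90, 0.10, 0.10)$n_required
#> [1] 922
```

The full synthetic study — generate a five-summer cohort of 326,702
encounters at the default calibration, then run the two-stage design
(62 algorithm-positive charts for PPV, 964 random charts for Sn/Sp/NPV,
20% duplicate abstraction):

```r
cfg    <- generator_config(seed = 1)
cohort <- generate_cohort(cfg)
report <- run_validation_study(
  cohort$encounters, reviews_from_cohort(cohort$encounters),
  study_design(seed = 1), weather = cohort$weather
)
report
#> == Validation of coding algorithm 'ahi' ==
#> Cohort: 326702 encounters; 202 algorithm-positive (0.06%)
#> Stage A (PPV): n = 62, gold-positive = 34
#> Stage B (Sn/Sp/NPV): n = 964; 2x2 [tp 0, fp 0, fn 2, tn 962]
#>   ppv         [wald     ] 54.8% (42.5% to 67.2%)
#>   ppv         [wilson_cc] 54.8% (41.8% to 67.3%)
#>   sensitivity [wald     ] 0.0% (0.0% to 0.0%)
#>   sensitivity [wilson_cc] 0.0% (0.0% to 80.2%)
#>   specificity [wald     ] 100.0% (100.0% to 100.0%)
#>   specificity [wilson_cc] 100.0% (99.5% to 100.0%)
#>   npv         [wald     ] 99.8% (99.5% to 100.0%)
#>   npv         [wilson_cc] 99.8% (99.2% to 100.0%)
#> Inter-rater kappa: -0.03 on 193 duplicated pairs
#> Strata: stratified validity suppressed: no gold-standard positives in hot days
```

Reading this: 0.06% of encounters are algorithm-positive, so PPV needs the
enriched stage-A sample (here 34/62 ≈ 55% of flagged charts are true AHI).
In the 964-chart random sample the algorithm missed both gold-standard
cases (estimated Sn 0%, with a Wilson upper bound of 80% — a 964-chart
sample simply cannot pin down the sensitivity of a condition this rare),
while specificity and NPV are essentially 1. The kappa near 0 despite
reviewers with 98% per-chart accuracy, and the suppressed temperature
strata, are honest features of rare-outcome validation — see the methods
vignette (`vignettes/validating-heat-illness-codes.Rmd`).

`write_validity_report(report, "out/")` writes `report.txt`, `report.csv`,
`two_by_two.csv` and `strata.csv`. A thin command-line wrapper with
`simulate`, `match`, `validate`, `samplesize` and `stats` subcommands lives
at `inst/cli/heatvalid-cli.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the pipeline from scratch at the given seed: the worked 2×2
metrics, the printed interval half-widths, both sample-size plans, and the
full synthetic-cohort two-stage validation study, then writes the results
JSON to `--out`.
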
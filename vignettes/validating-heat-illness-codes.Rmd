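---
title: "Validating an ICD-10 coding algorithm for acute heat illness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating an ICD-10 coding algorithm for acute heat illness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatvalid)
```

## The problem

Acute heat illness (AHI) — heat stroke, heat exhaustion, heat syncope,
dehydration — brings patients to emergency departments (EDs), and its burden
is expected to grow with climate warming. Population-level surveillance
usually has to rely on administrative ICD-10 diagnosis codes, which are
assigned by hospital coders for billing, not surveillance. Before such codes
can be trusted in research, their operating characteristics against the
clinical record — positive and negative predictive value (PPV, NPV),
sensitivity (Sn) and specificity (Sp) — must be measured in a chart-review
validation study.

`heatvalid` implements the full machinery of such a study, together with a
synthetic ED cohort generator, so the entire pipeline can be developed,
tested and calibrated without access to real health records.

## The coding algorithm

The bundled AHI algorithm (`ahi_code_set()`) contains 23 include entries:
direct heat codes (X30 exposure to excessive natural heat, X32 exposure to
sunlight, T670–T679 heat illness), and "expanded" consequence codes
(E860/E868 volume depletion, N17 acute kidney injury, R508/R509 fever,
M628/T296/G210 rhabdomyolysis, E87/E875 electrolyte disorders, R55 syncope
and collapse). W92 — excessive heat of man-made origin, such as saunas or
industrial sources — is recorded as *excluded*: the algorithm targets
environmentally caused illness.

Three matching decisions deserve explanation:

* **Category-prefix capture.** The include list mixes three-character
  categories (N17, E87, R55) with four-character codes (T670). Administrative
  records code at variable specificity, so an include entry matches any code
  it prefixes: N17 captures N170–N179. Whether the original study matched
  exact codes or categories is not decidable from the published material;
  prefix capture is this package's documented choice, and the matcher is
  property-tested against a brute-force prefix oracle.
* **W92 does not veto.** A chart carrying both W92 and an include code is
  still algorithm-positive: the code was left out of the algorithm, not given
  negating force.
* **E87/E875 redundancy.** E875 is a prefix-child of E87; both are retained
  verbatim from the source table. Matching is unaffected.

## The gold standard

A chart is gold-standard positive when it documents **both**
patient-reported exposure to heat **and** at least one heat-related
complaint. The complaint list is clinically open-ended; for testability the
package ships a closed default vocabulary (syncope, heat stroke, loss of
consciousness, muscle cramps, pain, exhaustion, fatigue, edema), extensible
via `read_complaint_vocabulary()` or a user-supplied vector. Unknown terms
are an error rather than a silent non-match, so vocabulary drift surfaces
immediately. `label_chart()` is monotone in both conjuncts.

## The two-stage design

Algorithm positivity is rare (on the order of 0.06% of coded ED encounters),
so a single random sample cannot estimate PPV: a 964-chart random sample
would be expected to contain fewer than one algorithm-positive chart.
`run_validation_study()` therefore uses two independent simple random
samples:

* **Stage A** draws `n_ppv_sample` (default 62) charts *from the
  algorithm-positive stratum*; the fraction meeting the gold standard is the
  PPV. Nothing else is estimated here.
* **Stage B** draws `n_random_sample` (default 964) charts from the whole
  coded cohort and cross-classifies algorithm positivity against the gold
  standard into a 2×2 table, giving Sn, Sp and NPV. PPV is never computed
  from stage B, and the two stages are never pooled — pooling an enriched
  and a random sample would bias every metric.

The two draws are independent and overlap is permitted (whether the original
study excluded stage-A charts from stage B is unstated; independent draws
are the simpler and self-consistent default). A configurable fraction
(default 20%) of stage-B charts is abstracted in duplicate for the
inter-rater kappa.

## Interval estimation: two methods, both reported

Published validation studies conventionally present estimates as
"point ± half-width", which is the Wald interval
$\hat p \pm z_{1-\alpha/2}\sqrt{\hat p(1-\hat p)/n}$. For proportions near 0
or 1 — exactly the regime of a highly specific algorithm — the Wald interval
degenerates (±0.0% at $\hat p = 1$). The continuity-corrected Wilson score
interval, whose bounds solve
$|\hat p - p| - \tfrac{1}{2n} = z\sqrt{p(1-p)/n}$, does not collapse and
always contains $\hat p$.

The package implements **both** (`wald_interval()`, `wilson_cc_interval()`)
and reports always carry both, labeled by method: the Wald column reproduces
the conventional ± presentation, the Wilson column is the better inferential
summary. The Wilson closed form is verified against an independent bisection
solver of the score equations to $10^{-6}$ over the full grid $k \le n \le 50$.
By convention the lower bound is 0 at $k = 0$ and the upper bound 1 at
$k = n$. The $z$ quantile is always computed from the normal distribution at
the configured confidence level, never hard-coded.

```{r intervals}
wald_interval(1, 4)        # Sn of 1 detected among 4 true cases
wilson_cc_interval(1, 4)
```

## Inter-rater agreement

`cohen_kappa()` computes the unweighted two-rater, two-category kappa
$(p_o - p_e)/(1 - p_e)$. When both reviewers assign one identical label to
every chart, $p_e = 1$ and kappa is undefined — the function errors rather
than returning a conventional value, and the study report records the
suppression. This matters in practice: with a gold-standard prevalence of a
few per thousand, a 193-pair duplicate subset frequently contains no
positives at all. A consequence worth stating plainly: with rare positive
labels, kappa is harshly chance-corrected, so even reviewers with 98%
per-chart accuracy (the generator's default `reviewer_flip_prob = 0.02`)
can produce kappa far below the "excellent agreement" range on an
almost-all-negative subset. A published kappa of ~0.9 cannot be reproduced
or checked without the underlying agreement table, which is not available;
the package therefore treats kappa as an output of the pipeline, not a
calibration target.

## Sample-size planning

`sample_size_ppv()` implements $n = \lceil z^2 P(1-P)/d^2 \rceil$ for a
proportion estimated to precision $d$; with $P = 0.80$, $d = 0.10$, 95%
confidence it gives 62 — the stage-A size. For sensitivity and specificity
the denominators come only from true cases and non-cases respectively, so
`sample_size_sn_sp()` inflates by prevalence:
$n_{Sn} = \lceil z^2 Sn(1-Sn)/(d^2\,prev) \rceil$,
$n_{Sp} = \lceil z^2 Sp(1-Sp)/(d^2(1-prev)) \rceil$, reporting both
components and their maximum. With the planning inputs
$Sn = 0.40, Sp = 0.90, prev = 0.10, d = 0.10$ the formulas give
$n_{Sn} = 922$ and $n_{Sp} = 39$. (The planning table this design mirrors
prints a total of 931 for these inputs; that value does not follow from the
cited formulas, which give 922 — the package reports the formula value, and
the test suite asserts 922 against an independent re-derivation.) Ceiling,
not rounding, is used throughout, and both components are always reported
because a single "total" hides which constraint binds.

## The synthetic world

`generator_config()` defines a stated world; the defaults are fixed once and
are not tuning knobs.

| parameter | default | meaning |
|---|---|---|
| `n_encounters` | 326,702 | May–September ED encounters, 2014–2018, two sites |
| `p_true_ahi` | 0.00156 | latent true-AHI prevalence (derivation below) |
| `p_algo_code_given_ahi` | 0.25 | latent coding sensitivity |
| `p_algo_code_given_not_ahi` | 0.000247 | latent false-positive coding rate |
| `p_exposure_documented_given_ahi` | 1 | exposure documentation among true cases |
| `p_complaint_documented_given_ahi` | 1 | complaint documentation among true cases |
| `p_exposure_documented_given_not_ahi` | 0 | spurious exposure documentation |
| `p_complaint_documented_given_not_ahi` | 0.3 | heat-type complaints among non-cases |
| `temp_link_beta` | 0 | log-odds of AHI per °C above the yearly median |

**Calibration and its one unavoidable conflict.** The study being emulated
prints four anchors: cohort positivity 0.06%, PPV 61.3%, Sn 25%, and 4
gold-standard positives among 964 random charts (prevalence ≈ 0.41%). These
four are *jointly infeasible* in any generating model: positivity × PPV =
prevalence × Sn, and inserting the printed positivity, Sn, and a prevalence
of 0.41% forces a PPV above 1. The defaults therefore anchor on the three
estimator-level results — positivity, Sn and PPV — which imply
`p_true_ahi` = 0.0006366 × 0.613 / 0.25 ≈ 0.00156 and a false-positive
coding rate of ≈ 0.000247. Under this world a 964-chart random sample
contains on average ~1.5 gold positives; the observed 4 is then an upward
sampling fluctuation (probability of ≥4 is about 7%), which is the reading
the generator adopts. No parameter was moved after observing test results.

**Documentation defaults.** Documentation probabilities for true cases
default to 1, i.e. the gold standard coincides with latent truth — mirroring
how a validation study must treat its reference standard. Lower values model
incomplete charting; they leave the estimated Sn unbiased for
`p_algo_code_given_ahi` (coding and documentation are independent given
truth) but shrink PPV, which is why they are not part of the calibrated
default.

**Temperature.** Only a median and IQR per season are available, so daily
maxima are drawn from a normal location–scale family with scale
IQR/1.349 (the normal IQR-to-SD ratio) — the minimal two-parameter family
matching both anchors. Values are rounded to 0.1 °C as a weather station
would report. A logistic temperature link for AHI risk is available
(`temp_link_beta`) but off by default: the emulated study observed that true
cases fell on moderate and hot days but quantified no dose–response, so the
default world does not invent one.

**Demographics** (age, sex, triage level, disposition) are drawn from
marginal frequencies of a large ED population; they are cosmetic, never
verified statistically, and carry no dependence on case status.

**Determinism.** One master seed; every component (weather, dates, truth,
coding, codes, demographics, documentation, each sampling stage, duplicate
abstraction) derives its own substream, so adding a field never perturbs
earlier draws and `simulate` + `validate` is byte-reproducible end to end.

What a green suite does *not* establish: the generator has no ICD
co-morbidity structure, no free-text triage notes, no multi-site
heterogeneity, and independence assumptions (coding ⟂ documentation given
truth) that real charts may violate. Green tests certify the statistical
machinery and the stated world, not the validity of any real-world code set.

## Day classification

Two schemes are provided:

* **Fixed thresholds** (`classify_day_fixed()`): hot ≥ 31 °C (the Ontario
  heat-warning threshold), cool < 20 °C, moderate otherwise. The verbal
  definition ("20–30 °C" vs "≥ 31 °C") leaves 30–31 °C unassigned; the
  package assigns [20, 31) to moderate so that every temperature has exactly
  one class.
* **Per-year quartiles** (`classify_days_quartile()`): within each year,
  days below Q1 are cool, above Q3 hot, and the closed interval [Q1, Q3]
  moderate (boundary days are moderate, following the wording "between the
  first and third quartile"). Quartiles use linear interpolation between
  order statistics (`quantile()` type 7), documented because the source
  specifies none.

Stratified validity (per day class) is computed only when every stratum
contains at least one gold-standard positive; otherwise the report records
the suppression explicitly — with a handful of true cases, stratified
estimates would be vacuous or undefined, and the honest output is "not
estimable".

## Numerical and degenerate-input choices

* Display rounding: percentages to one decimal (two for cohort positivity),
  round-half-even via base `round()`; all computation at full precision.
* A metric whose denominator is zero raises an error naming the metric;
  it is never reported as 0.
* `sample.int`-based sampling without replacement everywhere; stage-A
  sampling indexes the positive stratum directly so a single-positive
  cohort cannot trigger R's scalar-`sample()` pitfall.
* Sample sizes are kept as doubles: degenerate prevalence inputs can
  legitimately exceed integer range.
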
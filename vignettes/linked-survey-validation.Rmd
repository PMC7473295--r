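---
title: "Validating survey-reported chronic conditions against linked health records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating survey-reported chronic conditions against linked health records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenolink)
```

## The problem and the model

Self-reported survey answers about chronic conditions are cheap and widely
collected, but of unknown reliability. When survey records are linked at the
person level to coded clinical data — GP events carrying Read codes and
hospital episodes carrying ICD-10 codes — the clinical record can serve as a
gold standard (methodological triangulation) and the survey instrument can
be validated condition by condition.

The procedure `phenolink` implements:

1. **Linkage.** All linked survey respondents form a single "platform"
   record set; respondents without any clinical event are retained (they are
   informative true negatives). Respondents who could not be assigned a
   linkage identifier are removed up front; fuzzy (lower-confidence) matches
   are retained by default to maximise the sample, with `drop_fuzzy` as a
   sensitivity analysis.
2. **Phenotyping.** For each condition a code set defines diagnosis (ICD-10),
   GP event (Read) and optionally medication (Read) codes. A person is a
   clinical case when at least one record matches inside the ascertainment
   window. The window rule mirrors the survey wording: *ever been treated*
   questions use the full lookback; *currently being treated* questions use
   the 12 calendar months before the interview.
3. **Validation.** Survey answers (yes / no / no-answer) are crossed with
   clinical status into a 2×2 over valid responses; sensitivity, specificity,
   PPV, NPV, Cohen's kappa, prevalence per 1,000 with binomial confidence
   intervals, and item non-response rates are reported.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `icd_prefix_matching` | `TRUE` | ICD-10 category entries (`J45`) match subdivisions (`J45.9`), dot-insensitively. Hospital data carry 4-character codes while code lists are often at category level; exact mode is available. Read codes always match exactly (Read v2 semantics, trailing-dot padding normalized). |
| `min_gp_events` | 1 | qualifying GP events needed for GP-route ascertainment. A single record from either source defines a case by default; `2` gives the stricter two-GP-visits-or-one-hospitalisation definition. One hospital episode always suffices. |
| window | per condition | `CURRENT_12M` is a closed interval `[interview − 12 months, interview]`: interview-day and boundary-day events count. Month subtraction is calendar-exact with day-of-month clamped at month end (Mar 31 − 12 m → Mar 31; Mar 31 − 1 m → Feb 28/29). |
| lookback floors | GP 2010-01-01, hospital 2002-01-01 | `EVER` windows are bounded below by each source's data start — an honest emulation of finite lookback, configurable. |
| `ci_method` | `"wald"` | `p ± 1.96·sqrt(p(1−p)/n)`, bounds per 1,000 rounded to integers. Wilson is available and preferable near 0. |
| `prevalence_denominator_policy` | `"all_matched"` | prevalence uses all matched respondents, non-responders included; `"valid_only"` restricts to valid responses. |
| `clinical_numerator_policy` | `"contingency"` | clinical prevalence counts clinical positives among valid responders (`TP+FN`); `"all_identified"` counts every ascertained case, including non-responders to the survey item. Published practice is internally inconsistent between these two definitions, so both are first-class and the report records which was used. |
| `gp_coverage` | 0.8 | fraction of GP practices contributing data, used by the undercount estimator `floor(gp_only × (1/coverage − 1))`. |

## What the synthetic generator emulates — and what it does not

`generate_cohort()` states a world of ~11,323 adults interviewed over a
21-month window (2013-04-01 to 2014-12-31), with the linked sample's
age-by-gender structure as default demographic marginals, 80% GP-practice
coverage, and per-condition blocks: latent true status at `true_prevalence`;
survey answers with misreporting (`survey_sensitivity`,
`survey_specificity` — specificity below 1 captures over-reporting via
recall/telescoping); item non-response applied after the yes/no draw,
independent of status; and clinical records for true cases at
`p_record_gp` / `p_record_hospital`, dated inside the 12-month window with
probability `p_in_window`. Default condition parameters describe an
asthma-like condition (prevalence 0.105, sensitivity 0.70, specificity 0.96,
non-response 0.05, GP recording 0.90, hospital 0.15, in-window 0.90) —
chosen once from the observed asthma validation structure and not tuned.
Latent status is independent across conditions by default (no comorbidity
structure is asserted); `condition_correlation` adds a shared Gaussian
factor if wanted. Dates are uniform within their legal ranges — no
seasonality, no repeat-prescription rhythm, no practice-level clustering
beyond the coverage flag.

A green test on generated data therefore establishes that the pipeline's
*logic* is correct under the stated world — not that real survey respondents
behave like the generator (selection into consent, intentional non-response
correlated with status, and coding-practice drift are all outside it).

`plant_contingency()` is the sharper tool: it manufactures a cohort whose
pipeline output reproduces a specified 2×2 *exactly* — clinical positives
get at least one in-window matching record, negatives none, while decoy
records (out-of-window matches, in-window non-matching codes) are sprinkled
in and must not flip anyone. Published tables sometimes count clinical
positives among item non-responders (a clinical total exceeding `TP+FN`);
`no_answer_cases` plants exactly that surplus, which is what lets one cohort
reproduce a source-attribution table and its contingency table
simultaneously.

## Numerical choices

* **Rounding.** Printed-table reproduction uses round-half-away-from-zero,
  not banker's rounding; percentages print at 2 decimals with trailing zeros
  trimmed (`97.00` → `"97"`), while underlying values stay at full precision.
* **Undercount floor.** `floor(x + 1e-9)`: in floating point
  `32 × (1/0.8 − 1)` can land a hair below 8, and the epsilon guards the
  floor without changing the rule.
* **Undefined statistics.** A metric with a zero denominator is `NA` and
  flagged (never silently zero); kappa is `NA` when chance agreement is 1.
* **Confidence intervals.** Wald with `z = qnorm(0.975)`; bounds clamped to
  `[0, 1000]` per 1,000. One published survey CI pair (heart failure,
  191/11,323 → printed lower bound 15) is *not* the Wald interval (which
  gives 14.497 → 14) but is the Wilson bound; it is not asserted in tests,
  and Wilson is available behind `ci_method`.
* **Ties and order.** Generated tables are sorted on stable keys so equal
  seeds give byte-identical CSVs.

## Known limitations

* Shipped code lists are illustrative; every quantitative check is designed
  to be independent of the particular codes chosen.
* Probabilistic record linkage itself is out of scope — the pipeline starts
  from already-linked identifiers.
* The coverage-undercount estimator assumes non-contributing practices would
  contribute GP-only cases at the observed rate; the published "six to eight
  cases higher" range for cardiovascular conditions is not exactly the floor
  rule's output at its lower end (21 × 0.25 = 5.25), and only the floor rule
  is asserted.
* No survey weighting or design effects: estimates are unweighted counts
  over linked respondents, matching the validation design.
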
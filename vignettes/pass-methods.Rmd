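---
title: "The PASS score: model, validation machinery, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The PASS score: model, validation machinery, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(passdx)
```

## The diagnostic problem

Acquired aplastic anemia (AA) is an immune-mediated bone marrow failure
that demands urgent immunosuppression or transplant, yet it is a diagnosis
of exclusion: inherited bone marrow failure syndromes (IBMFS) — telomere
biology disorders, Fanconi anemia, Diamond–Blackfan anemia, GATA2
deficiency and others — can present identically in adults but respond
poorly to AA-directed therapy and tolerate standard transplant
conditioning badly. Genetic testing resolves the question but is slow,
not universally available, and often inconclusive. The Predictive
Aplastic Score System (PASS) addresses this with seven clinical factors
that are available at or shortly after presentation.

## The score

PASS is an additive integer score over seven factors; every attainable
total is a multiple of 10 in $[-70, 80]$:

| # | Factor | Points |
|---|--------|--------|
| 1 | Cytopenia severity | +20 if severe (SAA/VSAA), 0 if non-severe |
| 2 | Acuity (cytopenia duration) | +10 if ≤ 1 year; −10 if chronic and severe; −20 if chronic and non-severe |
| 3 | Age | +10 if ≥ 60 years; 0 if < 60 and severe; −10 if < 60 and non-severe |
| 4 | IBMFS red flags | −20 if any present; +10 if none |
| 5 | AA-associated conditions | +10 if any present; 0 otherwise |
| 6 | AA-associated somatic change | +20 if present; 0 if absent or unknown |
| 7 | Lymphocyte telomere length | −20 if < 1st percentile for age; 0 otherwise or unknown |

Severity follows the modified Camitta criteria: severe means two or more
of ANC < 0.5, reticulocytes < 60, platelets < 20 (all ×10³/µL). Factors
1–5 are required; the somatic and telomere factors are optional
refinements that contribute 0 when untested, so the score can be computed
at the bedside and re-computed as laboratory results arrive. Totals
stratify patients into three tiers: ≥ 30 high-confidence AA, 0–20
intermediate, < 0 likely IBMFS.

```{r worked}
p <- pass_patient("non_severe", "acute", age_years = 45,
                  red_flags = FALSE, aa_condition = FALSE,
                  somatic = somatic_from_markers(pnh_clone_pct = 6),
                  tl_lt_1st = "unknown")
compute_pass(p)[, c("total", "tier")]
p$tl_lt_1st <- "short"
compute_pass(p)[, c("total", "tier")]
```

This is the published worked example: with telomere length unavailable a
patient with acute non-severe cytopenias, no red flags and a 6% PNH clone
scores 30 (high-confidence AA); incorporating a < 1st percentile telomere
length moves the total to 10, correctly flagging diagnostic uncertainty
in a patient who carried a *TERT* variant.

### Decisions at the schema's edges

The point legend leaves a few boundaries open; the package fixes them as
follows and treats them as part of the score definition:

* age exactly 60 earns the older-age points ("60 years and older");
* duration exactly 1.0 year is acute ("1 year or less");
* SAA and VSAA are a single severe class — they carry identical points;
* the reticulocyte severity criterion defaults to ARC < 60 alone, because
  evaluable cohorts reliably report ARC but not always an anemia flag; an
  explicit `anemic` flag gates the criterion when supplied, and
  `strict_anemia = TRUE` requires it;
* the PNH clone threshold defaults to ≥ 0.5%; `sensitive_pnh = TRUE`
  counts any detectable clone, an opt-in because very small clones occur
  in healthy individuals and in rare IBMFS patients;
* unknown somatic or telomere status scores 0; missing *required* factors
  are an error in strict mode, and in lenient mode are scored as absence
  of abnormal findings (non-severe, acute, no red flags, no AA-associated
  condition) with a warning — the policy used when scoring retrospective
  external cohorts. Age must always be present.

## Validation machinery

The evaluation module carries the full statistics used to validate a
diagnostic score on a labeled cohort:

* **Discrimination.** `roc_auc_delong()` computes the midrank
  Mann–Whitney AUC with DeLong's nonparametric variance and a Wald 95% CI
  truncated to $[0, 1]$. Midranks matter here: PASS totals are multiples
  of 10, so ties are pervasive. `delong_paired_test()` compares two
  correlated AUCs on the same patients through the paired DeLong
  covariance, referred to $\chi^2_1$.
* **Calibration.** `calibrate_and_test()` refits outcome on score by
  univariate logistic regression, reports the Brier score of the fitted
  probabilities, a binned calibration table, and the Hosmer–Lemeshow
  statistic over deciles of predicted probability (duplicate quantile
  boundaries are merged; df = bins − 2; fewer than 3 distinct bins yields
  a flagged `NA` p-value rather than a fabricated one). Quasi-separation
  is reported via `converged = FALSE` instead of failing.
* **Thresholds.** `threshold_sweep()` computes sensitivity, specificity,
  PPV for AA (score ≥ t) and the IBMFS yield below threshold at every
  cut-off; empty strata give `NA`, never a coerced 0 or 1, and the
  confusion counts always accompany the rates.
* **Group comparisons.** `contingency_stats()` reports the cross-product
  odds ratio with the Woolf logit interval
  $\exp(\ln\text{OR} \pm 1.96\,\sqrt{1/a+1/b+1/c+1/d})$, the
  Haldane–Anscombe +0.5 correction when a cell is zero, and the two-sided
  Fisher exact p-value. The 1.96 multiplier is used literally (not
  qnorm(0.975)) — this reproduces the published intervals to printed
  precision. `univariate_cohort_summary()` applies this per factor,
  counting untested somatic status as absent (the score's own
  missing-data rule) while restricting the telomere comparison to
  evaluable patients, matching the published denominators (77 AA / 39
  IBMFS).
* **Agreement.** `fleiss_kappa()` implements Fleiss' chance-corrected
  multi-rater κ from the subjects × categories count matrix, with the
  all-one-category degeneracy flagged as undefined.

## Re-deriving the score

`derive_score_map()` reruns the derivation pipeline on any labeled
cohort: the seven factors are coded as 0/1 indicators of the AA- or
IBMFS-associated level (unknown → 0), an L1-penalized logistic regression
is fit along a path of 100 log-spaced penalties from $\lambda_{max}$
(the smallest penalty that zeroes every slope) down to
$10^{-4}\lambda_{max}$, and the penalty is chosen by stratified 10-fold
cross-validated minimum mean binomial deviance with a mandatory seed.
Features are deliberately not standardized: they are comparable binary
indicators, and unstandardized coefficients convert directly to points.
The path and CV computations are performed by glmnet; the suite verifies
each returned solution against the L1 subgradient (KKT) conditions at
tolerance $10^{-6}$ and against the unpenalized `glm()` fit as
$\lambda \to 0$.

`coefficients_to_points()` maps a coefficient to
$\mathrm{sign}(\beta)\times 20$ when $|\beta|$ reaches the magnitude
cut-off (default 2) and $\pm 10$ otherwise. Two things are known not to
be mechanically derivable from main-effect coefficients and are therefore
configuration rather than output: the severity-conditional acuity/age
points of the published schema, and the +20 somatic weight (its published
coefficient, 1.217, sits below any cut-off that still gives severity
+20). The conversion rule is exposed so users can audit exactly where
clinical judgment supplemented the regression.

"Support recovery" in the tests means the cross-validation-selected model
retains every truly active coefficient (nonzero at $\lambda_{min}$),
mirroring how the minimum-deviance criterion behaves — it controls
prediction error, not exact support; expecting noise coefficients to be
exactly zero at $\lambda_{min}$ would test a property lasso does not
have.

## The synthetic cohort generator

`generate_cohort()` emulates the 212-adult training cohort (76.4% AA).
The diagnosis is sampled first; the seven factors are then sampled
independently given the class at the published class-conditional
prevalences (AA: severe 79.6%, acute 88.3%, age ≥ 60 38.9%, red flags
3.7%, AA-associated conditions 6.2%, somatic changes 52.5%, short
telomeres 2.6% of evaluable; IBMFS: 8.0%, 16.0%, 22.0%, 90.0%, 0%, 2.0%,
56.4%); finally the somatic and telomere factors are masked to unknown at
per-class missingness rates. Telomere missingness uses the published
unavailability (85/162 AA, 11/50 IBMFS). For the somatic composite only
per-marker availability is published, and the rates differ by marker; the
generator uses PNH-flow availability (11/162 AA, 34/50 IBMFS untested) as
the default because PNH flow cytometry is the primary somatic screen.
Continuous ages are drawn uniformly within the band implied by the age
indicator (18–60 / 60–87, the published range).

What the generator does **not** emulate: correlations between factors
(only marginals are published — severity and acuity are certainly
correlated in real patients; a correlation hook was considered and left
out rather than invent a joint structure), cohort-specific referral
patterns, secular trends, and rater noise. Tests passing on these
cohorts therefore demonstrate that the score and the statistics behave
correctly under the published marginal structure, not that the package
reproduces the real cohorts' joint performance (AUC 0.990 training /
0.977 combined validation); those numbers require the patient-level data.
On default-specification cohorts of n = 5000 the score achieves AUC
≥ 0.95 with PPV for AA ≥ 0.98 at score ≥ 30, confirming that the
published prevalences alone already separate the classes strongly.

`training_margins_cohort()` is the deterministic counterpart: 212 pseudo
patients whose per-factor marginal counts equal the published training
cohort exactly (each factor assigned to the first k patients of its
class), so every univariate odds ratio reproduces to printed precision
end-to-end. Its joint structure is synthetic by construction and is never
used to claim cohort-level discrimination.

## Numerical and interface choices

* Problem sizes in the test-suite simulations (5 000-patient cohorts,
  100 × n = 2000 lasso replicates, 10⁴-subject κ simulation) were chosen
  as the smallest sizes at which the binomial/Monte-Carlo error is far
  below the tested tolerances.
* All randomness flows through explicit integer seeds; generation and
  cross-validation refuse to run without one.
* Undefined metrics are `NA` with counts, never silently 0 or 1.
* Display rounding follows the published tables (3 decimals for ORs, AUC
  and Brier; 1 decimal for percentages), but returned objects always
  carry full precision.
* The CSV dialect is comma-separated UTF-8 with a header; booleans
  `true`/`false`, tri-states `present`/`absent`/`unknown`, telomere
  category `short`/`not_short`/`unknown`. Either raw counts or a severity
  column, and either `duration_years` or an explicit `acuity` column, are
  accepted; the explicit column wins with a warning on conflict.

## Limitations

The package scores and validates; it does not interpret germline
variants, normalize flow-FISH telomere measurements, or reimplement the
two comparator models (a proprietary machine-learning classifier and a
recursive-partitioning rule set whose internal rules are defined
elsewhere). The score itself is validated for adults with bone marrow
failure; applying it to pediatric patients or to telomere assays other
than flow-FISH is outside its evidence base.
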
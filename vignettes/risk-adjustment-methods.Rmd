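---
title: "Methods: Elixhauser risk adjustment for internal-medicine hospitalizations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Elixhauser risk adjustment for internal-medicine hospitalizations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Internal-medicine (IM) inpatients are heterogeneous: two admissions billed
identically may differ enormously in comorbidity burden, expected length of
stay, and risk of death. Case-mix (risk) adjustment corrects for this by
scoring each hospitalization from its recorded diagnoses. `elixadjust`
implements the classic Elixhauser approach on ICD-9-CM coded data: 30
dichotomous comorbidity indicators are derived from the diagnosis codes of a
single hospitalization, and per-outcome regression models are refit to the
data at hand rather than imported as fixed weights.

Four outcomes are modeled, each separately:

* **in-hospital mortality** (logistic),
* **escalation of care** (logistic) — ICU or intermediate-care (IMCU) stay,
  mechanical ventilation, daytime BiPAP, or receipt of a vasopressor,
* **30-day readmission** (logistic), and
* **log length of stay** (ordinary least squares).

The analysis unit is the *hospitalization*, not the patient: codes recorded
during a different admission of the same patient never contribute flags, and
repeat patients may appear many times.

# Comorbidity mapping

## Code normalization and range matching

ICD-9-CM codes have a 3-digit category (with separate `V` and `E`
namespaces) and up to two sub-digits. Extracts mix dotted and undotted
forms, so codes are normalized to a namespace plus a dot-free digit string
(`"428.0"` → `4280`, `"V45.0"` → `V`/`450`).

The condition-definition table ships as a plain-text resource
(`inst/extdata/elixhauser_icd9.tsv`) with one row per condition: key,
display name, code tokens, and DRG-screen tokens. Tokens are single codes or
inclusive ranges (`428.0-428.9`). A range compiles to an interval at the
precision of its endpoints; a recorded code matches when, truncated to that
precision (or right-padded with zeros when shorter), it falls inside the
interval. Truncation is what makes a 4-digit table entry capture its
5-digit children — the standard convention for claims-based comorbidity
mapping, consistent with the definition table listing whole categories.

Two numerical choices deserve note:

* **Mixed-precision ranges.** Where a range's endpoints print at different
  precisions, the coarser endpoint is widened to the finer precision: the
  low endpoint is right-padded with `0` and the high endpoint with `9`.
  `042-044.9` becomes `[0420, 0449]`, and `495.0-505` becomes
  `[4950, 5059]`. Padding the high endpoint with `9` (rather than `0`) is
  deliberate: a bare category such as `505` denotes *all* of 505, and
  zero-padding would silently exclude `505.1`–`505.9`. The same applies to
  `V10.00-V10.9`, which must span every personal-history-of-cancer
  subdivision.
* **Matching is set up so that the compiled interval logic is provably
  equivalent to brute-force set expansion**; the test suite checks this
  equivalence against an independent enumeration oracle on 10,000 random
  codes across every shipped pattern.

## Hierarchy and DRG screen

Two severity pairs are mutually graded: if both uncomplicated and
complicated diabetes are coded, only complicated diabetes counts; if both a
solid tumor and metastatic cancer are coded, only metastatic cancer counts.
`apply_hierarchy()` is idempotent and only ever turns flags off.

The original Elixhauser scheme also screens out a comorbidity when the
hospitalization's DRG shows the condition was the principal reason for
admission (e.g. heart failure with a cardiac DRG). The screen is implemented
(`apply_drg_screen()`) but **off by default**: Israeli hospital records
carry no DRG assignment, so the default pipeline mirrors a no-DRG setting.
When enabled with missing DRGs it warns and passes flags through.

## Condition selection

`select_conditions()` fixes the design-matrix columns. The default excludes
`blood_loss_anemia`, reproducing a 29-condition analysis in which that
near-empty category (6 flags in ~56,000 hospitalizations) is removed;
`min_count` allows rarity-based exclusion but defaults to 0 so exclusions
stay explicit. One pragmatic exception: a condition with *zero* (or all)
flagged hospitalizations in the derivation set is inestimable — its
coefficient does not exist — so `run_pipeline()` drops such columns with a
message rather than failing the run.

# Outcome construction

* **Length of stay** is discharge minus admission in days with the
  fractional part kept, log-transformed with the *natural* log. The log base
  only rescales coefficients; the generator and recovery tests use the same
  base throughout. Zero-length stays are an error (undefined under the log).
* **Escalation** uses a half-open daytime window `[08:00, 20:00)` for
  BiPAP, making every timestamp unambiguous: BiPAP at night is commonly
  chronic therapy for sleep-disordered breathing, while daytime BiPAP
  proxies impending respiratory failure. The seven qualifying vasopressors
  (adrenaline, dobutamine, dopamine, milrinone, noradrenaline,
  phenylephrine, vasopressin) are compared case-insensitively after
  trimming. IMCU stays count by default (`include_imcu = TRUE`), with a
  switch because intermediate-care definitions vary between hospitals.
* **30-day readmission** is computed on calendar dates with an inclusive
  boundary (a gap of exactly 30 days counts; 31 does not), within the
  dataset only. Any subsequent admission counts, elective included. No
  censoring correction is applied for deaths or for stays discharged close
  to the end of the observation window — hospitalizations with no captured
  successor simply count as non-readmissions. This is a documented
  limitation, not an oversight: the intended use is case-mix comparison, not
  unbiased readmission-risk estimation.
* Death and escalation are **not mutually exclusive**; a patient escalated
  and then deceased counts in both models.

# Modeling and evaluation

The cohort is split 70/30 into derivation and validation sets by a simple
unstratified uniform draw (`split_sample()`), with the seed a required,
recorded argument. The derivation set gets `floor(0.7 n)` hospitalizations —
39,162 of 55,946 at the reference scale. Patients with several admissions
may straddle the split; splitting is by hospitalization, consistent with the
unit of analysis (a clustering caveat, accepted deliberately).

Logistic models are maximum-likelihood fits (IRLS via `glm`); linear models
are OLS via `lm`. Wald 95% intervals use `coefficient ± 1.96·SE` (odds-ratio
scale for logistic models via exponentiation; t-quantiles for the linear
model). No regularization and no multiple-testing adjustment are applied —
coefficient tables report raw Wald p-values with `*`/`**`/`***` stars at
0.05/0.01/0.001. Complete or quasi-complete separation (a live risk for
near-empty conditions such as AIDS/HIV) is detected from runaway estimates
(|log-odds| > 15 or SE > 10); the model is returned with
`converged = FALSE` and a warning naming the columns, never silently
repaired. An independent-optimizer test (direct likelihood maximization by
BFGS) confirms the fits on small instances.

Validation metrics always apply the *frozen* derivation coefficients — no
refitting — so a drop in fit reveals overfitting:

* **Discrimination.** The c-statistic is computed by the rank
  (Mann–Whitney) formulation with ties counted one half, which equals the
  trapezoidal area under the ROC curve; `roc_curve()` uses every distinct
  threshold with no binning. Linear fit is summarized by R², with
  validation R² defined as `1 − SSE/SST` against the validation-sample
  mean.
* **Calibration.** `hosmer_lemeshow()` sorts by predicted probability and
  cuts at decile quantiles, with tied probabilities never split across
  groups (so group sizes may be unequal — the reason observed deciles in
  practice are lopsided). The statistic is the grouped-binomial form
  `Σ (O_g − E_g)² / (E_g (1 − E_g/n_g))` on `g − 2` degrees of freedom.
  The test suite verifies the nominal type-I error rate by simulation:
  200 well-specified models at the validation-set scale (n = 16,784) must
  reject at 5% within [0.02, 0.08].

# The synthetic-hospitalization generator

No patient-level hospital data can ship with a package like this, so the
generator is a first-class module: it emits *raw* records (codes, ward
stays, timestamped treatment events, admission chains) whose statistical
structure matches what the analysis assumes, together with ground truth, so
every stage is testable end to end.

Default calibration (all overridable through `generator_config()`):

* **Prevalences** per condition as in a large IM service (hypertension 46%,
  CHF 27%, …, AIDS/HIV 16/55,946). Flags are drawn independently — the
  reference setting reports marginals only, so independence is an explicit
  modeling choice, not an observed fact — except that each severity pair is
  drawn as one multinomial split, making profiles hierarchy-consistent by
  construction while preserving both marginals.
* **Effect sizes**: the ground-truth log-odds are the natural logs of the
  reference odds-ratio table for each binary outcome; log-LOS uses the
  reference log-day betas. Keeping AIDS/HIV at its real near-zero
  prevalence deliberately exercises the separation-handling path.
* **Marginal rates**: mortality 6.9%, escalation 13%, readmission 15%. The
  intercept of each binary model is root-found (`calibrate_intercept()`,
  `uniroot` tolerance 1e-10) so the mean of `plogis(a + Xβ)` over the
  *realized* design equals the target rate exactly; observed rates then
  deviate only by Bernoulli noise.
* **Length of stay**: `log LOS = baseline + Xβ + N(0, σ)`. The baseline is
  set so the expected log-LOS equals `log(4.1)` (matching a 4.1-day median
  up to the small skew of Xβ), and σ follows the R² calibration rule
  `σ = sqrt(Var(Xβ)(1 − r²)/r²)` with `Var(Xβ)` computed analytically from
  the prevalences (including the negative covariance of the two exclusive
  pairs), so the fitted model's expected R² is 0.102 — the regime of real
  IM length-of-stay models, where comorbidities explain about 10% of
  variance.
* **Ages** from `105 − LogNormal(log 31, 0.54)` clamped to [18, 104]:
  median 74, quartiles near (61, 84), left-skewed like a real IM census.
* **Record realization.** Escalation labels are realized as one concrete
  qualifying mechanism chosen at random (ICU stay, IMCU stay, ventilation,
  daytime BiPAP, listed vasopressor); non-escalated stays get no qualifying
  event but may carry decoys — night-time BiPAP, or an infusion of a drug
  not on the vasopressor list — which must never flip a label. Readmission
  labels are realized as same-patient chains with gaps uniform on 1–30 days
  (or beyond-window decoy gaps). Diagnosis codes are sampled uniformly from
  each flagged condition's unambiguous code pool, plus Poisson(2)
  non-informative acute-care codes verified to map to no condition.
* **Determinism.** All randomness flows from the single config seed through
  a save/restore RNG scope, so identical configs give byte-identical
  output; the user's RNG state is never disturbed.

What passing tests on generator output do *not* show: real coding behavior
(up-coding, under-coding, facility-specific code preferences), correlated
comorbidity structure, seasonal admission patterns, or transfer-in/transfer-
out complexities. Recovery of generative coefficients demonstrates the
pipeline's correctness, not the clinical validity of any particular
coefficient set.

# Test problem sizes

The suite favors a few deep, parameterized checks per operation. Sizes were
chosen to make each statistical assertion comfortably powered while keeping
a full run around two to three minutes: mapper-oracle equivalence on 10,000
random codes; concordance oracle on instances up to n = 500; calibration
type-I error over 200 seeds at n = 16,784; split-stability and rate checks
at the full reference scale n = 55,946 (flag/label level); full raw-record
round trips at n = 2,000–3,000; and parameter recovery over 5 seeds at the
derivation scale n = 39,162, judged against the simulated standard error.
All stochastic assertions use 3-standard-error bounds (or the stated
acceptance bands) under fixed seeds chosen in advance.

# Known limitations

* ICD-9-CM only; no ICD-10/11 mappings, no AHRQ/Quan revisions, no van
  Walraven summary weights.
* Repeat patients are treated as independent hospitalizations (no
  mixed-effects or GEE correction) — appropriate for case-mix accounting,
  optimistic for patient-level inference.
* Readmission capture is facility-local and uncensored, as described above.
* The DRG screen is faithful to the published group lists but off by
  default and untested against a live DRG grouper.
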
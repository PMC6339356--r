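---
title: "Methods: scoring, survival machinery, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, survival machinery, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(katagiri)
```

This vignette documents the scientific and numerical choices behind the
package: the scoring rules and their edge cases, the survival machinery,
what the synthetic cohort generator does and does not emulate, and the
decisions we made where the published description of the score leaves
room.

## The modified Katagiri score

The score sums six factors assessed at the start of radiotherapy (RT):
primary tumor growth class (0/2/3), visceral or cerebral metastases
(0/1/2), laboratory category (0/1/2), ECOG performance status banded
0–2 vs 3–4 (0/1), previous chemotherapy (0/1) and multiple skeletal
metastases (0/1); totals 0–10 partition into low (≤ 3), intermediate
(4–6) and high (≥ 7) risk. Two structural properties are enforced and
tested: the partition is exhaustive over 0–10, and worsening any single
component can never lower the total or move the risk group toward low.

Age and Karnofsky Performance Status are deliberately *not* part of the
score: they are univariate analysis factors only (bands ≤ 64/≥ 65 and
10–60/70–80/90–100), and the result object has no place for them, so
they cannot leak into the total.

### Laboratory categorization

The six analytes split into two tiers by whether a derangement is
immediately life-threatening:

* abnormal tier: CRP ≥ 0.4 mg/dL, LDH ≥ 250 IU/L, albumin < 3.7 g/dL;
* critical tier: platelets < 100,000/μL, corrected calcium ≥ 10.3
  mg/dL, total bilirubin ≥ 1.4 mg/dL.

A panel is *critical* if any critical-tier threshold is crossed,
regardless of other analytes — worst-tier dominance is the only reading
consistent with the higher point value of the critical category, and it
makes the categorization order-independent and idempotent (tested
properties). Otherwise it is *abnormal* on any abnormal-tier crossing.
It is *normal* only when **all six** analytes are present, current and
within limits. Anything else is *undetermined*: a panel with five
missing analytes and one normal value cannot certify normality. An
undetermined panel is valid data — it makes the patient non-scorable
rather than raising an error. Whether such panels were treated as
normal or as unscorable in the original analyses is not documented;
we chose unscorable as the conservative reading, and it is what the
missingness machinery of the pipeline assumes.

**Corrected calcium.** The score's calcium threshold refers to
albumin-corrected calcium, but no formula is fixed by the score's
description. We use the Payne rule, standard in the clinical settings
the score comes from:

corrected = measured + 0.8 × (4.0 − albumin [g/dL]), applied only when
albumin < 4.0.

No downward correction is applied at high albumin, so the corrected
value is never below the measured one — conservative with respect to
the ≥ 10.3 mg/dL threshold. With albumin missing, the measured calcium
is compared as-is (and annotated `uncorrected`); since a missing albumin
already blocks the *normal* category, this choice can only affect the
abnormal/critical boundary through an extreme measured calcium, which is
exactly when flagging the patient is desirable.

**Validity window.** Laboratory values are used only if dated within 61
days (≈ 2 months) before the start of RT; older or post-RT values are
treated as missing. The window is applied per analyte when per-analyte
dates are supplied, or to the whole panel for a single panel date.

### Primary-site vocabulary

Growth classes follow the simplified scheme: all lung cancers are rapid,
all breast and prostate cancers slow, with no subcategorization by
molecular-targeted-agent exposure or hormone sensitivity. Unknown-origin
primaries are rapid; the explicit code `other` is moderate. The
site-to-class map ships as an editable TSV
(`system.file("extdata", "site_vocabulary.tsv", package = "katagiri")`);
an unrecognized site code is an error, never silently coerced — a caller
who wants the catch-all must write `other` deliberately.

## Survival machinery

All survival computations are implemented in the package from first
principles; the `survival` package appears only in the test suite as an
independent oracle (the tests require agreement to ~1e-10 on shared
datasets).

* **Kaplan–Meier.** Product-limit over distinct death times; subjects
  censored at a death time remain in that death's risk set (standard
  convention). Evaluation is a right-continuous step function; beyond
  the largest observed follow-up time the estimate is undefined and
  reported as `NA` — the curve is never extrapolated. The median is the
  *first death time with Ŝ ≤ 0.5* (inclusive at equality), `Inf` when
  never reached. Without censoring the estimator provably equals the
  empirical survival function, which the tests exploit as an exact
  oracle.
* **Log-rank.** k-sample form with the full hypergeometric
  variance–covariance matrix; one group is dropped before inversion
  (the matrix is singular by construction), with an SVD pseudoinverse
  fallback for degenerate risk structures. Zero total deaths yields
  χ² = 0, p = 1 rather than an error.
* **Cox proportional hazards.** Newton–Raphson on the log partial
  likelihood, vectorized over distinct death times via reverse
  cumulative risk-set sums. Ties use the Breslow approximation by
  default — matching the default of the commercial package behind most
  published clinical tables, hence the convention a validation analysis
  should reproduce — with Efron behind a switch. Convergence: relative
  log-partial-likelihood change < 1e-9 or 50 iterations, with
  step-halving so the likelihood path is non-decreasing; the gradient
  norm at the optimum is reported (tests require < 1e-8). Inference is
  Wald (HR = e^β, CI = e^{β ± 1.96·SE}), again matching clinical-table
  convention rather than likelihood-ratio intervals. Monotone
  likelihood (perfect separation) is detected through runaway
  coefficients (|β| > 15) and flagged, never returned silently; the
  linear predictor is max-shifted before exponentiation to avoid
  overflow on the way there.

## The validation pipeline

`run_validation()` scores the cohort, excludes non-scorable patients
from score-based analyses only (missing data are excluded per-factor in
the univariate screen, listwise per-model in the Cox fits), and builds
four artifacts: a characteristics table (percentages over the whole
cohort denominator, so factors with missingness sum to < 100%;
zero-count levels retained), a univariate table (per-level KM medians
plus per-factor log-rank p), the multivariable Cox models, and the
risk-group validation table with survival percentages at 3/6/12/24
months plus plot-ready KM step coordinates.

Sex and ECOG performance status are fitted in **separate** canonical
models (`with_ecog`, `with_sex`) — the two variables proxy overlapping
prognostic information and were evaluated separately in the validation
setting this package mirrors; because that practice is ambiguous to
reverse-engineer, we additionally report a combined model explicitly
marked non-canonical, surfacing the ambiguity instead of hiding it.
Reference levels default to woman, KPS 90–100, ECOG 3–4, critical labs,
rapid growth, disseminated spread; reference rows print HR = 1.000 with
no interval. Previous chemotherapy is available in the configurable
covariate list but is not part of the canonical model specifications.

Display rounding follows clinical-table convention — medians to integer
months, percentages to one decimal, HRs to three decimals — while exact
values are retained in `report.json`. Whether published integer medians
are rounded or floored is generally unstated; we round to nearest and
keep the exact value alongside, so either convention can be checked. No
multiple-testing adjustment is applied (none is customary in this
literature); the number of tests run is recorded in the report footer.
The pipeline is fully deterministic: identical input and configuration
produce byte-identical report files (tested via digests).

## The synthetic cohort generator

No patient-level data accompany the score's published validation, so the
generator manufactures cohorts with the published *summary* structure;
it defines the study conditions under which the package is exercised.

**Survival model.** Each risk group gets a piecewise-exponential model
with knots at the reporting times 3/6/12/24 months — the simplest family
that reproduces a printed survival profile exactly, since the segment
hazards have the closed form h_i = ln(S(t_{i−1})/S(t_i))/(t_i −
t_{i−1}). Default profiles are the published validation values: low
94.4/77.8/61.1/55.6%, intermediate 67.7/48.7/31.2/16.0%, high
39.1/22.1/9.0/3.0%. Beyond 24 months the hazard continues the last
segment's rate, except for the low-risk group, where S(24) = 55.6%
leaves the median unconstrained: its tail hazard is solved so the
analytic median equals the published 27 months. Self-consistency checks
fall out for free: the calibrated intermediate and high profiles imply
analytic medians of 5.76 and 2.21 months, rounding to the published 6
and 2.

**Covariates.** In the replica modes each patient's six component
scores are drawn uniformly among the combinations compatible with their
risk group, then decoded into concrete covariate values (a site of the
right growth class, lab values on the right side of the thresholds, an
ECOG value in the right band, …) such that re-scoring through the
scoring module reproduces the intended group for every patient — a
tested invariant, and the reason the replica cohort re-scores to exactly
18/133/205. The true joint covariate distribution within risk groups is
unpublished; uniform sampling over compatible combinations is a
documented stand-in. Sex and age are sampled independently at the
published marginal frequencies; KPS is loosely coupled to ECOG (ECOG
3–4 forces KPS ≤ 60) so both marginals stay near the published ones
without grossly discordant pairs.

**Censoring and missingness.** Administrative censoring uses a
per-patient horizon uniform on [24, 137] months — reproducing the
published follow-up range and a plausible survivor fraction without
modeling calendar-time accrual; censoring is independent of the event
process by construction. `replica_entire` mode appends 260 non-scorable
patients (616 − 356), blanking lab panels for 244 of them and visceral
status for the rest, echoing the observed pattern in which the
laboratory category is by far the most commonly missing component.

**covariate_effect mode** draws the six multivariable factors
independently at the published marginal frequencies and event times from
a proportional-hazards model with the published hazard ratios (e.g. male
sex 0.479, slow growth 0.278) on an exponential baseline. The baseline
(reference patient: woman, KPS 90–100, ECOG 3–4, critical labs, rapid
growth, disseminated spread) has a default median of 2 months — a
clinically plausible value for that profile, consistent with the
high-risk group's observed median. This mode backs the
parameter-recovery tests: Cox fits on large generated cohorts must
recover every generating log-HR within 3 standard errors.

**What the generator does not emulate.** Real cohorts have correlated
covariates within risk groups, non-uniform accrual, informative
censoring from lost-to-follow-up, measurement error in labs, and
site-mix idiosyncrasies; none of these are modeled. Passing tests
therefore demonstrate the *internal* correctness of scoring, estimation
and reporting under the published summary structure — not external
validity on any real population.

## Problem sizes and numerical settings

The test suite runs the replica cohort at its natural size (356 / 616),
parameter recovery at n = 20,000 (one fit) and n = 4,000, the
generator round-trip at 50,000 uncensored draws, and the log-rank
type-I calibration at 400 null replicates of n = 500 — sizes chosen so
Monte-Carlo error (3·√(p(1−p)/n) bands) is small relative to the
quantities checked while the whole suite stays interactive. All
randomness flows through explicit seeds; the piecewise quantile
transform is exact (closed form per segment), so generator accuracy is
limited only by sampling noise.

Known limitations: the Payne calcium correction is an assumption (the
original correction formula is undocumented); the low-risk stratum is
tiny (n = 18) in the replica configuration, so its Kaplan–Meier median
is volatile by design; Wald intervals can be poor near monotone
likelihood (which is why separation is flagged); and the CLI's
`manifest.json` records a timestamp, so *reruns* are compared on output
digests, not on the manifest file itself.
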
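---
title: "Blood pressure variability by Poincaré descriptors: models, simulator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blood pressure variability by Poincaré descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpvpoincare)
```

## The analysis this package implements

Intraoperative blood pressure in cardiac surgery with cardiopulmonary
bypass (CPB) is recorded by anesthesia information systems at a nominal
15-second cadence, in two channels: systolic pressure (SBP) and mean
arterial pressure (MAP). Surgery splits into three phases — pre-bypass,
bypass, post-bypass — and SBP is unmeasurable during bypass because flow is
non-pulsatile.

The question the pipeline addresses is whether *variability* of these
series predicts two binary outcomes, 30-day mortality and in-hospital renal
failure, beyond established preoperative risk (the Society of Thoracic
Surgeons [STS] predicted-risk scores). Variability is summarised per
patient, channel and phase by three statistics:

* **CV** — coefficient of variation, sample SD divided by sample mean.
* **SD1 / SD2** — the minor and major semi-axes of the ellipse fitted to the
  lag-1 Poincaré plot (each value $x_n$ scattered against its successor
  $x_{n+1}$), centred at the cloud's mean point and oriented along the line
  of identity. Equivalently, SD1 is the sample SD of
  $(x_n - x_{n+1})/\sqrt{2}$ (short-term variability, dispersion
  perpendicular to the identity line) and SD2 the sample SD of
  $(x_n + x_{n+1})/\sqrt{2}$ (long-term variability, dispersion along it).
  The two constructions are algebraically identical; the package carries
  both (`poincare_sd()` and the geometric `ellipse_fit_sd()`) and tests
  their agreement, because the redundancy is the cheapest possible guard
  against an axis-convention mistake.

These feature rows feed logistic regression models evaluated by the
concordance statistic (C-statistic/AUC, with a DeLong-style confidence
interval) and the Hosmer–Lemeshow calibration chi-square.

## The synthetic cohort: what it emulates

No clinical data ship with the package; `generate_cohort()` produces
cohorts with the statistical structure the analysis assumes, so every
stage is testable end to end.

**BP dynamics.** Each (channel, phase) series is a stationary AR(1)
fluctuation around a patient-specific phase level, restarted at phase
boundaries, sampled on a global 15-s grid, with i.i.d. sample dropout
(default 2%). AR(1) is the simplest process in which short- and long-term
variability are separately tunable: for autocorrelation $\rho$ and
stationary SD $\sigma$,

$$\mathrm{SD1} = \sigma\sqrt{1-\rho}, \qquad \mathrm{SD2} = \sigma\sqrt{1+\rho}.$$

The default $(\rho, \text{innovation SD})$ per cell is obtained by
*inverting* these identities at the cohort-median SD1/SD2 values reported
for large adult CPB cohorts (e.g. MAP pre-bypass SD1 ≈ 8.1, SD2 ≈ 21.7 mmHg
gives $\rho \approx 0.75$, $\sigma \approx 16.4$ mmHg; bypass MAP is much
smoother, $\rho \approx 0.90$ with $\sigma \approx 8.7$ mmHg). Phase levels
(MAP 78/57/70 mmHg, SBP 111/100 mmHg) and their between-patient spread come
from the corresponding cohort medians and IQRs, as do the lognormal phase
durations (medians 126.0 / 79.3 / 76.5 min).

**Covariates and outcomes.** Age ~ N(68, 11.9²) truncated to [19, 95];
surgery category with proportions 47.5% CABG, 29.8% valve, 19.7%
CABG+valve, 3.1% other; STS scores lognormal with a mild age trend and 26%
/ 28% missingness; a lognormal vasopressor-inotrope dose (the source
cohort's dose unit is not normalised, so the simulator treats it as an
abstract non-negative dose). Outcomes are Bernoulli draws from a logistic
model in these covariates; the intercept is calibrated by root finding so
the marginal prevalence matches its target (2.70% mortality, 2.85% renal
failure). By default the outcome model contains *no* BP-variability terms —
the null structure in which BPV cannot predict outcomes — and a coupling
can be switched on explicitly (any feature column name as a coefficient)
for positive-control runs.

**Reproducibility.** One integer seed expands into named substreams
(covariates / structure / levels / per patient / per channel / per outcome)
via a rolling hash, so adding a channel or an outcome does not perturb the
other draws, and the whole cohort is byte-reproducible.

**What it does not emulate.** Pulse contours, baroreflex dynamics,
nonstationary drift and artifact bursts are out of scope. One visible
consequence: within-phase CV of the simulated series is somewhat lower than
clinical tables report (e.g. MAP pre-bypass CV ≈ 0.21 vs ≈ 0.27), because
the clinical CV also absorbs slow drift that a stationary AR(1) does not
model, while SD1/SD2 — driven by local structure — land close to their
clinical medians. Passing tests therefore establish that the *machinery* is
correct under a plausible hemodynamic model, not that real BP series are
AR(1).

## Pipeline conventions and numerical choices

* **Phase boundaries** are half-open, `[start, end)`: a sample exactly at
  bypass start belongs to bypass. Unambiguous and free of double counting.
* **Exclusion funnel** applies first-matching criteria in the order age →
  no CPB → inadequate BP data, and the log reconciles
  `initial = retained + sum(excluded)` with exactly one reason per patient.
* **Adequacy** means all three MAP phase series have at least
  `min_phase_samples` samples (default 20, i.e. 5 minutes): there is no
  standard definition of "inadequate monitoring data", so this is an
  explicit package decision.
* **Lag-1 pairing** only bridges gaps up to `max_gap` (default 30 s, two
  nominal intervals, i.e. at most one missing sample). Pairing across long
  dropout gaps would count missingness as variability.
* **Denominators** are sample (n−1) SDs everywhere, matching the defaults
  of standard statistics packages; the identity
  $\mathrm{SD1}^2 + \mathrm{SD2}^2 = \mathrm{Var}(x_n) + \mathrm{Var}(x_{n+1})$
  holds exactly under either convention and is asserted in the tests.
* **Degenerate cells**: fewer than 2 admissible pairs gives missing
  descriptors; a constant series gives SD1 = SD2 = CV = 0 with the SD1/SD2
  ratio reported missing (no division blow-ups).
* **IRLS** declares convergence when the largest absolute coefficient
  change drops below 0.001 (the classic SPSS-style rule; `max_iter` 25),
  reports the iteration count, and flags quasi-separation. `stats::glm` is
  used as an independent oracle in the test suite, never as the
  implementation, because its deviance-based stopping rule is not the one
  this pipeline specifies.
* **C-statistic**: exact pairwise concordance when $n_1 n_0 \le 10^4$,
  an algebraically identical midrank path otherwise; both paths are tested
  to agree to $10^{-12}$ and to equal the Mann–Whitney $U/(n_1 n_0)$. CIs
  use the DeLong placement variance (cross-checked against pROC).
* **Univariable model AUC orientation**: reported as the C-statistic of the
  exposure in its natural increasing direction, *not* of fitted
  probabilities. Fitted-probability AUCs are folded above 0.5 by the sign
  of the estimated slope, which biases a null exposure's AUC upward
  (≈ 0.52 at this cohort size); the fixed orientation keeps null exposures
  centred on 0.5 and admits values below 0.5 for protective directions,
  which is how such tables are conventionally printed. Multivariable
  models use fitted probabilities.
* **Hosmer–Lemeshow**: 10 quantile groups, boundary ties to the lower bin,
  zero-expected bins merged with a neighbour (logged), df = bins − 2.
* **STS handling**: scores enter models on the log-odds scale; missing
  scores are median-imputed with a retained missingness indicator (the
  strategy is pluggable). Because "the STS model" is ambiguous between a
  score-only model and one adjusted to age, surgery category and dose, the
  suite reports both (`sts_only`, `sts_adjusted`) and the Table-6-style
  BPV models are compared against `sts_adjusted`.
* **Stepwise selection** (available, off by default): forward on Wald p
  with entry 0.05, backward pruning at stay 0.10, forced adjustment sets
  always retained.
* Written CSV output is rounded to 6 decimals so golden-file comparisons
  are platform-stable.

## A minimal run

```{r example, eval = FALSE}
cfg <- sim_config(n_patients = 500, seed = 1)
cohort <- generate_cohort(cfg)
analysis <- apply_exclusions(cohort)
features <- compute_cohort_bpv(analysis)
suite <- run_model_suite(features, analysis$records)
subset(suite, model %in% c("sts_only", "sts_adjusted"))

# or end to end, with CSV artifacts, report and manifest:
run_pipeline(list(n_patients = 500, seed = 1), out_dir = "bpv_out")
```

## Problem sizes used by the test suite

The unit tests run on deliberately small cohorts (tens to a few thousand
patients, shortened phases) where every property is still identifiable.
The statistical acceptance checks use the sizes at which their claims are
stated: 1000 random clouds for descriptor-oracle agreement; 500 random
score/label sets for the AUC paths; 500 replicates of n = 10,000 for the
Hosmer–Lemeshow null mean (target df = 8); n = 50,000 for coefficient
recovery; and 50 replicate cohorts of n = 3,687 at 2.7% prevalence with
zero BPV coupling for the null-structure study, in which the mean
univariable BPV AUC stays within 0.02 of 0.5 and adding any BPV term to
the adjusted model moves its AUC by less than 0.01.

## Known limitations

* The AR(1) generator understates nonstationary drift, so simulated CVs
  are conservative relative to clinical cohorts (see above).
* Outcome labels are inputs: deriving renal failure from creatinine or
  dialysis records, and the STS score computation itself, are upstream of
  this package.
* SD1/SD2 and CV deliberately ignore temporal ordering beyond lag 1;
  complexity measures (multiscale entropy and relatives) are out of scope.
* DeLong-style intervals are asymptotic; with very few events (tens) they
  can reach the [0, 1] clip.
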
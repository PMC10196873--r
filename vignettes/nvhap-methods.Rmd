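---
title: "Methods: electronic NV-HAP surveillance and attributable mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: electronic NV-HAP surveillance and attributable mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nvhap)
```

Non-ventilator hospital-acquired pneumonia (NV-HAP) is among the most common
and lethal healthcare-associated infections, yet it is not under routine
national surveillance: traditional case-finding needs manual chart review,
which does not scale to millions of admissions. This package implements a
fully electronic alternative — a deterministic surveillance definition over
routine EHR data — together with the statistical machinery to turn detected
events into a population-level estimate of the inpatient mortality
*attributable* to NV-HAP, and a synthetic inpatient-trajectory generator
with known truth against which both components are validated.

## The surveillance definition

An admission meets the definition on onset day $d$ when all of the
following hold:

1. **Sustained oxygenation deterioration.** Days $d$ and $d{+}1$ are both
   *worse* than the baseline day $d{-}1$, after at least two stable or
   improving days (day $d{-}1$ not worse than $d{-}2$, and $d{-}2$ not
   worse than $d{-}3$ when that day exists). "Worse" means an escalated
   oxygen-delivery device (rank ladder: room air 0, nasal cannula, simple
   mask, oxygen-conserving device, nonrebreather, high-flow nasal cannula,
   BIPAP, ventilator 7) **or** a drop in daily minimum SpO2 of at least
   $\delta$ percentage points below baseline.
2. **Systemic inflammation.** Temperature $\le$ 36 or $\ge$ 38 °C, or
   WBC < 4 or $\ge$ 12 $\times 10^3$/mm³, on some day within
   $d \pm 2$.
3. **Chest imaging** completed within $[d-1, d+2]$.
4. **New antimicrobials.** A course starting on day $d$ or $d{+}1$, with no
   antimicrobial administration in the preceding 2 days, covering at least
   3 consecutive days (agents may differ day to day). Courses cut short by
   discharge or death count only when 3 days were actually observed.

Patients on a ventilator on either baseline day are excluded — pneumonia
arising on mechanical ventilation is VAP, a different surveillance entity.
One event is kept per admission (the first qualifying day): incidence
denominators are admission-level.

Tunable parameters, with defaults and rationale
(`surveillance_params()`):

| parameter | default | units | why |
|---|---|---|---|
| `spo2_drop` ($\delta$) | 3 | SpO2 points | a margin below which day-to-day oximetry jitter would trigger spurious deterioration |
| `temp_wbc_window` | $\pm 2$ | days | inflammation evidence must be contemporaneous with onset |
| `imaging_window` | $[-1, +2]$ | days | imaging is usually ordered the day of, or just after, deterioration |
| `abx_lookback` | 2 | days | antimicrobial-free span required for a course to count as *new* |
| `abx_min_run` | 3 | days | distinguishes empiric treatment of pneumonia from single-dose prophylaxis |
| `normal_spo2` | 97 | % | unmeasured pulse oximetry and oxygen devices are treated as normal; 97% is a typical room-air saturation |

The deterioration thresholds and criterion conjunction are fixed by the
definition; the window widths, the SpO2 margin and the lookback are
implementation choices exposed as configuration because published accounts
of such definitions state the criteria without always fixing these
constants. The daily oxygenation summary fed to the rule is the *worst of
day* (minimum SpO2, maximum device rank): a deterioration definition
should not be maskable by a good reading later the same day.

Missingness rule: unmeasured oxygenation is normal (no supplemental
oxygen, `normal_spo2`); unmeasured temperature and labs never satisfy a
criterion. Patients ventilated *after* a non-ventilated onset are
retained — the event predates mechanical ventilation.

## From events to attributable mortality

Simply comparing deaths among event vs non-event admissions overstates
harm: sicker patients both acquire pneumonia and die of their underlying
disease, and length of stay mediates exposure time (time-dependent bias).
The package instead contrasts two counterfactual scenarios on the same
cohort:

* **current care** — the cohort as observed;
* **hypothetical elimination** — what the cohort's mortality would have
  been had NV-HAP not occurred, estimated by censoring follow-up at onset
  and re-weighting the remaining NV-HAP-free person-days.

### Person-day file

Eligibility: admissions of at least 3 days with a recorded value on day 1
or 2 for hospital service, WBC, hematocrit, platelets, sodium, glucose and
creatinine (`eligible_cohort()`). Time zero of the analysis file is day 3 —
the earliest possible onset given the 2-day stable baseline — and days 1–2
contribute only baseline and lagged covariates. One row per
hospitalization-day through day $\min(\text{los}, 60)$; stays beyond 60
days are administratively censored.

Covariates on each row (`build_person_days()`):

* time-fixed: facility bed-size class, teaching status, region; age, race,
  sex; seven comorbidity flags plus the summary comorbidity index; prior
  90-day admission;
* time-varying, as of **two days prior** (so they are measured before the
  exposure they predict): service, ICU status, oxygen device rank, minimum
  SpO2, the routine labs (last observation carried forward) with a
  days-since-last-panel counter, and ordered categories
  (not measured / normal / abnormal) for the nonroutine labs ALT,
  bilirubin and albumin. A value recorded only on day 2 backs up the day-3
  row, where no observation two days prior exists yet.

Right-skewed labs (platelets, glucose, creatinine) enter the propensity
model on the log scale. Discharge to hospice is an alive discharge (a
competing event), not a death: hospice disposition is reported separately
in the descriptive tables.

### Propensity model and weights

`fit_daily_propensity()` fits one pooled logistic regression over all
at-risk person-days (in hospital, alive, NV-HAP-free through the previous
day), outcome = onset today, with a flexible day effect — a natural cubic
spline on hospital day (4 knots / 3 df by default) or, for testing, one
parameter per day, in which case the covariate-free fit reproduces the
empirical daily hazard exactly. If the MLE separates, a weak ridge penalty
(`glmnet`, $\lambda = 10^{-4}$) is used with a warning. With zero onsets
the model degenerates to $\hat p = 0$ and all weights are 1, so the two
scenarios coincide — as they must.

Under elimination, subject $i$'s follow-up is censored at onset and each
remaining NV-HAP-free day $t$ is weighted by

$$W_i(t) = \prod_{k=3}^{t} \frac{1}{1 - \hat p_i(k)},$$

the inverse of the estimated probability of having remained NV-HAP-free,
truncated at the 99th percentile (unstabilized by default; stabilized
weights are available via `causal_params(stabilized = TRUE)`). A fitted
$\hat p = 1$ is a positivity violation and aborts rather than silently
producing infinite weights.

### Weighted Aalen-Johansen estimator

For each day $t$ and event $e \in \{\text{death}, \text{discharge}\}$:

$$\hat\lambda_e(t) = \frac{\sum_i W_i(t)\, I(\text{event } e \text{ on } t)}
                          {\sum_i W_i(t)\, I(\text{at risk on } t)},
\qquad
\hat S(t) = \prod_{s \le t} (1 - \hat\lambda_{\text{death}}(s)
                               - \hat\lambda_{\text{discharge}}(s)),$$

$$\hat F_e(t) = \sum_{s \le t} \hat\lambda_e(s)\, \hat S(s-1).$$

$F_{\text{death}} + F_{\text{discharge}} + S = 1$ at every day by
construction (tested to $10^{-12}$), both incidence functions are
nondecreasing, and weights enter only as ratios. Days with an empty risk
set carry zero hazards, so curves go flat rather than undefined. With a
single event type the estimator collapses to one minus Kaplan-Meier
survival; on unweighted data it agrees with `survival::survfit`'s
multi-state estimator to machine precision (both are tested).

The headline summary (`estimate_attributable()`): 60-day death risks under
the two scenarios, their difference and ratio, and the attributable
fraction $1 - \text{RR}$ — the share of inpatient deaths associated with
NV-HAP under the elimination contrast.

### Inference, pooling, stratification

Confidence intervals are percentile intervals from a nonparametric
bootstrap resampling *hospitalizations* (the clustering unit) with
replacement, 500 times by default, re-running the whole pipeline —
propensity refit included — per replicate; replicates without events are
recorded at RR 1 and flagged. Multi-site analyses run per site and are
pooled as size-weighted averages, replicate-wise for the intervals, so no
person-level data crosses sites. `stratified_estimates()` re-runs the
pipeline within strata (age, service, day-3 ICU status, comorbidity
quartile, bed size, region, teaching status) and supports the 30-day
sensitivity horizon; empty or degenerate strata are reported as not
estimable instead of aborting.

## The synthetic cohort generator

`generate_cohort()` emulates exactly the structures the pipeline consumes;
it is a validation instrument, not a model of any particular hospital
system. Design:

* **Admissions.** Age from a truncated normal (median ≈ 65, IQR ≈ 55–75),
  30% female, race and service mixes, comorbidity flags with realistic
  marginal frequencies, a comorbidity index correlated with the flag
  count, facilities with size/teaching/region attributes and uneven
  volumes.
* **Daily trajectories.** An exogenous ICU Markov chain; routine labs
  drawn as a shared panel (always on day 1 for ~97% of admissions, then on
  ~60% of days) with creatinine following a per-patient log-AR(1) process;
  sporadic nonroutine labs; temperature and SpO2 with configurable jitter.
* **Competing daily transitions.** Death, then alive discharge, then
  (from day 3, if event-free) NV-HAP onset — mutually exclusive within a
  day. Baseline hazards 0.004 and 0.16 per day give ~2% baseline
  in-hospital mortality and a median stay of ~4 days. Onset follows a
  per-day logistic model on age, comorbidity index, and *lagged* ICU and
  log-creatinine — the same features, same lag, the propensity model uses,
  so the analysis model is correctly specified on synthetic data. The
  death and discharge hazards share those severity covariates:
  confounding is real, and the naive "drop the event admissions" contrast
  is visibly biased while the weighted one is not (tested). After onset
  the death hazard is multiplied by `theta_death` (default 2) and the
  discharge hazard by `theta_discharge` (default 0.5), mirroring the
  longer stays and higher mortality of pneumonia patients;
  `theta_death = theta_discharge = 1` is the exact causal null. A
  facility-level random intercept acts on onset only (incidence variation
  without confounding).
* **Surveillance signatures.** True events always express the oxygenation
  deterioration (device escalation sustained to end of stay plus an SpO2
  drop exceeding the default margin, after stable days); the fever/WBC,
  imaging and antimicrobial signatures are each emitted with probability
  `signal_completeness`. Background noise — oximetry jitter, incidental
  antimicrobial courses, imaging and fever — is configurable and can be
  switched off entirely.

The default onset intercept gives roughly 0.7–1 onset per 100 at-risk
days, i.e. ~3–5 events per 100 eligible admissions. This is deliberately
denser than large multi-hospital cohorts report (~0.5–0.8 per 100
admissions): simulation cohorts of 10–20 thousand admissions need
hundreds, not dozens, of events for estimator checks to be informative,
and the estimators are invariant to the overall event density. Ground
truth (onset day, terminal cause, and whether the stay lasted long enough
— onset + 2 days — for every signature to be observable) is written to a
separate table and never into the analysis data.

**What the generator does not emulate:** any specific network's case mix,
seasonal or pandemic drift, inter-hospital transfer, within-day event
ordering, post-onset ICU transfer (the ICU chain is exogenous so that
confounders are strictly pre-exposure), or informative lab-measurement
schedules. Passing tests on synthetic data therefore demonstrate the
*internal* correctness of the definition and estimator — not calibration
to any real population.

## Validation design and numerical choices

* **Detector.** On noise-free data with complete signals, sensitivity and
  positive predictive value are both 1.0 and the onset day is recovered
  exactly. Sensitivity is asserted on *fully observed* events: an onset
  whose stay ends within two days cannot satisfy a definition that
  requires two deterioration days and three antimicrobial days — no
  detector honouring the definition can find it, which is a property of
  surveillance definitions generally, not of this implementation.
  A brute-force oracle that re-derives every criterion with naive scans
  must agree with the engine admission by admission, and detection is
  monotone: deleting evidence can only remove events, never create them.
* **Estimator.** The weighted Aalen-Johansen implementation is checked
  against an independent day-by-day tabulation to $10^{-12}$ on a
  hand-computed fixture and on 1000 random small instances, and against
  `survival::survfit` on unweighted data. The causal pipeline must
  recover the null (RR within 3% of 1 at 20 000 admissions under
  `theta = 1` with confounded onset, ground-truth events fed to the
  estimator so the detector is not part of this particular test) and the
  effect direction (`theta_death = 1.5` lowers the elimination risk in
  ≥ 19 of 20 seeds at the same size). Propensity coefficient recovery is
  checked against the generator's known coefficients.
* **Problem sizes.** Simulation-based tests use 1 000–20 000 admissions
  and bootstrap sizes of 10–100; these sizes give Monte-Carlo error
  comfortably inside the asserted tolerances while keeping the whole
  suite fast enough to run routinely.
* **Ties and tie-breaks.** First qualifying onset day wins; one event per
  admission. Within a day, death precedes discharge precedes onset in the
  generator, and the analysis censors *at* onset (the onset-day row gets
  weight zero) so an onset-day death is never attributed to the
  elimination scenario.
* **Degenerate inputs.** Zero admissions, zero events, empty strata,
  all-identical bootstrap clusters and empty risk sets all return
  well-defined results (empty tables, RR 1, "not estimable" rows, flat
  curves) rather than errors; genuinely invalid inputs (day > los,
  duplicate days, unknown devices, positivity violations) raise typed
  errors.

## Known limitations

* The elimination scenario is a statistical device for attributable-risk
  estimation, not a claim that NV-HAP is fully preventable.
* Weight truncation (99th percentile) trades a little bias for variance;
  with very strong time-varying confounding the truncated estimator can
  under-correct.
* The propensity model's functional form (spline day effect, log labs,
  linear age) is a modelling choice; on real data misspecification is
  possible and stabilized weights plus the categorical day effect are the
  built-in sensitivity levers.
* Chart-review agreement statistics are computed from review tables; the
  package does not reproduce any manual review itself.
* Detection near the end of a stay is structurally limited by the 3-day
  antimicrobial requirement, as discussed above; real-world sensitivity
  analyses should bear this censoring in mind.
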
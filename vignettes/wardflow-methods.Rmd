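---
title: "Dynamic deterioration prediction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic deterioration prediction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Hospitalized patients on general wards deteriorate at low but consequential
rates: a small fraction of admissions end in unplanned transfer to an
intensive-care unit or in-hospital death. Bedside early-warning scores flag
such patients from a handful of manually collected vitals; `wardflow`
implements the alternative strategy of learning a dynamic risk model from
routinely recorded event-stream EHR data — pre-admission diagnosis history,
in-stay laboratory results and clinical-note text — re-assessed every few
hours throughout each admission.

The target is the composite outcome of *clinical deterioration*: unplanned
ICU transfer (an acute ICU admission beginning during the stay or within 24
hours after discharge from a non-ICU ward) or in-hospital death. At every
assessment time `t` during an admission, the model predicts whether this
event occurs inside the half-open prediction window `(t, t + W]`, for an
assessment rate Δ ∈ {6, 12, 24} h and window W ∈ {1, 2, 7, 14} d.

Real ward EHR extracts are access-restricted, so the package ships a
synthetic generator whose output exercises every pipeline stage and carries a
known planted signal against which recovery can be verified.

## The synthetic generator

`synth_config()` / `generate_ehr()` emulate the statistical structure of a
large inpatient cohort:

* **Outcome prevalence.** Composite prevalence 2.2% of eligible admissions
  (1.5% death, 0.7% ICU transfer). Rather than fixing a hazard by hand, the
  per-step hazard intercept is calibrated by root-finding so the *expected*
  prevalence over the realized severity trajectories equals the target; the
  empirical prevalence then matches to binomial accuracy at any cohort size.
* **Lengths of stay.** Lognormal with median 31 h and `sdlog = 1.75`
  (quartiles ≈ 9–98 h), administratively capped at 28 days.
* **Latent severity.** Each patient has a Gaussian frailty; each admission
  adds an age-linked, noisy baseline and follows a random walk on a 6 h grid
  — the finest assessment clock, so emissions align with the sampler. The
  per-6 h event hazard is `min(1, scale · logistic(c + 1.1 · s))`; setting
  `event_hazard_scale = 0` disables events outright (it is not re-calibrated
  away).
* **Observations.** Laboratory values are drawn per analyte with a mean
  shifted by `direction · lab_shift · severity` standard deviations, so the
  extreme decile tokens of directional analytes carry signal. Note tokens
  are drawn from risk / protective / neutral pools with log-linear
  severity weighting; diagnosis histories (negative-binomial length, median
  ≈ 23 codes, timestamps before the first admission) are weighted by patient
  frailty. Emission rates are set so that roughly 19 lab tokens and ~200
  note tokens accrue in the first 24 h of a stay.
* **Exclusion arms.** Configurable fractions of minors (< 16 y), patients
  with disconnected record histories, outpatient contacts, acute
  emergency-department admissions, standalone direct-ICU admissions, and
  late (> 24 h post-discharge) ICU admissions that must *not* count as
  transfers. The generator records per-rule planted counts so the cohort
  module's attrition table can be verified exactly.

What the generator does **not** emulate: real clinical language (notes are
token streams, not prose), national coding dialects, vital signs,
informative/missing-not-at-random measurement schedules, seasonal or
hospital-level effects, and competing discharge-event dependence beyond the
severity link. Passing tests therefore demonstrate that the pipeline's
machinery is correct and that a planted signal of realistic sparsity is
recoverable — not that any particular performance level transfers to real
ward data.

`synth_config_strong()` raises the severity-to-observation links
(`lab_shift` 0.9, `note_link` 1.05, `diag_link` 1.2, `frailty_sd` 0.8) for
signal-recovery experiments; prevalences and stay structure are unchanged.

## Cohort construction

Consecutive visits of one patient merge into a single admission when the gap
between them is at most 24 h — the boundary itself merges, since a
department transfer should never split a stay. Exclusions are applied in a
fixed order (direct ICU, outpatient, acute ED, minors, disconnected), so the
attrition counts are order-dependent by construction. Ages are fractional
years at admission start; 16.0 years is retained, anything below is not.
When both an ICU-transfer candidate and an in-hospital death fall inside an
admission's event horizon, the earlier event defines the outcome. Patients
are split 64/16/20% into train/validation/test at the patient level;
every admission inherits its patient's set.

## Tokenization

* Diagnosis codes roll up to their first three characters (`C341M → C34`),
  collapsing specific codes onto clinically coherent level-3 stems.
* Laboratory records become strings
  `COMPONENT_SPECIMEN_unit@lo-hi`, where `lo`/`hi` are the decile edges (q =
  10 per analyte, fitted on training-split values only; per-analyte rather
  than global quantiles, since a token such as `HEMOGLOBIN_B_mmol/L@8-8.5`
  should span a hemoglobin-plausible range). Edges print at 4 significant
  digits with trailing zeros stripped. Analytes with fewer distinct values
  than bins fall back to as many bins as the data support; out-of-range
  values clamp to the end bins.
* Note streams are lower-cased; clinician-signature patterns, punctuation,
  stop words and negation terms are dropped, order preserved. Only the
  listed negation tokens are removed — not the tokens following them — since
  scope resolution is not attempted.
* Vocabularies keep tokens with training frequency ≥ `min_freq`, assign ids
  by descending frequency (lexicographic tie-break), and reserve PAD = 0 and
  UNK = 1. Encoding keeps the **most recent** `pad_size` tokens — the
  clinically relevant end of the stream — and right-pads.

Default pad sizes are 9 (diagnoses), 28 (labs) and 48 (notes). The first two
are the search optima for those domains; the note pad is a desk-scale
choice — long enough to cover roughly a day of cleaned note tokens in the
synthetic streams while keeping recurrent unrolling affordable on one CPU.

## Sampling

One sample is materialized per (admission, assessment time), with `t = 0,
Δ, 2Δ, …` strictly before the event or discharge. The doorstep sample
(`t = 0`) uses only pre-admission history and demographics. Sequences
contain only records timestamped at or before `start + t` (diagnoses: before
admission start), so leakage is excluded by construction and verified by
perturbation tests. Assessments stop strictly before the event so no sample
contains outcome-coincident data. Static features are z-scored age and
prior-admission count (training statistics) plus a 0/1 sex indicator.

## The model

One submodel per domain: an entity embedding of dimension
`round(6 · α · V^(1/4))` (α the tunable embedding coefficient, V the
vocabulary size), a single-layer GRU (or LSTM) over the embedded sequence,
and additive attention pooling `e_t = v·tanh(W h_t + b)` with a masked
softmax, so padding positions receive exactly zero weight. The pooled
vectors are concatenated with the static features and mapped through one
linear unit with a logistic activation to a risk in (0, 1).

Masking is strict: embeddings at padded positions are zeroed, the recurrent
state carries through them, and attention ignores them — changing token ids
at masked positions provably never changes the output. All-PAD sequences
(doorstep samples) unmask one position so pooling stays defined; its input
remains the zero vector, so all such samples share one learned
representation per domain.

Forward and backward passes are hand-written matrix code; gradients are
verified against central finite differences (relative error ~1e-5) for both
cell types in the test suite.

## Training

Mean binary cross-entropy, Adam (default learning rate 1e-3; the pipeline
default is 3e-3 for its short-epoch runs), mini-batches of 256, early
stopping with patience 5. The model is checkpointed each epoch and the
parameters of the epoch with the lowest validation loss (first minimum on
ties) are returned; validation AUPRC is the model-selection metric across
configurations, since under ~1–3% prevalence AUROC saturates while AUPRC
retains contrast. Plain (unweighted) BCE handles the class imbalance.
Hyperparameter search is pluggable; the default sampler draws uniformly at
random from the declared space and persists a trials ledger. Training is
deterministic given the seed.

## Calibration

Isotonic recalibration is fitted on the validation split only
(pool-adjacent-violators on the raw risks, tied scores pooled first so the
map is a function of the score) and applied to the untouched test split as a
right-continuous step function with end-value clamping. The primary
diagnostic is the binned calibration slope/intercept: a weighted
least-squares line through (mean predicted, observed rate) over ten
equal-count bins — ideal (1, 0) on the probability scale. A logit-scale
logistic-recalibration slope is available as a secondary diagnostic.

## Evaluation

AUROC uses the rank (Mann–Whitney) formulation with ties counted ½. AUPRC is
step-wise average precision without trapezoidal interpolation, avoiding the
known optimism of interpolated PR areas; its chance level equals the
prevalence. Threshold tables report precision/recall/specificity at 1, 5,
10, 20 and 50% risk. Confidence intervals are percentile bootstrap over 200
resamples of the assessment samples (resamples missing a class are redrawn,
at most ten times); resampling is at the assessment-sample level — the unit
the model scores — and admission-level resampling is left as future work.
Stratified reports cover sex and the age bins 16–37, 37–58, 58–79, 79–100,
flagging strata with too few positives as not evaluable, and a time-course
report tracks metrics and shrinking sample counts over time into the stay.

## Attribution

Expected-gradients Shapley values are computed on the embedding inputs: for
each explained sample, gradients of the (uncalibrated) logit are accumulated
along interpolation paths from baseline samples drawn from the validation
pool (default 64), multiplied by `(input − baseline)`, summed over embedding
dimensions and averaged. The logit is attributed by default because
isotonic calibration is monotone and sign-preserving; probability
attribution is a flag away.

Two numerical choices matter. First, the population reference for the
completeness identity is the mean model output over the baseline pool
*evaluated inside the explained sample's own sequence structure*: with
variable-length masked sequences, a baseline's own forward pass is not the
endpoint of the interpolation path, so the reference is computed under the
explained sample's masks. Second, interpolation points default to a
composite-midpoint rule along each baseline's path (`alpha_scheme =
"quadrature"`): the path integrand has localized sigmoid transitions, and on
measured paths the midpoint rule beat both naive Monte-Carlo and
higher-order quadrature by an order of magnitude, making per-sample
completeness hold within tight tolerance at 64 baselines × 256 draws. A
jittered-stratified uniform scheme (`"uniform"`) keeps the fully stochastic
behaviour available. PAD positions attribute exactly zero by construction.

## Numerical conventions and degenerate inputs

Timestamps are integer minutes from an arbitrary epoch; intervals are
half-open `[start, end)`. Quantiles are type-7 throughout. PAVA pools tied
scores before fitting. Single-class inputs error early (AUROC, AUPRC,
isotonic fitting, calibration slopes); constant predictions make the binned
slope undefined and error rather than returning a number. Empty corpora,
zero budgets, negative noise and non-partition split fractions are rejected
with configuration errors.

## Problem sizes used by the shipped tests

The test suite builds its shared world at 2,500 patients (strong-signal
preset) with a hidden size of 8 and four training epochs; signal recovery is
additionally demonstrated on a ~20,000-admission cohort (11,600 patients),
and the full 3 × 4 grid runs at 1,200 patients with two epochs. These sizes
are the package's choices for a reproducible desk-scale demonstration;
nothing in the code limits larger cohorts, and `default_experiment_config()`
exposes every knob.

## Known limitations

* The generator's event mechanism is a single latent severity channel; real
  deterioration has heterogeneous, multi-cause dynamics, and event-type
  (death vs ICU) is drawn independently of severity by default.
* Notes are emitted directly as token streams; nothing about real clinical
  NLP (names, abbreviations, negation scope, Danish morphology) is modelled.
* The recurrent core is single-layer and unidirectional by default;
  bidirectional and multi-layer variants are declared in the spec surface
  but the hand-written backward pass covers the single-layer case.
* Bootstrap intervals ignore within-admission correlation of samples.
* Training is single-threaded CPU matrix code: adequate at desk scale,
  not a substitute for accelerator-backed frameworks at registry scale.
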
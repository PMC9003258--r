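---
title: "Compensatory reserve estimation from simulated LBNP waveforms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compensatory reserve estimation from simulated LBNP waveforms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(crwave)
```

## The problem

During the compensatory phase of hemorrhage, standard vital signs barely
move: heart rate, blood pressure and oxygen saturation are actively defended
until compensation is nearly exhausted, at which point the patient collapses
quickly.  The *compensatory reserve* reframes monitoring around the fraction
of that defence capacity still available — 1 (100%) at rest, 0 at
hemodynamic decompensation.  Because the reserve is encoded in the beat-level
morphology of the arterial pressure pulse (pulse-pressure narrowing,
tachycardia, damping of the dicrotic notch), it can be estimated continuously
from a non-invasive finger arterial pressure waveform.

The experimental model behind this package is staged lower-body negative
pressure (LBNP): suction applied to the lower body pools blood in the legs
and reproduces graded central hypovolemia without bleeding.  The protocol is
a 5-min rest followed by 5-min stages at 15, 30, 45, 60, 70, 80, 90 and
100 mmHg of suction (we store magnitudes; the conventional minus sign is
presentation), terminated when systolic pressure falls below 80 mmHg with
presyncopal symptoms.  Established physiology maps 30/60/90 mmHg of LBNP to
roughly 450/1000/1600 mL of blood loss in a 70 kg adult
(`lbnp_to_blood_loss()`).

The reserve ground truth is the LBNP surrogate ratio

$$\mathrm{reserve}(t) \;=\; 1 - \frac{\mathrm{LBNP}(t)}{\mathrm{LBNP@HD}},$$

where LBNP@HD is the level at which the individual decompensates
(`reserve_from_lbnp()`, `true_reserve()`).  Subjects completing the 60 mmHg
stage (1500 s of protocol including rest) are *high tolerant* (HT), the
rest *low tolerant* (LT); a time of exactly 1500 s would be HT ("tolerated
beyond 60 mmHg" includes completing it), though the simulator never draws
the boundary exactly.

The package compares two estimator families head to head on simulated
cohorts: a 1-D convolutional network scoring normalized 20-s waveform
segments (the "CRM-style" estimator) and a transparent per-beat
morphology-feature regression averaged over a 30-beat sliding window (the
"CRI-style" stand-in for a proprietary feature-based algorithm).

## The synthetic cohort: what it emulates, and what it does not

The original waveform database is closed (a government-controlled
repository), so the package generates virtual experiments
(`generate_cohort()`).  The generator states a world and sticks to it:

* **Cohort structure** — 191 subjects, P(HT) = 131/191; class tolerance
  times with mean (sd) 1838 (262) s for HT and 1286 (193) s for LT; body
  mass 74.5 (16.1) kg.
* **Tolerance-time draws** are truncated normals confined to each class's
  side of the 1500-s rule (LT within [601, 1499] s — no decompensation
  before completing the first stage — and HT within [1501, 2700] s).  The
  printed class statistics describe the *realized, already classified*
  groups, so drawing from normals with exactly those parameters and then
  truncating would bias the class means by ≈50 s.  `match_truncated_normal()`
  therefore solves for the underlying (μ, σ) whose truncated distribution
  has the stated mean.  One limitation is intrinsic: on [601, 1499] with
  mean 1286, no truncated normal reaches sd 193 (the family ceiling is
  ≈190.6); the LT sd realizes at ≈189.9.  Means are matched exactly.
* **Waveforms** — 500 samples/s beat trains from protocol start to the
  tolerance time.  Each beat is a parametric template: a systolic Gaussian
  bump (peak at 25% of the beat), a dicrotic Gaussian bump (at 55%), and a
  broad diastolic runoff, normalized so the template peak maps to the target
  systolic pressure.  Defaults: heart rate 65 beats/min, SBP/DBP 120/75 mmHg,
  additive Gaussian noise of 1 mmHg — typical healthy-adult values and a
  realistic noise floor for a volume-clamp finger cuff.
* **Degradation** — morphology is driven by a *continuous* depletion driver
  d(t): the stepwise reserve linearly interpolated within stages
  (`depletion_driver()`).  Training targets remain stepwise (as the
  estimators were conceived), but a stepwise morphology would make the
  final-stage collapse unlearnable, so the physiology moves smoothly.  As d
  runs 0 → 1: heart rate rises by 50%, pulse pressure shrinks by 60%, the
  dicrotic bump amplitude (0.35 of pulse height at rest) attenuates to zero,
  and systolic pressure falls as $\mathrm{SBP}_0 - (\mathrm{SBP}_0 -
  \mathrm{SBP}_{end})\,d^2$ with SBP_end = 75 mmHg.  A terminal 10-s ramp
  (`d_sbp = max(d, 1 - 0.0057\,(t_{tol}-t))`) guarantees the final beats
  cross the 80 mmHg criterion even when the drawn tolerance time falls just
  after a stage transition, where d(t) has barely moved within the new
  stage.  Decompensation is *imposed* by the drawn tolerance time, matching
  the experimental definition (LBNP release defines the endpoint), not an
  emergent property.

What the generator does **not** emulate: respiratory modulation, ectopy and
movement artifacts, baroreflex oscillations, sex/age effects on tolerance,
the calibration drift of real finger-cuff hardware, and the baseline
instability the original feature-based algorithm shows on real recordings.
A green estimator-quality test therefore establishes that the pipeline can
recover reserve from clean, stationary beat morphology whose degradation is
monotone in depletion — not that either estimator would reach the same
accuracy on clinical data.

## Preprocessing

The fixed chain is truncate → resample to 100 samples/s by 1-D linear
interpolation → per-subject min/max normalization → non-overlapping 20-s
segmentation → stepwise target assignment (`preprocess_record()`).  Choices
the sources left open:

* Normalization constants are per *subject over the whole truncated record*,
  never per segment — per-segment scaling would erase the pulse-pressure
  trend that carries most of the signal.
* A trailing remainder shorter than 20 s is dropped; the decompensation flag
  moves to the last full segment, whose target is pinned to 0 (the subject
  decompensates within it).
* A segment's target is the stepwise reserve at its *start* time —
  deterministic and simple; mid- or end-window conventions differ only for
  the one segment straddling each stage boundary.
* The resampling grid is k/100 s from the truncation start; samples are
  never filtered or otherwise altered.

## The convolutional estimator

Architecture (`crm_architecture()`): one input convolutional layer, seven
convolution + max-pool(2) blocks, two fully connected layers, one linear
output — eleven named blocks; a 2000-sample segment shrinks to 15 time
steps before the dense head.  Stated structure aside, the hyperparameters
are package choices: channels (8, 16, 16, 32, 32, 64, 64, 64), kernel width
7, ReLU, dense 64/32, mean-squared-error loss, Adam (lr 1e-3), batch 64,
and **6 epochs** by default.  Six, not more, because the synthetic task
converges by epoch ~4 (validation MSE ≈ 0.003 against a 0.05 criterion) and
a single CPU spends ~35 s per epoch at the 48-subject desk scale; every
value is a `crm_train()` argument.  The engine is ~400 lines of
RcppArmadillo (batched im2col + GEMM, analytic backprop verified against
central finite differences in the tests).  Training splits *subjects*
80/20, never segments, so no subject leaks across the split.  Randomness
(init, shuffling) is injected from R's RNG: single-threaded runs reproduce
bit for bit; multi-threaded BLAS may differ in the last bits (documented
contract: validation loss agreement within 1e-3).

Inference (`crm_predict_series()`) scores the trailing 20-s window every
10 s (training windows do not overlap; inference slides at the reporting
cadence) and clips the linear head's output into [0, 1], since a reserve is
a fraction by definition.

## The beat-feature estimator

`detect_beats()` finds onsets as the local minima preceding systolic
upstrokes (adaptive mid-level crossings, physiologic interval bounds);
`extract_beat_features()` computes six transparent per-beat features: beat
interval, pulse amplitude, upstroke slope, time-to-peak fraction,
dicrotic-notch relative amplitude (secondary-peak rise after the systolic
peak), and the systolic/diastolic area ratio.  A ridge regression
(`cri_train()`, λ = 1, standardized features) maps features to the stepwise
reserve — deliberately simple, deterministic and inspectable, since the
algorithm it stands in for is proprietary ("hundreds of features" never
disclosed).  Per-beat predictions are averaged over a trailing 30-beat
window and resampled to the 10-s cadence; before 30 beats have elapsed the
running mean over available beats is used (warm-up, a documented choice —
the original handling is unknown).

## Evaluation

`evaluate_head_to_head()` mirrors the published comparison:

* **Clustered logistic regression**: the decompensation indicator (the final
  10-s observation of each subject) regressed on the reserve estimate, GEE
  with logit link, subjects as clusters, exchangeable (compound-symmetry)
  working correlation, robust sandwich errors.  The sources mix "GEE" and
  "random effects" vocabulary; GEE is named twice and compound symmetry
  stated, so GEE it is.  Numerics worth recording: the design (exactly one
  terminal event per cluster) induces *negative* within-cluster residual
  correlation, and the moment estimate of α can hit the positive-definiteness
  boundary −1/(n−1), so α is clamped to ≥ −0.9/(n_max − 1); scoring uses a
  glm warm start and step-halving on the working-score norm.  Separation is
  flagged (non-convergence or |β| > 30) and resolved with a small L2
  penalty — the flag threshold must sit well above the |β| ≈ 23 a sharp but
  genuine reserve slope produces on clean data.
* **ROC AUC** by the DeLong placement decomposition, with paired DeLong
  comparison of the two estimators on identical observations.  The original
  comparison procedure is unstated (and its two reported p-values disagree
  internally); paired DeLong is the standard correlated-ROC test.  AUC is
  rank-invariant to the logistic link, so the separation fallback cannot
  alter it.
* **Stage means** (baseline = level 0): subject means within stage, averaged
  across subjects still in protocol — on this balanced design identical to
  least-squares means.
* **End-of-stage ("amalgamated") regression**: group-average estimates at
  the last 10-s point inside each stage regressed on the stage's LBNP
  magnitude; reports R² and (negative) slope.
* **Dependent correlations**: Steiger's Z1* with Fisher's r-to-z and the
  mean-correlation plug-in compares the two estimators' stage-mean/LBNP
  correlations; n is the number of stage-level points (a stated limitation —
  it is the unit of that regression).

All strata (ALL / HT / LT) reuse the probabilities of the *single* fitted
model per estimator; no class-specific retraining occurs, and a test
asserts the stratified AUC equals a direct subset computation.

## Tolerances, degenerate inputs, tie-breaks

* Reserve values live in [0, 1] internally; percent only at presentation.
* `protocol_lbnp` errors beyond the schedule end (protocol overrun);
  `sample_subject` looks up the decompensation level at `t − 1e-9` so a
  draw exactly at the schedule end remains defined.
* Flat records refuse normalization and beat detection with explicit
  degenerate-input errors; records shorter than one window refuse
  segmentation and inference.
* The truncated-final-beat systolic check smooths with a 20-ms moving
  average before taking the peak, so the 1 mmHg noise floor cannot
  manufacture a >80 mmHg excursion.
* AUC comparisons with zero variance and zero difference return p = 1
  (identical markers) rather than 0/0.

## Known limitations

* The LT tolerance-time sd realizes at ≈189.9 s (printed: 193) — the
  truncated-normal ceiling discussed above.
* The synthetic world is much easier than clinical reality; the
  estimator-quality thresholds (held-out oracle correlation ≥ 0.85,
  AUC ≥ 0.9, end-of-stage R² ≥ 0.9) characterize pipeline correctness, not
  clinical performance, and the published headline numbers (AUC 0.9268 vs
  0.9164 on 191 real subjects) are not reproduction targets.
* The GEE's observation set (every 10-s estimate) and the event coding
  (final observation = 1) are explicit package conventions where the
  sources are silent; both are configurable at the `label_observations()` /
  `fit_clustered_logistic()` level.
* `crwave_cli("preprocess", ...)` assumes the default full schedule; API
  users pass shortened schedules explicitly.
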
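---
title: "Methods: wrist accelerometry, symptom-triggered sampling and engagement accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wrist accelerometry, symptom-triggered sampling and engagement accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`remotewear` implements the analytic core of a remote-monitoring platform
for older adults: a device-agnostic pipeline that turns raw 10 Hz wrist
accelerometry into frailty-aligned mobility metrics, the state machine
that schedules symptom-triggered prompts (surveys, scale sessions,
watch-monitoring windows), and the adherence/engagement accounting used
to judge feasibility. A synthetic-data generator with closed-form ground
truth makes the whole system testable at desk scale, because raw
participant recordings from home deployments are not redistributable.

This vignette is the package's own account of the models, the tunable
parameters and why their defaults are what they are, the numerical
choices, and what the synthetic tests do and do not establish.

## The measurement problem

Frailty in older adults expresses itself in mobility: inactivity (few
steps), slowness (low cadence), poor endurance (short walking bouts) and
low overall movement intensity. A wrist accelerometer worn during
monitoring windows captures all four, provided the processing separates
true wear from non-wear, steps from arm movement, and activity from
sensor noise. Because monitoring is burdensome, the platform samples:
surveys of self-rated health (SRH) every 5–9 days decide when a symptom
survey and a 48-h watch-monitoring window are warranted, rather than
recording continuously.

## Signal pipeline

### Units and epochs

The sensor reports integer counts over ±8 g at 4,096 counts/g, sampled
at 10 Hz; `counts_to_g()` is the exact linear map `g = count / 4096`.
`epochize()` summarises the calibrated signal into 1-second epochs —
per-axis mean and SD, vector-magnitude (VM) mean and SD — aligned to
integer seconds from the recording's first timestamp, so segmentation is
reproducible regardless of clock phase. Seconds without samples are
emitted with `n_samples = 0` and missing statistics; samples are never
interpolated and duplicate timestamps keep their first occurrence,
because fabricating data in a measurement pipeline is worse than
acknowledging a gap.

### Calibration

`find_stationary()` locates quiet-stationary intervals: seconds where
the VM SD over a sliding 10-s window stays below 13 mg, merged into runs
of at least 60 s. The 13 mg threshold is the widely used low-movement
convention for wrist devices; it is deliberately the same value used by
the non-wear rule below so that the pipeline has one notion of
"still". `estimate_calibration()` then chooses a scalar VM bias so the
median stationary VM equals 1 g, sets the noise floor at 3× the
stationary VM SD, and estimates the device's systematic per-axis noise
variance σ̄² (the Activity Index reference) as the mean per-axis variance
over stationary 1-s epochs. Bias correction is applied to the vector
magnitude rather than per axis: every downstream consumer works on VM or
on per-axis *variances*, neither of which benefits from an orientation
correction, and a scalar is estimable from any still posture. When a
recording is too short to calibrate (< 60 s stationary), the pipeline
falls back to documented defaults (bias 0, floor 13 mg, σ̄² = (13 mg)²)
instead of aborting. After correction, VM deviations from 1 g inside the
noise floor — and any residual negative deviations — are clamped to
zero.

### Non-wear

A block is non-wear when per-axis SD stays below 13 mg on at least 2 of
the 3 axes over a contiguous span of at least 90 min. The SD is
evaluated over rolling 30-min sub-blocks stepping 1 min, which makes the
90-min rule local and testable; the sub-block SD is the *pooled
raw-sample* SD reconstructed exactly from per-epoch mean/SD/n (epoch
means alone would hide within-second oscillation and misclassify gait).
Detected blocks are padded by 15 min on each side to guard against
motion bleeding into their edges, padded minutes count as non-wear for
the validity budget, and a side whose boundary minute contains no
samples is not padded — there is nothing to guard against, and this
makes detection idempotent on already-masked records. On records up to
6 h the implementation is verified identical to a brute-force scan over
every ≥ 90-min window.

Two boundary behaviours are worth knowing. First, non-wear bordered by
*active* signal is recovered exactly to the minute; bordered by quiet
wear, the boundary can blur by up to one sub-block (30 min) per side,
because a variance rule cannot tell where stillness ends and absence
begins inside a window that contains both. Second, a variance-only rule
fundamentally cannot distinguish a perfectly still worn device from an
unworn one; real wrists are never perfectly still for 90 min, which is
what the rule relies on.

### Steps

Step detection is two-stage. `classify_motion()` labels 5-s windows
moving/not-moving from time-domain features: VM SD ≥ 30 mg and a
dominant frequency in the 0.6–2.5 Hz gait band carrying at least half
the (DC-removed) spectral power. The classifier is a fixed threshold
rule rather than a trained model: no training corpus ships with the
package, thresholds are config-exposed, and a deterministic rule is
auditable. `detect_steps()` then band-passes the VM 0.6–2.5 Hz with a
zero-phase Butterworth filter (zero-phase so peak timestamps — hence
cadence and bout timing — are unbiased), finds local maxima above
`max(50 mg, 0.6 × band-passed window RMS)`, and keeps maximal runs of at
least 4 peaks whose successive intervals lie in [0.33, 1.67] s and
differ pairwise by ≤ 0.35 s: regular, physiologically timed steps. Steps
inside non-wear are removed, and no two emitted steps are ever closer
than 0.33 s. 10 Hz is the contract rate; other rates are rejected unless
linear resampling is explicitly enabled.

### Per-24-h metrics and validity

Each watch session is a 48-h window anchored at the moment the wearer
pressed "Start monitoring" (not calendar midnight), splitting into two
24-h intervals. Per interval:

| metric | definition | default parameters |
|---|---|---|
| `total_steps` | detected steps after non-wear masking | — |
| `cadence_p90` | 90th percentile (linear interpolation) of per-minute counts over minutes with ≥ 1 step | — |
| `lwb_steps` | steps in the bout with most steps, a bout being a maximal run with inter-step gaps ≤ 3 s, truncated 2 h after its first step | gap 3 s, cap 7,200 s |
| `aind_daily` | Σ over daytime hours of Σ per-epoch `AI_t` | 07:00–19:00 local clock |

with `AI_t = sqrt(max(0, mean_axes((σ²_axis,t − σ̄²) / σ̄²)))`: the
average per-axis epoch variance in excess of the device's systematic
noise, on a square-root (amplitude-like) scale. Non-wear epochs
contribute zero; the daily value is a *sum* (not mean) of hourly
summaries, which is what produces values on the 10⁴–10⁵ scale the
metric is known by; the choice is config-exposed. "Uninterrupted" is
not defined by any standard for walking bouts: 3 s preserves slow-gait
continuity while breaking at genuine rests, and is config-exposed. The
2-h cap reflects routine older-adult bouts; a 3-h continuous walk
reports exactly 7,200 steps / 7,200 s.

An interval is valid when non-wear ≤ 1.5 h **and** total steps ≥ 300,
both boundaries inclusive (the exclusions are phrased strictly:
non-wear *exceeding* 1.5 h, *fewer than* 300 steps), and the interval
had any coverage at all. The 300-step rule is applied after non-wear
masking: steps the mask rejects were never credible. The Activity Index
is retained per 48-h window (the larger of the two 24-h summaries) even
when step validity fails, because intensity has its own coverage
requirement — at least 50% of daytime epochs worn and recorded,
otherwise the value is reported missing.

## Prompt engine

Time is simulated in whole minutes on a local clock with no DST
transitions, for bit-reproducibility. The rules:

* **SRH surveys** every 5–9 days (integer gap, uniform), available 48 h.
* Fair/poor SRH → a symptom survey prompt **and** a watch prompt
  (`srh_triggered`); good-or-better → a watch prompt with probability
  `p_random_watch` (default 0.5; the random-selection rate is not pinned
  by any protocol document, 0.5 makes both arms common, and it is
  config-exposed). The draw is made per SRH response.
* **Symptom surveys** grade items 0–3. Any grade ≥ 2 opens a follow-up
  chain re-prompting every 3 days — anchored to the previous prompt's
  issue time, so chain spacing is exactly 3 days — until a response has
  all grades ≤ 1. A follow-up that expires without a response closes the
  chain: with no data there is no evidence of an open episode.
* **Scale sessions** weekly from deployment start, available 48 h.
* Every prompt expires 48 h after issue, inclusively: completion at
  exactly +48 h counts. Uncompleted past expiry, a prompt becomes
  `device_failed` when a logged device-failure event overlaps its window
  (matched to the failed device's modality), otherwise `expired`.
  Completions recorded after expiry are rejected with an audit note.
* Uncompleted SRH and scale prompts emit exactly one reminder instance
  at +24 h, counted as its own scheduled instance — matching how
  deployed platforms count reminder/duplicate prompts. Watch prompts do
  not remind: initiation is a single act on the device.

`run_simulation()` drives a cohort through these rules with a behavior
model: per-modality completion probabilities, a watch device-failure
probability, and SRH following an ordinal random walk with configurable
downdrift. Defaults are the rates observed in the 12-week pilot the
packaged fixture transcribes — SRH 0.86, symptom 0.87, scale 0.83, watch
initiation 0.74 with device-failure probability 0.13 ≈ 8/62 — and a
start level of "very good" (the pilot cohort was 80% good-or-better at
baseline). Randomness uses one named substream per participant per
purpose (scheduling, selection, behavior), all derived from the run
seed, so editing one knob never shifts unrelated draws. The ledger
invariant `scheduled = completed + expired + device_failed` is asserted
on every simulated ledger.

## Engagement accounting

Two adherence notions are kept strictly apart and both reported:
**end-to-end completeness** is completed/scheduled with device failures
in the denominator; **participant-attributable adherence** removes them
(completed/(scheduled − device-failed)). On the packaged pilot fixture
these give the watch 40/62 = 65% end-to-end and 40/54 = 74%
participant-attributable.

Engagement is judged per 28-day block anchored at each participant's
deployment date: all modalities pool into one fraction per block (the
prespecified criterion counts "prompted tasks", not tasks per modality;
a per-modality breakdown is also emitted), device-failed prompts are
excluded from the block denominator — engagement measures participant
behavior, not hardware — and a block is met at ≥ 50%, inclusive. The
study criterion requires ≥ 6 of 10 participants to meet every block. A
final partial block is dropped when its scheduled prompts span under 7
days, so a straggler week cannot fail a participant on its own.

Printed percentages round half-up to integers throughout
(`round_half_up()`), because that is the rounding that reproduces every
published figure from the underlying counts (e.g. 46/53 → 87, not 86);
it is exposed as a formatting option. The System Usability Scale is
scored as `2.5 × Σ(odd items − 1, 5 − even items)`, 0–100, no
imputation. Geriatric-assessment change flags implement the prespecified
thresholds exactly: G8 decline ≥ 1, CARG increase ≥ 1, CIRS-G increase
≥ 1, any G8-SRH downgrade, FACT-G decline > 3 (a decline of exactly 3
does not flag); instruments missing at either timepoint are recorded
unevaluable rather than guessed.

## Synthetic data: what it emulates, and what it does not

`generate_accel()` renders scripted days at 10 Hz from three segment
kinds. *Gait* is a two-harmonic waveform on the gravity axis,
`1 + A(sin 2πft + 0.3 sin 4πft)` with `f = cadence/60` Hz, plus smaller
phase-shifted components on the other two axes (arm swing) and Gaussian
noise — one fundamental period per step, so the true count is
`floor(duration × f)` by construction. *Stationary wear* is gravity plus
8 mg noise plus a brief 0.3 g two-axis wrist fidget every 90 s: without
the fidgets, worn-but-quiet time would be indistinguishable from
non-wear under any variance rule, and the 90-s spacing still leaves
≥ 60-s quiet stretches for calibration. *Non-wear* is gravity plus 2 mg
noise, below every threshold. Output is deterministic per seed.

What passing tests on this generator establish: the detector recovers
regular gait at 60–140 steps/min within ±5%, the non-wear rule equals
its brute-force definition, the metrics follow their closed forms, and
the whole pipeline composes correctly. What they do not establish:
performance on real wrist data — shuffling gaits, pushed wheelchairs,
arm-only activity, device reorientation, missing-sample bursts and
individual gait variability are all absent from the generator. The
two-harmonic waveform was chosen over recorded gait traces precisely to
keep ground truth closed-form and the package free of external data;
hardware-specific validation needs hardware.

`generate_cohort()` builds the behavior configs for the prompt
simulation; the packaged fixtures (`pilot_prompt_counts()`, and the
synthetic per-participant split of the full-deployment watch counts in
`watch_full_deployment()`) anchor the accounting to published totals.

## Problem sizes and numerical choices

The test suite and acceptance script run on: 60-s gait bouts at four
cadences embedded in ~5-min records; non-wear oracle records of 4–6 h;
a scripted ~6.5-h "day" for end-to-end recovery; 24-h closed-form epoch
series for the Activity Index; 1,000 seeded SRH schedules plus 25 full
cohort simulations (3 participants, 56 days) for the scheduler laws; and
one 10-participant, 84-day simulation. These sizes were chosen so every
property that scales (recovery rates, oracle equality, conservation
laws) is exercised at a size where a violation would already be visible.

Numerical details: epoch SDs use the n−1 denominator with single-sample
epochs reported as 0; percentile interpolation is the standard linear
type; LWB ties break to the earliest bout; the band-pass is a 2nd-order
zero-phase Butterworth; FFT features use the DC-removed spectrum of full
windows only, with trailing partial windows labelled not-moving.

## Known limitations

* The non-wear/quiet-wear boundary blurs by up to one sub-block per side
  (see above); totals on mixed records are conservative, not exact.
* The moving/not-moving rule is threshold-based; cadences outside
  0.6–2.5 Hz (shuffling below 36 steps/min, running above 150) are out
  of band by design.
* The behavior model is memoryless per prompt; real participants
  cluster their non-adherence. The simulation is a scheduler testbed,
  not a forecast.
* Scale readings and impedance are recorded as raw values only; body
  composition analytics are out of scope.
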
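# remotewear

Analytics for remote, wearable-based monitoring of mobility and frailty
in older adults. The package takes the three data streams such a
platform produces — raw 10 Hz wrist accelerometry, a ledger of prompted
tasks (health surveys, symptom surveys, smart-scale sessions,
watch-monitoring initiations), and usability/geriatric-assessment
instruments — and turns them into the quantities a feasibility study
reports: frailty-aligned mobility metrics per valid 24-h interval,
end-to-end and participant-attributable adherence, per-block engagement
against a prespecified criterion, System Usability Scale scores and
geriatric-assessment change flags.

It is written for researchers running (or simulating) symptom-triggered
home monitoring: rather than continuous wear, self-rated health (SRH)
surveys every 5–9 days decide when a symptom survey and a 48-h
accelerometry window are warranted, and every analytic step downstream
of that trigger logic lives here.

## What it computes

**Signal pipeline** (per 48-h session, split into two 24-h intervals at
the initiation time):

- counts → g conversion (±8 g, 4,096 counts/g), 1-s epoch summaries,
  bias correction from quiet-stationary intervals with noise-floor
  clamping;
- non-wear: per-axis SD < 13 mg on ≥ 2 of 3 axes over ≥ 90 min
  (rolling 30-min sub-blocks), 15-min padding;
- steps: moving/not-moving window classification, then regularly spaced
  peaks in the 0.6–2.5 Hz band with physiologic timing constraints
  (intervals in [0.33, 1.67] s, runs of ≥ 4);
- metrics: total steps; cadence as the 90th-percentile steps/min over
  stepping minutes; longest walking bout (inter-step gap ≤ 3 s, capped
  at 2 h); Activity Index
  `AI_t = sqrt(max(0, mean_axes((σ²_axis,t − σ̄²)/σ̄²)))` summed over
  daytime hours 07:00–19:00, with σ̄² the device's systematic noise
  variance;
- validity: a 24-h interval is analyzable when non-wear ≤ 1.5 h and
  steps ≥ 300 (inclusive boundaries).

**Prompt engine**: the full trigger state machine (SRH every 5–9 days →
fair/poor triggers symptom survey + watch prompt; symptom grade ≥ 2
re-prompts every 3 days until all grades ≤ 1; weekly scale sessions;
48-h expiry; one reminder instance at +24 h for uncompleted surveys),
plus a seeded cohort simulator with configurable completion behavior and
device-failure rates.

**Engagement accounting**: completeness tables per participant ×
modality with the conservation invariant
`scheduled = completed + expired + device_failed`, participant-
attributable adherence (device failures removed from the denominator),
pooled ≥ 50 %-per-28-day-block engagement with a ≥ 6-of-10 study
criterion, SUS scoring, and prespecified geriatric-assessment change
flags.

A synthetic-data generator (`activity_script()` / `generate_accel()` /
`generate_cohort()`) renders scripted gait, quiet wear and non-wear at
10 Hz with closed-form ground truth, so every pipeline stage is testable
without any participant data.

## Worked example

The package ships the per-participant prompt-completion counts of a
12-week, 10-participant home pilot as a fixture, reconstructable into a
full prompt ledger:

```r
library(remotewear)

led <- pilot_ledger()
tab <- tabulate_completeness(led)
tab[tab$participant_id == "Total", ]
#>  participant_id modality scheduled completed incomplete_participant
#>           Total      srh       126       108                     18
#>           Total  symptom        53        46                      7
#>           Total    scale       100        83                     17
#>           Total    watch        62        40                     14
#>  incomplete_device pct_completed
#>                  0            86
#>                  0            87
#>                  0            83
#>                  8            65

round_half_up(100 * participant_attributable(led, "watch"))
#> [1] 74
```

Read: surveys and scale sessions completed at 86 %, 87 % and 83 %
end-to-end; watch monitoring was initiated in 65 % of prompts, and in
74 % once the 8 prompts lost to confirmed device failure are removed
from the 62 scheduled. The 22 non-initiations decompose into 14
participant-attributable and 8 device-attributable.

The signal pipeline on synthetic gait with known truth:

```r
g <- generate_accel(activity_script(data.frame(
  kind = c("stationary_wear", "gait", "stationary_wear"),
  duration_s = c(120, 60, 120), cadence = c(NA, 110, NA)), seed = 7))
steps <- detect_steps(counts_to_g(g$raw))
c(truth = g$truth$total_steps, detected = nrow(steps))
#>    truth detected
#>      110      110
```

A command-line wrapper covers the same ground:
`remotewear process --input raw.csv --out dir/`,
`remotewear simulate --seed 7 --out dir/`,
`remotewear report --pilot --out dir/`,
`remotewear synth accel --script s.yaml --out raw.csv`.

## Scope

Hardware acquisition (Bluetooth pairing, watch firmware, tablet
services), cloud backends and clinician portals are out of scope, as are
inferential statistics on the resulting metrics — those are ordinary
model fits on the package's outputs. Body-composition analytics beyond
recording raw scale values are likewise out of scope.
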
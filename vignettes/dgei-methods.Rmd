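---
title: "The dynamic gait event identifier: model, tuning and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The dynamic gait event identifier: model, tuning and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitdgei)
```

## The signal and the model

The detector consumes a single uniformly sampled channel from a
shank-mounted inertial sensor — the sagittal-plane tibial orientation,
nominally at 60 Hz. In this channel a gait cycle shows one dominant pulse
peak at toe-off (TO) and one dominant trough at heel strike (HS); standing
spans are flat apart from low-amplitude tremor. The assumptions are that
the channel is uniformly sampled (irregular timestamps are rejected, not
resampled), that each cycle contains one event of each type, and that the
slope into an event is the steepest structure of its neighbourhood.

Detection works on slope, not on raw amplitude. With
$\Delta y_k = y_k - y_{k-1}$ and rate $\Delta y_k / \Delta t$, two causal
sliding-window accumulators are kept per frame: the positive curve sums
weighted differences with $\Delta y_k > \mathrm{bar}$ over the last
$w + 1$ frames, the negative curve those with $\Delta y_k < -\mathrm{bar}$
(an alternative `verbatim` indicator mode gates the negative branch on
$\Delta y_k \le \mathrm{bar}$, the exact set complement; it is retained
and tested, but with $\mathrm{bar} > 0$ it routes small positive changes
into the trough accumulator, so magnitude gating is the default). The
balance weights $\alpha$ and $\beta = 1 - \alpha$ trade the immediate
change against its rate; they are re-estimated at every frame from the
stream seen so far, $\alpha = \sigma_{\Delta y} / (\sigma_{\Delta y} +
\mu_{\Delta v})$, so the package is causal end to end. Because a
whole-recording estimate would not be, the running estimate is the
default and a `fixed` mode accepts precomputed constants for offline
replication. $\mu_{\Delta v}$ uses the mean *magnitude* of the rate: a
signed mean is approximately zero on any symmetric signal, which would
push $\alpha$ to 1 regardless of the data; the signed variant remains
available as a switch.

Because the accumulators track slope, their extrema occur at or slightly
before the raw extrema — the curves "see the peak coming" as the rise
decelerates. The package keeps that anticipatory lead as the *decision*
time but stamps the reported event at the raw-signal extremum within
$\pm w$ frames of the curve candidate (`refine = TRUE`). This is what
aligns reported frames with human annotations, which mark the
biomechanical extremum, while the lead remains available to downstream
controllers via the candidate frame in the state log.

## Decision rules

Curve extrema become events through three gates, applied in a single
forward pass:

* **Adaptive threshold.** A candidate's curve magnitude must exceed 60%
  of the positionally weighted mean (weights $1..q$ toward the newest
  entry) of the last $q$ accepted peak amplitudes; until the first
  acceptance the floor `threshold0 = 0` applies, so the first genuine
  peak seeds the queue and a cold start cannot deadlock.
* **Weighted sleep time.** After an accepted event, same-type candidates
  are suppressed while closer than the current sleep time: the weighted
  mean of the last $q$ stride intervals, scaled by `sleep_margin = 0.9`
  and clamped below by `sleeptime0 / 2`. The margin matters: a refractory
  equal to the *mean* stride would reject every below-mean interval of a
  naturally variable gait, so the refractory is set at the shortest
  credible stride instead. The cold-start value `sleeptime0` (the tuned
  hyperparameter) is applied literally, without the margin.
* **Alternation.** A candidate whose type equals the last accepted event's
  type is rejected (`soft` mode); `off` disables the rule for gaits where
  events drop out and strict alternation would cascade misses.

Two further choices keep the state machine honest:

* **Baseline hysteresis.** A new curve extremum is valid only after the
  curve has returned to the baseline since the previous one. Without
  this, sub-percent drift of the running $\alpha$ turns the flat top of
  one excursion into several strict local maxima, each re-entering the
  validation queue.
* **Cadence tracking from candidates.** The interval queue is fed by the
  spacing between successive *above-threshold candidates*, not only
  accepted events, gated to gaps shorter than `cadence_cap = 1.75` times
  the sleep time in force. Both halves are load-bearing. If only accepted
  intervals fed the queue, the refractory could never shorten: every
  accepted interval is at least the current sleep time, so the weighted
  mean could only ratchet upward, and a cadence increase would halve the
  detection rate forever. And without the gap gate, the two-stride
  interval that follows any missed event would enter the queue and lock
  the refractory onto a multiple of the true stride. 1.75 sits midway
  between one and two strides; sub-threshold (tremor) candidates never
  touch the queue.

Walking starts and pauses are quiescence-derived: WS at the first
validated event of the stream and at any validated event preceded by at
least `ws_quiet_frames = 120` quiet frames (2 s); WP stamped at
`last_event + 2 × sleeptime` whenever that span passes with no validated
event, including a trailing stand. Sub-threshold tremor cannot reach this
stage, so standing never produces starts.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `window_w` | 10 | frames | accumulator window (~167 ms at 60 Hz); also the refinement half-width |
| `bar` | 9 | degrees/frame | indicator threshold and candidate baseline; grid-tuned |
| `sleeptime0` | 60 | frames | cold-start refractory (one stride at 60 Hz); grid-tuned |
| `threshold_fraction` | 0.60 | — | fraction of the weighted peak mean a candidate must clear |
| `queue_len_q` | 5 | events | weighted-queue capacity; adapts within a few strides |
| `sleep_margin` | 0.9 | — | shortest-credible-stride allowance on the adaptive refractory |
| `cadence_cap` | 1.75 | — | single-stride plausibility gate on queue admissions |
| `ws_quiet_frames` / `wp_quiet_multiplier` | 120 / 2 | frames / — | quiescence rules for WS and WP |

The defaults `sleeptime0 = 60`, `bar = 9` are the operating point selected
by the grid-search module (0–100 × 0–30, step 1) on annotated input; the
package's own profile test shows the sensitivity-optimal sleeptime band
ending exactly at the stride period, since a refractory longer than one
stride must reject events until the queue adapts.

## The synthetic generator

No public recordings accompany the method, so the generator is the
package's test bed and defines its study conditions. Each cycle is a
smooth composite of a raised-cosine pulse (TO, at 30% of the cycle) and an
equal-depth trough (HS, at 70%) with zero endpoints; both features are
asymmetric — a steep edge of 8% of the period into the extremum, a gentle
30% recovery — as the tibial channel is around push-off. The asymmetry is
not cosmetic: with symmetric features the trough's recovery is as steep as
the pulse's rise and fires the positive accumulator a second time per
cycle. Reference conditions are a 60-frame (1 s) stride at 30° amplitude;
scenario kinds vary period, amplitude, jitter and noise (fast 40-frame
cycles at 36°, turning 70 at 27°, shuffling 50 at 15°, a pathological kind
with 12%/20% jitter, 10% dropped pulses and heavier noise, and a static
kind that emits only baseline plus sparse 3-frame tremor bumps below 0.28
of the standard amplitude). Scenarios are spliced with a 5-frame linear
cross-fade, and every draw happens inside an isolated RNG scope under the
spec's seed, so identical specs are byte-identical and the caller's RNG is
untouched.

What the generator does *not* emulate bounds what green tests show:
sensor drift and orientation error, left/right asymmetry, double support
variability, surface changes, and real tremor spectra are all absent. Two
regime effects are worth knowing. With amplitude 30 and `bar` 9 the
indicator cuts mid-edge, so the accumulated peak value varies by tens of
percent under 5% amplitude jitter and the 60% rule occasionally rejects a
genuine event; together with the literal cold-start refractory (which
costs about one stride when the first jittered interval falls below
`sleeptime0`), jittered synthetic detection rates sit a few points below
the near-perfect clean-loop figures. Passing tests therefore demonstrate
the method's mechanisms — adaptation direction, specificity, exactness of
clean recovery — not field accuracy on clinical data.

## Numerical choices

* Frames are 0-based; `time_s = frame / sample_rate_hz`. Difference
  index $k$ corresponds to signal frame $k$.
* Window warm-up: frames before $w$ use the growing partial window from
  the signal start, and the running $\alpha$ holds 0.5/0.5 for the first
  $w$ differences; the detector is causal from the second sample.
* The window bound $i - w .. i$ is inclusive ($w + 1$ terms), documented
  because the summation bounds admit either reading.
* Degenerate statistics ($\sigma_{\Delta y} + \mu_{\Delta v} \le 0$, e.g.
  a constant signal) fall back to $\alpha = \beta = 0.5$; on such signals
  both accumulators are identically zero anyway.
* Batch and streaming paths are bit-identical, not merely close: the
  batch cumulative sums round to double at every step (base `cumsum`
  accumulates in extended precision, which broke byte-equality with the
  online stepper), and the streaming candidate scan replays the same
  run-length/hysteresis logic with an ordering guard so validation sees
  candidates in frame order with the toe-off-first tie-break.
* Plateaus of exactly equal curve values yield one candidate at the
  plateau's first frame; refinement ties resolve to the earliest frame.
* Event matching is the optimal one-to-one assignment (maximum pairs,
  then minimum total absolute error) computed by a non-crossing dynamic
  program over the two sorted streams — for time-ordered point events an
  optimal matching never crosses, so the DP is exact. A nearest-first
  greedy pass was considered and rejected: on tie chains such as truth
  (0, 6) vs detections (5, 7) at tolerance 5 it strands a feasible pair.
* True negatives for the MCC are counted as event-free bins of one median
  stride: MCC needs a negative class that point events do not define.
  Continuous walking has no empty bins, so its MCC is 0 by convention;
  streams with standing spans get a meaningful value. A user-supplied TN
  count overrides the convention.
* Detection rate uses the ±5-frame matching; sensitivity is computed at
  the stricter ±3 frames. Both tolerances are arguments.

## Problem sizes

The test suite and acceptance script run at desk scale by choice: clean
loops use 20 cycles (1200 frames), the static specificity stream 2400
frames, the oracle-equivalence sweep 200 random signals of 50–500 frames,
the matching-optimality sweep 500 instances of up to 8 events per side,
and the full 101 × 31 grid runs on a 200-frame fixture (3131 detector
runs, under a minute serially). These sizes exercise every code path
while keeping the whole suite in the low minutes.

## Known limitations

* The four events are the entire vocabulary: no stance/swing durations,
  no left/right disambiguation, no multi-sensor fusion.
* HS is detected on the negative accumulator only; a channel whose
  heel-strike signature is not a trough needs re-mapping before input.
* The quiescence rules for WS/WP are an interpretation — the event types
  are standard, but no reference algorithm exists for them within this
  framework — and their constants (2 s quiet, 2× sleep time) are
  conventions fixed here.
* Recordings with irregular timestamps are rejected; resampling is out of
  scope.
* The `verbatim` indicator mode reproduces the printed equations exactly
  and is kept for comparability, but it mixes small positive changes into
  the trough accumulator and is not recommended for detection.
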
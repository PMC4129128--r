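---
title: "Recognising activities of daily living from ambient sensor streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognising activities of daily living from ambient sensor streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adlsense)
```

## The problem

Monitoring how well a person copes with activities of daily living (ADL) —
sleeping, grooming, toileting, getting ready for bed, cooking, eating,
watching TV and seated activity — is a core question in the care of older
adults and people with dementia. Questionnaires are unreliable; cameras and
microphones are intrusive; body-worn sensors demand compliance. The
alternative modelled by this package is a fully ambient deployment: one
small wireless sensor box per room, mounted about 2 m high, plus one box on
the kitchen fridge door and one on the bathroom flush handle. Every box
samples five channels at 0.2 Hz — temperature (°C), absolute humidity
(g/m³), luminance (lx), binary passive-infrared (PIR) motion, and an
acceleration magnitude (m/s²) — and radios each sample to a central unit as
a data packet protected by an even-parity bit.

`adlsense` implements the complete processing chain of such a system, and —
because no recordings of the original deployment are publicly available — a
synthetic single-occupant home simulator that serves as its closed-loop
benchmark.

## The processing chain

**Sorting.** Incoming packets are first routed to their origin compartment
by a bucket sort (one stable pass over the packet stream; each room is one
bucket), then each bucket is ordered chronologically by a
least-significant-digit radix sort over a five-component time key:
second-of-minute, minute, hour, day-of-month, month. Both stages are stable
and linear-time; neither calls a comparison sort, and the test suite checks
them against a comparison-sort oracle on random instances up to $10^5$
packets. Packets whose parity check failed are excluded before sorting and
surface in the transmission-integrity report
(`reliability = 100 · captured / (captured + lost)`), never silently
dropped. The five-component key covers streams within one calendar year;
multi-year archives would need a year digit, which the 20-day recordings the
system targets never require.

**Segmentation.** The engine needs "potential ADL" windows to reason about.
Candidates are maximal presence episodes per compartment: PIR-active samples
of any box in the room are merged while gaps stay within a tolerance
(default 120 s), and episodes shorter than 60 s are discarded. The PIR
model's hold time (10 s) plus this tolerance set a floor on the motion
density observable inside any surviving window — roughly 0.1–0.25 even
while the resident sleeps — which is why the default rulebase bounds motion
density well above the raw movement rate of a sleeping person (see below).

**Ambient value matrix and features.** For each candidate a channels ×
samples matrix is assembled from the sorted streams of the room's boxes
(wall box, plus the appliance box in kitchen and bathroom); samples missing
to packet loss are masked, not interpolated. The feature vector is
deliberately simple and deterministic: duration; robust channel deltas
(difference of the medians of the first and last 30 s); luminance range and
mean; motion density; the number of acceleration transients on appliance
boxes (excursions 1.5 m/s² above the box median separated by ≥ 10 s); and
time-of-day.

**Rules and forward chaining.** Behavioural knowledge is declarative: each
rule names a target ADL, a compartment scope, duration bounds, a conjunctive
predicate list over the features, an optional prior-fact requirement and a
unique priority. A parser turns the JSON rule file into the validated
in-memory look-up table the engine uses. Inference is data-driven forward
chaining: in each pass every unlabelled candidate is tested against the
rules; when several rules are satisfied, conflict resolution picks the rule
defined first (smallest priority number); each new classification is
appended to the fact database, so fact-dependent rules can fire in later
passes — getting ready for bed needs the adjacent sleeping fact, eating may
need the preceding cooking fact. The run stops at a fixpoint or after
`max_iterations` (default 5) passes, with a warning and the partial result
in the pathological case. The database is append-only, so the iteration is
monotone and terminates.

The worked example is toileting: a bathroom candidate of a few minutes with
the light on, one flush-handle transient, and humidity and temperature that
do not change significantly. A long bathroom candidate with a humidity rise
≥ 3 g/m³ is grooming (the shower); both rules can be in scope and priority
resolves the conflict in grooming's favour.

**Evaluation.** Ground truth comes from a protocol device (one switch per
ADL) merged with paper-logbook corrections (`add`, `delete`, `relabel`,
`retime`, applied in file order; the merged log must keep same-label events
non-overlapping). Classified events are correlated with truth by greedy
one-to-one event matching in time order: a truth event is recovered if a
same-label classified event overlaps it by at least 50% of the shorter
event. Per ADL, sensitivity is `100·TP/(TP+FN)` and specificity
`100·TN/(TN+FP)` with a one-vs-rest negative universe (truth events of
other labels; an epoch-based mode is available as an alternative). Overall
figures are unweighted (macro) means of the eight per-ADL percentages —
the aggregation that reproduces a published overall value from published
per-class rows. Activity maps bin each day into 5-minute slots labelled by
majority coverage; the regularity score is the mean day-to-day bin
agreement.

## The synthetic benchmark

The simulator emulates the study conditions the system was deployed under:
single-occupant homes, a 5-room two-bedroom layout with 7 boxes, and about
6.6 protocolled ADL per day. Per-ADL daily rates are taken from the
deployment's event counts over 200 subject-days (toileting 1.5/day, TV
1.6/day, cooking 0.35/day, grooming 0.7/day, …); they are the generator's
defaults, not tuning knobs. Routines are sampled as Bernoulli slots at
preferred times (meals, TV sessions, morning grooming), truncated-Poisson
daytime toileting, a nightly sleeping block with optional pre-bed hygiene
ending 2 min before sleep onset, and cooking-linked eating after a 4–10 min
lag. Start times are jittered with SD `jitter_sd · (1 − structure_level)`;
at `structure_level = 1` the generator is fully deterministic and every day
is identical. A minimum inter-event margin (600 s) and a post-shower
bathroom cooldown (1800 s, matching the humidity decay constant) keep
events separable — without them, two bathroom visits inside one motion
episode would be indistinguishable for any event-level classifier.

Emission physics is intentionally minimal but parametric: a half-sine
outdoor luminance curve attenuated per room (the bathroom is effectively
windowless), lamps that switch on for active occupancy in the dark, a TV
luminance signature (~55 lx) in the living room; shower and cooking pulses
that rise linearly over the event and decay exponentially (τ = 20 min,
shower +6 g/m³, cooking +2 °C / +1.5 g/m³); movement bouts whose spacing
depends on the activity (every ~10 s while cooking, ~90 s while asleep)
sensed by a PIR with trigger probability 0.95 per 5 s of movement, 10 s
hold and a 10⁻⁴ false-trigger rate; and 3 m/s² transients on the fridge
door and flush handle. Channel noise is Gaussian (defaults: 0.08 °C,
0.15 g/m³, 6 lx, 0.05 m/s²). Packets are dropped independently at the
deployed system's observed loss share (0.47%) and can be bit-corrupted at a
configurable rate; a corrupted packet is represented by a failed parity
flag, which is exactly what even parity yields for any single flipped bit.

What the simulator does *not* model matters for interpreting results:
multi-occupant homes, visitors and pets, appliance heat sources other than
cooking, seasonal daylight changes, sensor drift, and any overlap or
ambiguity between activities beyond what the eight mutually exclusive
definitions allow. Passing the closed loop therefore shows the chain is
internally consistent and recoverable under the stated physics — not that
the rulebase would transfer unchanged to an arbitrary real home.

### The closed-loop oracle

With sensing made deterministic — channel noise SDs 0, PIR trigger
probability 1, false triggers 0, no packet loss — every simulated activity
must be recovered exactly: all per-ADL sensitivities and specificities are
100% and there are no false positives. The acceptance suite runs this on 3
homes × 5 days. The headline benchmark then restores all stochastic
defaults (noise, PIR randomness, 0.47% loss) and runs 10 homes × 5 days
under seed 42; its macro sensitivity and specificity must clear the real
deployment's published figures (91.27% / 92.52%), which a clean synthetic
benchmark comfortably does. Problem sizes (5 days rather than the study's
20, 10 homes) keep a full run in tens of seconds while every ADL still
occurs dozens of times.

## Calibration and numerical choices

The original deployment's rule parameters were never published, so the
shipped rulebase (`inst/extdata/rules.json`) is calibrated to the default
emission model and documented as configuration, not as a claim about the
original system:

- **Motion-density bounds.** A sleeping resident produces a movement bout
  every ~90 s; with the 10 s PIR hold this yields an observable density
  near 0.2 inside a single candidate window, and any lower movement rate
  would split the night into sub-minute fragments that segmentation
  discards. The sleeping rule therefore allows density ≤ 0.35 and relies on
  darkness, duration and the bedroom scope for discrimination; TV allows
  ≤ 0.6; quiet kitchen/living presences ≤ 0.95 (the high-activity states
  saturate at 1.0).
- **"Lit room" instead of "luminance change".** A candidate window opens at
  the first motion sample, when the lamp is typically already on, so a
  within-window range would miss the switch-on edge; the rules test mean
  luminance ≥ 25 lx instead. The range feature is still computed.
- **Disjunctions.** Predicates within a rule are conjunctive; alternatives
  are separate rules at distinct priorities (e.g. a lower-priority "dry
  grooming" rule for long lit bathroom stays without the shower humidity
  signature).
- **"Does not change significantly"** is operationalised as fixed
  per-channel thresholds on 30 s median-endpoint deltas (|Δhumidity| <
  2 g/m³, |Δtemperature| < 1 °C for toileting), not statistical tests: the
  engine is a parameterised look-up, not an estimator.
- **Ties and degenerate inputs.** Conflict resolution is strictly by unique
  priority; activity-map bin ties go to the earlier-starting event; empty
  denominators yield `NA` ("undefined"), never 0; a candidate window with
  no surviving samples is an error, not an empty feature vector.
- **Time model.** Date plus integer seconds-of-day on the 5 s grid, no time
  zones or DST; event times are absolute seconds from day 1, 00:00, so
  nights cross midnight without special cases.

The humidity unit follows the deployed part list's documentation (absolute
humidity, g/m³) even though the named sensor family reports relative
humidity; nothing in the chain depends on the distinction beyond the
thresholds' units.

## Presets

`alzheimer_profile()` provides a qualitative low-structure preset —
`structure_level = 0.3`, fragmented night sleep with nocturnal bathroom
visits, more toileting — to reproduce the contrast between a regular and a
disrupted routine on activity maps. Its only tested claim is ordinal: its
day-to-day regularity score is strictly lower than the default profile's
under the same seed. No clinical interpretation is attached.

## A worked run

```{r, eval = FALSE}
library(adlsense)
bench <- run_benchmark(n_homes = 10, n_days = 5, seed = 42)
bench$metrics
bench$integrity
```

`run_pipeline(out_dir, ...)` performs the same chain and writes per-home
event CSVs, pooled metrics, the transmission-integrity report and a
manifest sufficient to reproduce the run; `scripts/acceptance.R` wraps the
benchmark for reproduction from the command line.
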
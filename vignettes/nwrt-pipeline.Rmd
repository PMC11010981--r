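---
title: "Closed-loop NWR threshold tracking: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop NWR threshold tracking: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nwrtsim)
```

## The problem

The nociceptive withdrawal reflex (NWR) is a polysynaptic spinal reflex: a
noxious electrical stimulus applied over a peripheral nerve evokes a
withdrawal contraction that can be read from the EMG of a flexor muscle.
The NWR *threshold* (NWRt) — the lowest stimulation current that evokes the
reflex with 50% probability — falls as nociceptive excitability rises and
climbs as anesthesia deepens, which makes its continuous tracking a
candidate complement to EEG-based depth-of-anesthesia monitoring,
particularly in pigs, where validated depth indices are scarce.

`nwrtsim` implements the whole closed loop in software: a synthetic subject
(drug kinetics, psychometric response, EMG trace synthesis, EEG suppression
ratio), the adaptive staircase that hunts the threshold, the per-trial
reflex detector, the logistic threshold readout, a session runner that
executes a stepwise propofol dose-escalation protocol, and the group-level
statistics. Every stage can therefore be exercised, audited, and re-run
with no animal data — and the statistical pipeline applies unchanged to
recorded session logs.

## The synthetic subject

### Drug model

Propofol dosing (IV boli in mg/kg and a piecewise-constant infusion in
mg/kg/h) drives a one-compartment model with first-order elimination `ke`
and a first-order effect site `ke0`:

$$C_p' = \frac{u(t)}{V} - k_e C_p, \qquad C_e' = k_{e0}\,(C_p - C_e).$$

The system is linear, so `effect_site()` evaluates the superposition of
bolus impulse responses and infusion step responses in closed form — no
numerical integration, hence no step-size artifacts; the test suite checks
the closed form against an independent `deSolve` integration. With per-kg
dosing the body mass cancels from all concentrations.

This is *not* a claim about porcine pharmacokinetics. The model is the
simplest one producing the qualitative features the protocol needs — a
bolus peak with a lag between plasma and effect, near-steady behavior under
constant infusion — and all rate constants are configuration, not biology.
No pharmacokinetic sampling stands behind the default values; they were
fixed once, by simulating the default protocol and keeping the cohort
summaries inside the ranges reported for this preparation (awake threshold
near 7 mA, first interval means near 17–21 mA, final interval means near
29–32 mA, escalation phase nominally ~45–90 min with at least four dose
increments, induction dose on the order of 10–14 mg/kg):

| parameter | default | units | role |
|---|---|---|---|
| `V` | 2 | L/kg | apparent distribution volume |
| `ke` | 0.085 | 1/min | elimination rate (plasma half-life ≈ 8 min) |
| `ke0` | 0.35 | 1/min | effect-site equilibration (lag ≈ 2–3 min) |
| `T0` | 7.2 | mA | awake reflex threshold |
| `k_thr` | 4.5 | mA per µg/mL | threshold gain with effect-site concentration |
| `beta` | 2 | 1/mA | psychometric slope |
| `sr50` | 7.2 | µg/mL | concentration at 50% suppression ratio |
| `sr_slope` | 1.2 | per µg/mL | steepness of the suppression-ratio sigmoid |

### Threshold link and psychometric function

The true threshold is linear in the effect-site concentration,
`T(Ce) = T0 + k_thr * Ce`. A saturating (Emax-type) link would express a
ceiling effect; the linear form was chosen because the pipeline's own
summary statistic — a straight-line fit of threshold on time interval — is
the quantity under study, and a linear generator makes its target
unambiguous. Response to a stimulus of intensity *I* is Bernoulli with

$$P(\text{reflex}) = \frac{1}{1 + e^{-\beta (I - T)}},$$

so the 50% point *is* the true threshold by construction.

### EMG traces and their limits

`generate_trace()` returns a stimulus-locked trace on (by default) a
[−150, 150] ms window at 1 kHz: zero-mean Gaussian background noise
(`noise_sd`, 2 µV default); with the psychometric probability, a reflex
burst — a 20 ms half-sine envelope modulating Gaussian noise, rescaled to a
fixed absolute peak `reflex_amp` (30 µV default) at a latency drawn
uniformly in 50–120 ms, so the burst sits strictly inside the 40–140 ms
reflex window; and, with probability `p_artifact`, a rectangular 20 µV /
10 ms excursion in the pre-stimulus noise window, the minimal event that
trips the 15 µV artifact rule.

The generator reproduces exactly the features the detector measures —
window membership, amplitude relative to background, pre-stimulus
artifacts — and nothing else. Real EMG has colored noise, variable burst
morphology, movement artifacts that invade the reflex window, and
stimulation artifacts; none of these are emulated. Passing tests therefore
validate the *logic* of detection, tracking, estimation and analysis, not
the detector's operating characteristics on real recordings. The
requirement `reflex_amp > 10 * noise_sd` keeps true bursts above the
Z-score criterion so that the trial-level response probability equals the
psychometric probability up to binomial noise (verified at n = 2000 per
intensity in the suite).

## Reflex detection

All windows are half-open `[lo, hi)` in ms relative to stimulus onset:
noise `[-130, -10)`, reflex `[40, 140)`. A sample at exactly +40 ms is in;
one at exactly +140 ms is out. Fixing one convention (and testing its
edges) matters more than which convention is fixed.

A trial is invalid when the raw absolute amplitude strictly exceeds 15 µV
anywhere in the noise window (a device-style artifact rule; exactly
15.0 µV passes), or when the noise window has zero variance — a degenerate
case only synthetic input can produce, marked invalid rather than allowed
to yield an infinite Z-score. Valid trials are scored by the interval peak
Z-score

$$z = \frac{\max_{t \in [40,140)} \left| x(t) - \bar{x}_{\text{noise}} \right|}{\mathrm{sd}_{\text{noise}}},$$

positive when `z > 10` (strictly). Measuring the peak as the absolute
*deviation from the noise mean* makes `z` exactly invariant to constant
offsets and to rescaling, which the suite asserts; the amplitude reading is
otherwise the conventional absolute peak. Invalid trials are discarded:
they never reach the staircase or the estimator, and the stimulus is
repeated at the same intensity.

## Staircase and threshold readout

The bracketing controller starts at 1 mA: a negative response raises the
intensity, a positive one lowers it, by 0.3 mA — enlarged to 0.5 mA for the
first change after the last three changes ran in the same direction, and
for as long as that run continues; any reversal restores 0.3 mA. Two
points the protocol leaves open are fixed as follows: the enlarged step
applies to the change *after* three completed same-direction changes (four
consecutive negatives from 1.0 mA give 1.3, 1.6, 1.9, then 2.4 mA), and the
intensity is clamped below at 0.3 mA (one step above zero; negative
currents are meaningless) and above at a configurable 60 mA safety cap.
Stimuli repeat nominally every 10 s with 50% interval randomization, taken
as uniform on [5, 15] s — the standard jitter reading when no distribution
is stated.

After every valid stimulus, once 12 valid trials exist, `estimate_nwrt()`
fits a Bernoulli likelihood logistic to the last 12 and reads the threshold
at the 50% point. Twelve-point staircase windows are small and
concentrated near threshold, so degenerate configurations are routine and
need explicit rules, all flagged in the output's `method` column:

* **Perfect separation** (every negative below every positive): the
  likelihood has no finite maximizer and the 50% point is taken as the
  midpoint between the highest negative and the lowest positive intensity.
  At a large finite slope the likelihood's optimum approaches exactly this
  midpoint, so the rule is the separation limit of the ML fit, not an ad
  hoc patch.
* **All-same-response windows**, reversed separation, non-increasing
  fitted slopes, and fits whose 50% point falls outside the window's
  intensity range all carry no usable crossing information: the previous
  estimate is carried forward. Before the first crossing of a session the
  estimate is simply undefined (warm-up).

The ML route itself is iteratively reweighted least squares
(`stats::glm.fit`); the suite cross-checks it against an independent
coarse-grid likelihood maximizer (agreement within 0.1 mA) and against
parameter recovery from windows drawn at a known threshold.

From a cold 1 mA start against a fixed threshold *T*, the first positive
response cannot occur before roughly `3 + (T - 1.9)/0.5` trials — the
staircase must climb the whole distance in 0.3/0.5 mA steps — and no
estimate exists before the first positive. Convergence-time expectations
for distant thresholds must respect that arithmetic floor: the tracked
intensity reaches *T* ± 1 mA within the bracketing bound
`⌈(T−1)/0.3⌉ + 6` trials for all tested thresholds (3–30 mA), and the
readout settles within ±0.5 mA a few trials after the first reversal.

## The session protocol

`run_session()` executes: a 10 min awake baseline recording; induction
with a first bolus of 4–5 mg/kg, top-ups of 0.5–1 mg/kg every 30–60 s, and
a parallel infusion at 20 mg/kg/h started with the first bolus; intubation
as soon as the effect-site concentration reaches `ce_intub` (3.4 µg/mL
default — intubation readiness is modeled as a concentration threshold
because only its timing and dose consequences matter downstream); a 15 min
stabilization wait; then +6 mg/kg/h and a 0.5 mg/kg bolus every 10 min
until the suppression ratio has sat inside 10–30% for 10 consecutive
minutes (sampled at 1/min, endpoints included, window restarted by any
excursion; the first sample window admissible is the one starting at the
end of stabilization), at which point the infusion stops. A 150 min safety
cap ends escalation if the stop rule never fires. The suppression ratio is
generated directly as a sigmoid summary number — no EEG waveform is
synthesized.

All randomness in a session flows from one `set.seed()` at entry, consumed
in a fixed order (protocol draws first, then the stimulus stream), so runs
are bit-reproducible; `audit_session()` re-derives the demanded schedule
from the logged events and verifies the executed one against it. Cohorts
(`simulate_cohort()`) redraw `T0` and `k_thr` per subject from log-normal
spreads truncated at ±2 sd — untruncated tails could put a subject's awake
threshold beyond what the staircase can reach before the baseline window —
and reuse the same subject parameters across days (test–retest design)
with distinct derived seeds.

## Analysis

Per session: the baseline is the mean of estimates in `[-5, -4)` min
before the first bolus; the span from end-of-stabilization to
end-of-infusion is cut into five equal time intervals (TI1–TI5, half-open
bins, last bin closed) normalizing sessions of different length to
comparable depth stages; the per-TI mean thresholds are regressed on the
interval index by ordinary least squares, giving the slope `b1` in mA per
TI. The "Intubation" row of the cohort table is the *mean* estimate
between first bolus and intubation — a convention, since a peak-based
reading is equally defensible; on a fast induction this mean is dominated
by tracker lag and sits well below the transient threshold peak, which is
worth remembering when comparing it across studies. Cohort rows report
medians with 25/75 percentiles (linear interpolation between order
statistics, R's default type 7).

`friedman_rm()` compares baselines and slopes across days: within-subject
ranks, the tie-corrected statistic against χ²(k−1), and — because the
panels here have 4–6 subjects — an exact permutation p over all `(k!)^n`
within-row orderings. Incomplete subjects are dropped (complete-row
deletion is the only missing-data policy; `simulate_cohort(drop_one =
TRUE)` exercises it). Fully tied panels return statistic 0 and p = 1. On
random 5 × 3 panels the χ² p can differ from the exact p by up to ~0.1 in
the mid-range while agreeing closely below 0.2 and never disagreeing about
significance at the 5% level in the tested draws — reporting both is the
point.

## Problem sizes and verification scale

The suite validates the detector against a shared-nothing brute-force
implementation on 10 000 random traces, estimator/grid agreement on 200
twelve-trial windows, slope recovery on 20 replicate cohorts of 5 subjects
× 3 days tracking a 5 mA-per-TI ramp (with the day-wise Friedman test
rejecting at its nominal 5% rate under the null), exact Friedman
enumeration on 4 × 3 panels (1296 arrangements), and full protocol audits
on complete closed-loop sessions. `scripts/acceptance.R` runs the default
5 × 3 cohort end to end and reports the cohort medians, slopes, Friedman
p-values and protocol quantities it computes.

## Known limitations

* The drug model is a deliberately minimal linear compartment model;
  concentrations are internal state, not predictions.
* The EMG generator covers only the features the detector measures; no
  claims transfer to real recordings without validation on recorded
  traces (`detect_traces()` accepts them).
* The escalation schedule is strictly periodic; the protocol's occasional
  discretionary extra rate elevations are not modeled.
* The commercial device's estimator internals are unpublished; the
  separation and carry-forward rules here are documented conventions, and
  analyses can filter on the `method` flag where the distinction matters.
* Recovery, concomitant drugs, and physiological covariates are out of
  scope.
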
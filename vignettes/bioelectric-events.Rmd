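---
title: "Detecting bioelectric events in cyanobacterial voltage recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting bioelectric events in cyanobacterial voltage recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyanospike)
```

## The measurement and its signal model

Planar gold microelectrodes in contact with an *Oscillatoria* sp. biofilm
record small extracellular potential fluctuations — tens of microvolts —
produced by the ionic and redox fluxes of cohort metabolism. Under nitrogen
starvation this activity intensifies over about four days and collapses
again within one to two days of ammonium repletion. Two event classes
dominate such traces:

* **fast spikes** — transient, millisecond-scale, relatively high-amplitude
  excursions of either polarity;
* **RTS steps** — random-telegraph-signal fluctuations: the trace switches
  between two levels and dwells on each for seconds at a time.

`cyanospike` models a recording as the sample-wise sum

$$ v(t) \;=\; \underbrace{\textstyle\sum_i a_i\, g\!\left(\frac{t-t_i}{w}\right)}_{\text{spikes}}
\;+\; \underbrace{s(t)\,\Delta}_{\text{RTS}}
\;+\; \underbrace{\eta(t) + b(t)}_{\text{noise + drift}} $$

where $g$ is a unit Gaussian bell of full width $w$ (milliseconds), the
$t_i$ form a homogeneous Poisson process, the $a_i$ are log-normal with a
random sign, $s(t) \in \{0, 1\}$ is a two-state Markov process with
exponential dwell times (rates $k_\mathrm{up}$, $k_\mathrm{down}$; mean
high dwell $1/k_\mathrm{down}$), $\Delta$ is the level separation, and the
noise is white plus a $1/f$ component over a slow baseline drift $b(t)$.
The analysis half of the package inverts this model; the generator half
simulates from it.

## The synthetic six-day course

No raw recordings are publicly deposited for this system, so the package
ships a seeded generator whose defaults reproduce the reported daily
summary statistics of the six-condition course (four starvation days
`-Nd1`..`-Nd4`, two post-repletion days `NH4+d1`, `NH4+d2`); the targets
are exposed by `schedule_targets()`. Calibration is direct:

* the Poisson spike rate of each day equals that day's median per-minute
  rate (1, 2, 1, 5, 3, 1 events/min) — the medians rise to a day-4 peak and
  relax after repletion;
* the log-normal amplitude law is fitted by `calibrate_amplitude()`: the
  median is matched exactly and the log-scale spread is the least-squares
  solution through the reported quartiles,
  $\sigma_{\log} = \log(q_{75}/q_{25}) / (2\,z_{0.75})$. The reported daily
  maxima are treated as observed maxima, not fitted: with a day-4 rate
  maximum of 82 events/min against a median of 5, the upper column can only
  be an extreme-value statistic, which a 60-draw maximum reproduces in
  distribution but no quantile fit should chase;
* the RTS level separation equals the day's median amplitude, so pooled
  amplitude statistics remain centred on the reported medians.

Choices the reported summaries do not constrain, fixed once here:

* **Sampling rate 2 kHz, 3600 s per condition.** 2 kHz resolves 5 ms pulses
  with ~10 samples; an hour per day keeps a six-day simulation desk-scale.
* **RTS kinetics** $k_\mathrm{up} = 0.005\,\mathrm{s^{-1}}$,
  $k_\mathrm{down} = 0.5\,\mathrm{s^{-1}}$ on every day: seconds-scale high
  dwells (mean 2 s) appearing as intermittent excursions a few times per
  ten minutes, matching their qualitative description as occasional slow
  fluctuations rather than a dominant square wave.
* **Pulse shape**: Gaussian bell, full width 5 ms taken as six standard
  deviations. Only width and peak amplitude enter the readout, so any
  smooth unimodal template is equivalent.
* **Polarity**: positive with probability 0.5; electrode wiring sets trace
  polarity, and detection is polarity-agnostic anyway.
* **Noise floor**: white 0.2 µV, pink 0.3 µV, drift 0.5 µV/min — a
  low-noise recording in which the smallest reported amplitude quartile
  (2.5 µV) sits well above the 5-sigma detection threshold (~1 µV).

Sub-seeds are derived deterministically from the master seed (condition
$i$ uses $\mathrm{seed} + 1009\,i + \{1,2,3\}$ for spikes/RTS/noise,
modulo $2^{31}-1$), so any single condition can be regenerated alone,
bit-identically.

### What the generator does and does not emulate

It reproduces the event classes, their time scales, the reported daily
rate and amplitude quartiles, a 1/f + white noise floor, and slow drift.
It does **not** emulate electrode drift nonstationarity within a day,
mains interference, burst clustering (overdispersed spike counts), spike
waveform diversity, day-to-day correlation of a single biofilm, or any
mechanistic link between the RTS process and spiking. Passing the
recovery tests therefore demonstrates that the pipeline inverts the stated
signal model at realistic SNR — not that it is robust to every artifact of
a wet recording.

## Preprocessing

`remove_baseline()` subtracts a running median over a 60 s window — long
against both event classes, so spikes and seconds-scale dwells pass
through, while drift does not. Two implementation points matter. First,
the median is computed over short block medians (window/120 per block) and
interpolated back, which makes hour-long traces cheap without changing the
estimate. Second, the windowed median of a near-balanced two-level signal
is unstable — as the window slides, the majority level flips and the raw
running median can chatter between levels; a same-window moving average of
the median track removes that switching artifact while leaving offsets and
ramps untouched. The result has zero median by construction.

`split_bands()` separates time scales at `fc_hz = 10` — two octaves from
each class boundary (5 ms pulses vs 0.5 s dwells). The high-pass is a
4th-order Butterworth applied forward and backward (zero phase, so peak
times and amplitudes are unbiased; peak shift through the filter is under
one sample). The slow band is the exact complement, so
`fast + slow + baseline` reconstructs the input identically. A 5 ms pulse
retains ~96% of its peak in the fast band; the irreducible loss is the
pulse's own sub-10 Hz content. The forward–backward pass runs in compiled
code with odd-reflection padding of length `3 fs / fc` so start-up
transients die out outside the retained segment.

`noise_sigma()` estimates the fast-band noise scale as
$1.4826 \times \mathrm{MAD}$ — consistent for Gaussian noise and nearly
immune to a percent-level contamination by large spikes, which a plain
standard deviation is not.

## Spike detection

`detect_spikes()` thresholds $|v|$ at $k_\sigma \hat\sigma$ with
$k_\sigma = 5$, the conservative convention in extracellular
electrophysiology: at 2 kHz an hour of pure Gaussian noise yields well
under 0.2 false events per minute. Contiguous supra-threshold excursions
closer than the 20 ms refractory window merge into one event; each event
reports onset, supra-threshold extent, and peak $|v|$. The implementation
is vectorised but exactly equivalent to a sample-by-sample scan with the
same rules, and the test suite holds it to that equivalence.

Raising $k_\sigma$ cannot create events from unimodal pulses: a pulse's
excursion shrinks or vanishes, and any split within a pulse re-merges
inside the refractory window.

## RTS segmentation

`segment_rts()` fits a two-level model to the slow band:

1. **Level fit.** A two-component equal-variance Gaussian mixture is
   fitted by EM on a decimated subsample. Decimation at the slow band's
   information rate (spacing $\ge f_s / 2 f_c$) matters twice over: it
   bounds cost, and it keeps the samples near-independent so the model
   comparison below is honest. The EM is initialised from a deterministic
   two-means split seeded at the value-range extremes — a sparse high state
   (a percent of samples) is an outlier component that generic mixture
   initialisations routinely miss, while the extreme-seeded split hands it
   to the EM directly. A degenerate EM (zero within-level variance, e.g. a
   noise-free telegraph signal) falls back to the two-means partition.
2. **"No RTS" decision.** Segmentation is declared empty — a flag, not an
   error — if BIC prefers a single Gaussian to the two-component fit, or if
   the fitted separation is below twice the within-level sigma. On a pure
   Gaussian slow band an equal-variance mixture happily splits the bulk
   into two half-normals 1.6 total-sigmas apart, which the within-sigma
   rule alone does not reject; the BIC comparison does.
3. **Hard assignment** of every sample at the posterior boundary
   (midpoint shifted by $\sigma^2 \log(\pi_1/\pi_2)/\Delta$).
4. **Dwell enforcement.** Runs shorter than `min_dwell_s = 0.5` are merged
   into their longer neighbour, shortest first, ties merging backward in
   time — a deterministic cleanup of assignment chatter. One `rts_step`
   event is emitted per surviving high dwell; the amplitude is the
   re-estimated level separation.

Dwells below `min_dwell_s` are censored by construction, exactly as
sub-dead-time events are in single-channel dwell analysis; a dwell is
*resolvable* when it and both flanking dwells exceed the floor, and
recovery guarantees in the tests are stated over resolvable dwells. With
exponential dwells of mean 2 s, about a fifth of all dwells fall below a
0.5 s floor, so no segmentation with this resolution can return them.

## Classification and the two-class boundary

`merge_and_classify()` unions the two event lists in time order with a
duration boundary of 0.1 s between the classes — a two-sided gap to the
50 ms maximum spike width and the 0.5 s minimum dwell. Two boundary rules:

* **Step-edge guard.** A level step through any high-pass filter leaves a
  transient of roughly half the step height and ~20 ms width in the fast
  band — above threshold for every calibrated day. Fast-band events whose
  peak falls within `edge_guard_s = 0.05` of a slow-band state transition
  are therefore absorbed into the step event rather than counted as
  spikes. The guard uses the *pre-merge* transition times, because a
  sub-resolution dwell still leaves its pair of edge artifacts.
* **Long-event rule.** A remaining fast-band event with duration at or
  above the class boundary is reclassified `rts_step` if it lies inside a
  segmented high dwell, and otherwise kept — the conservative choice when
  the slow-band model has no corroborating dwell.

A short spike landing inside a high dwell keeps its class: the time scales
are distinct, and coincidence is not evidence of identity.

## Summaries and the repletion contrast

`events_per_minute()` counts events in tumbling (non-overlapping) 1-minute
windows anchored at $t = 0$, dropping a trailing partial window — the
literal reading of events-per-minute, with independent counts.
`quartile_summary()` reports median, 25th/75th percentiles (linear
interpolation between order statistics, everywhere in the package) and the
observed maximum, for rates and for amplitudes. By default the amplitude
pool includes both event classes and the headline rate counts only fast
spikes; both are switches in `detection_config()` (`amp_classes`,
`rate_classes`), since the reported summaries do not state the pooling.

`repletion_response()` reduces the six-day table to the recovery readout:
rate and amplitude ratios of each post-repletion day to starvation day 4,
`decline_24h` (day-5 median rate strictly below day 4) and
`near_baseline_48h` (day-6 median rate within 1 event/min of day 1).

## Numerical contracts and degenerate inputs

* Quantiles are type-7 (linear interpolation) everywhere.
* Trace CSVs serialize time to 6 decimals and voltage to 3; readers
  validate sampling uniformity against the declared rate within the
  serialization granularity, and reject unit fields other than `"uV"`
  rather than rescale silently.
* Empty traces give empty event lists; an all-constant trace has zero
  noise sigma; a trace with no credited events still produces a summary
  row (zero amplitudes, flagged `amp_empty`).
* Every validation failure carries a distinct condition class
  (`cyanospike_error_*`), so callers can branch on the failure mode.

## Problem sizes in the test suite

The shipped tests exercise the full study geometry once — the
six-condition hour-long schedule at 2 kHz — and replicate the stochastic
guarantees at reduced scale chosen for tight Monte-Carlo error at
desk-scale cost: 100 seeds of 600 s at 1 kHz for the repletion flags
(rate-based flags do not depend on the sampling rate; 1 kHz still gives
five samples per pulse), 200 seeds of 60 s days for detection F1, 50
seeds of 400 s telegraph traces for dwell recovery, and 200-seed
generator-law checks at low sampling rates where only event statistics
matter. A replication note: with 600 s per condition the repletion flags
rest on medians of just ten Poisson counts, so the day-5-below-day-4
comparison has an irreducible few-percent failure rate per seed under the
calibrated rates themselves — visible in the wide day-4 rate quartiles —
which is worth remembering when interpreting short recordings.

## Known limitations

* The amplitude of a detected spike is read from the fast band; the ~4%
  high-pass loss of a 5 ms pulse is not compensated. The end-to-end
  amplitude checks budget for it.
* RTS occupancy near 50% with dwells at the resolution floor produces
  missed-event fusion (two highs bridged by a sub-floor low); the package
  reports what is resolvable and does not attempt dead-time correction of
  dwell-time distributions.
* The per-day analysis treats conditions independently; no shared noise
  model or day-to-day state is carried.
* The pipeline assumes the trace is already calibrated to microvolts at
  the electrode; amplifier transfer functions are out of scope.
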
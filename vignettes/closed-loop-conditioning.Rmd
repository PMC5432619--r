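---
title: "Closed-loop beta conditioning and depth-camera movement monitoring: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop beta conditioning and depth-camera movement monitoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betacage)
```

## The system this package models

`betacage` is a software re-implementation of a wireless closed-loop
conditioning rig for freely behaving primates in their home cage.  The
original rig couples three subsystems: an implanted recorder that computes
beta-band (10–30 Hz) local field potential power online and triggers a
reward when power crosses a calibrated threshold; a radio-frequency link
that carries each reward event to a cage-side control hub driving a pellet
feeder and audio feedback; and a depth camera that quantifies the animal's
gross movement and saves event-triggered video clips.  This package
reproduces all of that as testable code — detection, calibration, the RF
codec with a lossy-channel simulator, the movement algorithm, clip
buffering, and the session analyses — plus a synthetic session generator
that stands in for the hardware and the animal.

Everything is tabular and pipe-friendly: traces, events, schedules and
movement series are tibbles; fitted-style results have `tidy()`, `glance()`
and `autoplot()` methods.

## Band power and the conditioned signal

The conditioned quantity is the running average of the rectified, band
limited LFP over a trailing 500 ms window:

* `bandpass_filter()` applies a 3rd-order bandpass at 10–30 Hz.  The filter
  family is not dictated by the protocol description, so a Butterworth
  design is used — the standard choice for a flat passband — run
  forward-backward ("bidirectional"), which squares the magnitude response
  and cancels the phase.  Causal one-pass filtering is available via
  `bidirectional = FALSE` for latency studies.
* `rectified_power()` uses a *trailing* window because the original
  detector ran online; a centered window would be acausal.  During the
  first 500 ms the mean is taken over the samples available so far rather
  than padding with fabricated data, so output length equals input length
  and early-session detection is reproducible.
* `quantize_power()` mirrors the on-chip integer power representation with
  `floor(value * scale)`; the default scale is 1 unit per µV.  The original
  computation is only described as integer-based, so the scale is exposed.

## Threshold calibration, lockout, epochs

`calibrate_threshold()` implements the protocol's rule: choose the
threshold so that, had the unrewarded baseline been a rewarded session, the
subject would have earned a chosen number of rewards.  Two readings are
possible ("exactly N" vs "at least N"); this package returns the *largest
integer threshold yielding at least* the target count, which is
well-defined (event count is non-increasing in threshold) and matches the
intent of "would have received a chosen number of rewards".  Infeasible
targets raise a classed error carrying the achievable maximum.  The
protocol texts give both a 60-min and a 30-min baseline duration; neither
is privileged here — baseline length is an input, and the run configuration
defaults to 60 min.

`detect_events()` fires where power reaches the threshold (`>=` — integer
thresholds against integer power need a closed side) gated by a refractory
lockout, 10 s by default (the hardware allowed 5–10 s; the deployed
sessions settled on 10 s after observing that the post-pellet beta drop
takes 3–10 s to recover).  Sustained supra-threshold power *re-triggers at
lockout expiry* (`retrigger = "level"`): the lockout is described as the
sole gate, and a 500 ms running average stays high through sustained
modulation.  An `"edge"` mode requiring a dip below threshold is provided
for comparison.

`schedule_epochs()` tiles the session with alternating Reinforced /
Non-Reinforced epochs on half-open `[start, end)` intervals, so boundary
events are unambiguous; `gate_events()` labels events accordingly
(`rewarded` only in R epochs — NR events are counted but unrewarded, and
the lockout runs continuously across boundaries).  Reward audio is three
1200 Hz beeps (250 ms on / 250 ms off); the audio layer enforces the
hardware envelope of 10–4000 Hz and a 50 ms minimum on-time.

## The RF event codec

Each reward event is transmitted as 3 sets of 10 biphasic pulses (1 ms
pulse width, 1000 pulses/s).  The "20 ms delay between each set" is
interpreted as the **onset-to-onset set period**: sets begin at 0, 20 and
40 ms after the event, giving the 60 ms nominal transmission window the
protocol also states.  The alternative reading (a 20 ms gap after each
10 ms burst) would give 70 ms and contradict that window, so it is
rejected.  Biphasic pulses are encoded positive-half-first (polarity is not
specified; the decoder rectifies, so the choice is inert) and are charge
balanced by construction.

The channel model erases whole pulse sets independently with probability
`set_drop_prob` and adds Gaussian noise — an intentionally symbolic model
of link loss (posture shadowing, reflections), not RF electromagnetics.
The decoder declares a set when at least half its expected pulses appear at
the expected spacing, and an event when **at least one** of its redundant
sets is detected; the receiver's exact firmware logic is not documented, so
threshold-and-spacing matching with a one-set quorum is this package's
design.  Under per-set loss probability $p$ an event is missed only when
all $n$ sets drop, so efficiency is $1 - p^n$ — the testable content of the
reported >99% transmission efficiency.

## Gross movement from depth frames

A depth frame is a matrix of millimetre distances with 0 marking an invalid
return.  After ROI masking (pixel margins plus near/far depth cutoffs that
zero out the back wall and passers-by), the movement value for a frame pair
is the sum of absolute changes of the six extremal voxels — topmost,
bottommost, leftmost, rightmost pixel indices and closest/furthest depths:

$$\mathrm{GMV} = |\Delta \mathrm{Top}| + |\Delta \mathrm{Bottom}| +
  |\Delta \mathrm{Right}| + |\Delta \mathrm{Left}| +
  |\Delta \mathrm{Front}| + |\Delta \mathrm{Back}|$$

Design points:

* **Mixed units.**  Pixel terms and millimetre terms are summed as printed
  in the defining equation.  A `depth_scale` factor (default 1) lets users
  re-weight the depth terms without changing the default semantics.
* **Indexing.**  Coordinates are 1-based and inclusive, R's native
  convention.  GMV depends only on index *differences*, so values are
  unchanged relative to any 0-based formulation.
* **Quadrants.**  The ROI can be split into a near-equal grid (remainder
  pixels to the last tile); extremes are recomputed per tile, which is what
  lets a tile report movement only when movement happened there, and
  `GMV_total` is the sum over tiles.
* **Dropouts.**  An all-invalid frame (or tile) reuses the previous
  extremes, contributing zero — otherwise a one-frame sensor dropout would
  register as a huge spurious movement.
* **Normalization.**  Infrared flicker around reflective cage bars gives
  GMV a scene-dependent nonzero floor, so within-session analyses min–max
  normalize each column to the session range (`normalize_gmv()`); a
  constant column maps to zeros by convention, and the tile-sum identity is
  only claimed for unnormalized series.

`event_triggered_average()` aligns windows to event times on the sample
grid; events whose window is truncated by the record edges are excluded and
counted, never padded.

## Clip buffering

The video recorder keeps a rolling 8 s buffer, stores every 4th frame of a
32 fps feed (8 fps stored), and on a trigger runs 4 s further before saving
`[t - 4, t + 4]` as the event's clip.  The protocol text is internally
inconsistent about saved-clip length (an 8 s buffer with 4 extra seconds
vs. "4-s video snippets"); this package defaults to 4 s pre + 4 s post and
leaves both configurable, so either reading is reachable.  Decimation
selects frames by pushed index (every Nth), not by timestamp, matching
"saved every 4th frame"; eviction keeps the boundary frame so a trigger at
the oldest retained instant still finds its full pre-window.  Clip tagging
is injective per event id.

## The synthetic session generator

`synth_session()` exists so that every component is exercisable without
hardware, downloads or animals.  Its defaults *are* the study conditions
the protocol states; scene parameters the protocol does not state were
chosen once for realism and are not tuned:

| parameter | default | why |
|---|---|---|
| `lfp_fs` | 1000 Hz | typical LFP sampling rate |
| `frame_fps` | 32 | the camera feed rate |
| `beta_center_hz` | 20 | centre of the 10–30 Hz band |
| `baseline_beta_amp` | 30 µV | resting beta amplitude over a ~20 µV 1/f floor |
| `retrieval_drop_frac` | 0.6 | post-pellet drop depth; shown only graphically in the source, so a free parameter |
| `retrieval_recovery_s` | 5 s | inside the observed 3–10 s recovery range |
| `artifact_dur_ms` | 100–150 ms | the reported transmission-artifact duration |
| `movement_coupling_gain` | 1 | linear movement→beta suppression; movement is normalized so `g = 1` halves the envelope at typical roaming speed and silences it only during vigorous movement (a saturating normalization would hide the post-reward drop the generator injects) |
| `frame_h × frame_w` | 96 × 128 | a downscaled camera viewport; keeps full-session GMV computation cheap while preserving the algorithm's geometry |
| `event_rate_per_min` | 2 | planned crossing rate, same order as the ~1/min reward target |

The generator composes: an Ornstein–Uhlenbeck blob trajectory (velocity
correlation time 2 s) with a near-pause in the 1.5 s before every planned
event and a fast "retrieval reach" after rewarded ones; an LFP equal to 1/f
noise plus a beta oscillation whose envelope is
`baseline × max(0, 1 − g·movement) × (1 + bursts)`, with a strong
event-locked burst driving each planned crossing, a post-reward drop
recovering linearly, and biphasic transmission artifacts on rewarded
(transmitted) events only; and a depth scene of back wall, flickering
reflective-bar strip (the GMV floor; bars sit between camera and subject,
so they are drawn over the blob) and the subject blob.  Session records
compute the movement stream on the whole ROI: per-quadrant series are
available through a gridded ROI, but a roaming subject crossing tile
boundaries makes quadrant *totals* spike as the blob enters and leaves
tiles, so quadrants are opt-in for session-level analyses.  All randomness
is drawn up-front from the seed, so identical `(config, seed)` give
bit-identical sessions and frames can be streamed rather than stored.

What the generator does *not* emulate: biophysical LFP spectra beyond 1/f,
photorealistic depth scenes, other animals or personnel in the room, and
camera optics.  Passing tests therefore show the algorithms recover the
structure the generator injects under realistic noise — not that any
particular animal behaves this way.

### Problem sizes used by the tests and acceptance script

Statistical checks run at sizes chosen to make their expectations sharp:
2000 Monte-Carlo transmissions for the efficiency law ($3\sigma \approx
0.6$ points); 300–600 s sessions for the movement–beta correlation sign
(and a 1200 s, event-free, uncoupled session for the null check — the
envelope and movement are smooth signals, so short records do not
concentrate a null correlation near zero); 50 events per side for the R/NR
permutation comparison (200 permutations, one-sided); a 2000 s record for
the envelope–movement independence property.

## Session analyses

`epoch_rates()` divides labeled event counts by the minutes each epoch kind
occupies.  `performance_metric()` computes per-session
`d = R rate − NR rate` normalized by the maximum |d| across the sessions
provided, preserving sign (so values lie in [−1, 1] and the metric is
scale-invariant).  `triggered_compare()` contrasts event-triggered power
averages for R vs NR events, and `triggered_drop_test()` formalizes the
R-only post-reward drop as a one-sided permutation test over event labels,
with the per-event statistic taken on a 0.5–5 s post-event window to skip
the transmission artifact.  `estimate_recovery_time()` inverts the linear
recovery model: it smooths the triggered average, takes the pre-event
baseline over [−6, −2] s (clear of the pre-event volitional burst), fits a
line to the 10–85% climb out of the post-event minimum, and reports where
the fit re-crosses the baseline — unbiased when the recovery really is
linear, which is how the generator builds it.

## Numerical and degenerate-input conventions

* Detection uses a 1 µs slack when comparing event spacing to the lockout
  so floating-point time grids cannot drop a legitimate boundary event.
* `calibrate_threshold()` binary-searches the integer thresholds (the count
  is monotone); `target_count = 0` returns `max(power) + 1`.
* Empty traces, empty event sets, zero-duration epochs, all-invalid frames
  and infeasible targets raise classed conditions
  (`betacage_insufficient_data`, `betacage_undefined_rate`,
  `betacage_calibration_infeasible`, ...) rather than returning sentinels.
* The pink-noise FFT pads to a power of two before transforming so awkward
  sample counts never hit a slow large-prime transform.
* File writers stamp a format version; readers reject future majors and
  corrupt headers with parse errors naming the file and position.

## Known limitations

* The GMV is a *gross* index by design: it cannot attribute movement to a
  limb, and two simultaneous movements in one tile are not separable.
* The channel model is symbolic; it says nothing about range, antennas or
  carrier frequency.
* The deployed system's per-session behavioral numbers are not reproducible
  from the publication (no data were deposited), so session-level claims
  are validated as properties on synthetic data instead.
* `performance_metric()` normalizes within the set of sessions it is given;
  comparing across different session sets requires re-normalization.
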
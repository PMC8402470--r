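---
title: "Detecting gait events from grip pressure on a cane handle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gait events from grip pressure on a cane handle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canegait)
```

## The problem

People who walk with a one-sided impairment — after a stroke, with a paretic
leg, or while using a unilateral exoskeleton or functional electrical
stimulation (FES) — commonly carry a cane on the side opposite the impaired
leg and move it in synchrony with that leg. Controllers for such assistive
devices need gait events (heel strike, toe off, the onsets of the swing
sub-phases) in real time, and ideally slightly *ahead* of time: an
electromechanical prosthesis needs 30–100 ms to act, and electrically
stimulated muscle needs 50–150 ms to build force. Instrumenting the cane
instead of the body keeps all sensing off the user, which helps acceptance
and daily use.

This package implements the full analysis for a cane whose handle carries a
16-unit force-sensing-resistor (FSR) array: 10 sensors under the palm
("top" side) and 6 under the fingers ("bottom" side), scanned at 50 Hz.
Grip pressure redistributes systematically over the gait cycle, so
variables derived from the array exhibit per-stride extrema whose timing,
relative to gait-phase onsets measured by a reference motion-capture
stream, characterizes them as gait-event beacons. A negative timing offset
means the extremum *anticipates* the phase.

## Derived grip variables

With \(f_i\) the output of sensor \(i\) and \((x_i, z_i)\) its coordinates
in the handle's sagittal frame (millimetres; \(z\) along the cane shaft),
the six variables are

\[
\mathrm{CoMX_{Up}} = \frac{\sum_{i \in \mathrm{top}} f_i x_i}{\sum_{i \in \mathrm{top}} f_i},
\qquad
\mathrm{CoMX_{Down}} = \frac{\sum_{i \in \mathrm{bottom}} f_i x_i}{\sum_{i \in \mathrm{bottom}} f_i},
\]
\[
\mathrm{CoMX} = \frac{\sum_i f_i x_i}{\sum_i f_i},
\qquad
\mathrm{CoMZ} = \frac{\sum_i f_i z_i}{\sum_i f_i},
\]
\[
\mathrm{MP_{Up}} = \frac{1}{10}\sum_{i \in \mathrm{top}} f_i,
\qquad
\mathrm{MP_{Down}} = \frac{1}{6}\sum_{i \in \mathrm{bottom}} f_i ,
\]

i.e. grip centre-of-pressure analogues along the two axes and per-side mean
pressures, plus the time derivative of each (prefixed `d`, e.g. `dCoMZ`),
giving twelve channels in all. Forces stay in raw conditioned sensor units:
FSRs are dependable for *timing*, not for absolute force, and nothing
downstream needs newtons.

A centre-of-pressure value is undefined when its group's total force is
zero, which genuinely happens when the cane unloads during its swing. Such
samples are reported as `NA` and excluded from smoothing fits and peak
detection rather than being fabricated — this is the package's resolution
of a case the defining equations leave open.

```{r}
lay <- default_handle_layout()
f <- matrix(0, 1, 16); f[1, 3] <- 2 # only sensor 3 loaded
compute_derived(fsr_series(0, f), lay)$data
```

## Reference segmentation

The reference stream (modelled on an inertial motion-capture suit sampled
faster than the cane, 100 Hz by default) provides per-foot speed and
sagittal orientation, the tracked shank angle, the inter-feet distance and
the cane inclination. A rule-based state machine splits each stride into
seven phases; the initial-contact phase occupies only ~8% of the cycle at
eight-phase granularity, so it is merged with loading response. The
decision rules, in stride order, with their default thresholds:

| # | Phase onset | Rule | Threshold |
|---|-------------|------|-----------|
| 1 | initial contact / loading response | tracked-foot speed falls below the stance threshold after a swing | 0.4 m/s |
| 2 | mid stance | opposite-foot speed rises above the swing threshold (opposite toe off) | 0.8 m/s |
| 3 | terminal stance | tracked foot angle rises above 0° (heel rise) while speed is in stance | 0°, 0.4 m/s |
| 4 | pre-swing | opposite-foot speed falls below the stance threshold (opposite initial contact) | 0.4 m/s |
| 5 | initial swing | tracked-foot speed exceeds the swing threshold with the foot pitched toe-down | 0.8 m/s, −9° |
| 6 | mid swing | local minimum of the inter-feet distance below the distance threshold (feet adjacent) | 0.4 m |
| 7 | terminal swing | shank crosses vertical (interpolated between samples) | 90° |

These are the standard Perry-cycle events that the stated conditions name;
each threshold is used exactly once. Crossings must hold for 2 consecutive
samples (hysteresis against chatter), and the tibia-vertical crossing time
is linearly interpolated. Only complete strides — all seven onsets, in
order, closed by the next initial contact — are kept. Terminal stance is
segmented but *not* used as an event reference by default: it sits so close
to pre-swing that events cannot be separated between the two, and its
detection is the least reliable of the seven.

## Stream synchronization

The cane's electronics and the reference system free-run on their own
clocks. Both, however, observe the same physical quantity: the cane's
inclination from vertical. Synchronization therefore (1) normalizes both
inclination signals to [0, 1]; (2) trims each to the segment between its
first and last local peak, so both span the same cyclic content — a peak
must rise at least 5% of the signal range above its surroundings so noise
cannot define the trim bounds; (3) upsamples the 50 Hz cane signal onto the
reference sampling period by linear interpolation (cane dynamics are slow
relative to both grids, so linear is adequate); (4) slides one signal
against the other in integer reference samples over a ±5 s window; and
(5) takes the lag maximizing the Pearson correlation, ties broken toward
the smallest magnitude. The lag is applied once, globally, to every
cane-stream timestamp; clock *drift* over a two-minute recording is far
below a sample and is not modelled.

Because a strictly periodic signal correlates equally well one whole
stride off, real recordings are assumed to carry stride-to-stride amplitude
variability (the simulator injects ~8% by default); with that variability
and noise down to 10 dB SNR the lag is recovered to about one reference
sample in the median.

## Event pipeline

After synchronization the six variables are smoothed with a 3rd-order
Savitzky–Golay filter. The window length is 11 samples (0.22 s at 50 Hz) by
default: shorter than any phase at ordinary cadence so peak timing is
preserved, yet wide enough to absorb sample-scale spikes; being a
least-squares cubic fit it reproduces polynomials up to degree 3 exactly.
Derivatives are taken *after* smoothing (central differences, one-sided at
the ends) to limit noise amplification. To avoid the less regular strides
near the start and end of a recording, the 30 central strides are analyzed;
with an odd surplus the extra stride is discarded from the start.

Per stride and per channel, local maxima and minima are detected with a
prominence floor of 5% of the channel's interquartile range over the
analyzed strides (plus a 10⁻⁹-of-channel-scale absolute term so a
numerically constant channel cannot report floating-point ripples as
extrema). Each extremum is referenced to the phase onset minimizing the
absolute offset, among this stride's onsets and the next stride's initial
contact; near-equidistant ties go to the *following* onset, the
anticipating reading, which is the useful one for pre-triggering assistive
devices. An event is retained only if it recurs in at least 25 of the 30
strides; its offset distribution is summarized by median and interquartile
range, with 0 s the phase start and negative values anticipation.

```{r}
rep_ <- run_pipeline(pipeline_config(
  simulate = gait_sim_config(injected_lag = 0.25), seed = 4
))
ev <- as.data.frame(rep_$events)
ev[ev$variable == "CoMZ" & ev$phase %in%
  c("pre_swing", "initial_contact_loading_response"),
  c("variable", "kind", "phase", "n_strides_detected", "median_offset")]
```

Stride-time normalization (`normalize_stride_time()`) resamples each
stride onto [0, 1] between consecutive initial contacts and averages across
strides, the standard representation for visual inspection of how a
variable evolves over the cycle.

## The synthetic-data generator

No public recordings exist for this sensor pair, so the package ships a
ground-truthed simulator, `simulate_gait()`, which is first-class, tested
code. It emulates the study conditions end to end: treadmill walking with a
contralateral cane synchronized to the impaired leg; a 50 Hz cane stream
and a faster (100 Hz) reference stream; a configurable clock offset between
them; and stride-periodic 16-channel grip patterns.

Design choices, made once:

* **Kinematics** are periodic piecewise-linear templates anchored so that
  each segmentation rule fires exactly at the configured phase fraction —
  the generator *constructs* the threshold crossings rather than hoping a
  biomechanical model produces them. Defaults follow the standard cycle:
  stance ends at 60%, the merged initial-contact/loading-response phase at
  10%, feet adjacent at 73%, tibia vertical at 87%, stride period 1.1 s.
* **Grip forces** are a loading envelope (high during cane stance, ~35%
  residual grip during cane swing, baseline 10 force units) common to all
  sensors, plus per-event Gaussian bumps (σ = 5% of the cycle) distributed
  across sensors along the gradient of the target variable. Because each
  bump's sensor weights sum to zero within the relevant group, the group's
  total force is unchanged; scaling the bump by the envelope then makes the
  centre-of-pressure perturbation exactly proportional to the bump, so the
  planted extremum lands exactly at the configured cycle fraction. (An
  unscaled bump divided by the time-varying total force drifts off target
  on the envelope's flanks — the reason for this choice.) For derivative
  channels the parent bump is centred one σ after (maximum) or before
  (minimum) the target, where a Gaussian's derivative is extremal.
* **The cane inclination** is a sinusoid locked to the gait cycle (15°
  amplitude) with per-stride amplitude variability (CV 8%), present in
  both streams; the cane-stream copy is evaluated at lagged time, so the
  injected lag is exactly what synchronization must recover.
* **Noise** defaults are modest and per-stream: 0.2 force units on the
  FSRs (2% of baseline), 0.02 m/s on foot speeds, 0.5° on angles, 5 mm on
  the feet distance, 0.2° on the inclinations. Per-stride event-time
  jitter (default σ = 10 ms) models the cycle-to-cycle variability of real
  grip events. All randomness flows from a single seeded stream, so equal
  seeds give bitwise-equal recordings.

What the simulator does **not** emulate: musculoskeletal dynamics, FSR
nonlinearity and hysteresis, clock drift, pathological or asymmetric gait,
and the inter-subject variability that dominates real recordings. Passing
tests therefore demonstrate that the *pipeline* is correct — that it
recovers what is truly in the signals at the stated tolerances — not that
any particular patient's grip will exhibit a given event.

## Numerical choices and degenerate inputs

* Zero-total-force samples: centre-of-pressure `NA`, mean pressures 0;
  `NA` spans are bridged by linear interpolation for the smoothing fit and
  restored afterwards.
* Local extrema use exact-equality run-length encoding, so a plateau of
  equal samples counts once, at its middle sample — sampled symmetric peaks
  cannot vanish by landing between two equal samples.
* The shift search uses integer reference samples; sub-sample lag precision
  is not claimed. Ties in the correlation go to the smallest |lag|.
* Constant signals are rejected by normalization (zero range), monotone
  signals by trimming (fewer than two peaks), standing posture by
  segmentation (no strides): every degenerate input fails loudly with the
  stage named.
* Problem sizes throughout the test-suite simulations — typically 8–40
  strides, 50/100 Hz, 10–20 seeds per property — were chosen as the
  smallest at which the estimated quantities stabilize well inside their
  tolerances.

## Known limitations

* The segmentation decision logic is a reconstruction from the stated
  thresholds and the standard gait-cycle events; real inertial-suit data
  may need per-subject tuning, which is why every rule's threshold is
  exposed in `segmentation_config()`.
* Event detection is offline and per-recording; the online,
  threshold-based detection that a real-time controller would need is out
  of scope, as are machine-learning classifiers and pooling statistics
  across subjects.
* With a strictly periodic, noise-free cane signal the synchronization lag
  is identifiable only up to a stride period; recovery relies on
  stride-to-stride variability, which real recordings (and the simulator)
  provide.
* Force calibration to newtons is deliberately absent; all force-unit
  quantities are relative.
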
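# canegait

Gait-event detection from grip pressure on an instrumented cane handle.

## What this is for

Controllers of lower-limb prostheses, exoskeletons and functional
electrical stimulation (FES) need gait events — heel strike, toe off, the
swing sub-phase onsets — in real time, and preferably *before* they happen:
actuators take 30–100 ms to respond and electrically stimulated muscle
50–150 ms. For people with a one-sided impairment who carry a cane on the
opposite side and swing it in synchrony with the impaired leg, the cane
itself can do the sensing, keeping everything off the user's body.

`canegait` implements the complete analysis for a cane handle carrying a
16-unit force-sensing-resistor (FSR) array (10 sensors under the palm, 6
under the fingers, scanned at 50 Hz). It is aimed at researchers in
wearable sensing and assistive-device control who want a tested, end-to-end
reference pipeline:

* **Grip variables** — per sample, the force-weighted centre of pressure of
  the grip and the per-side mean pressures,

  CoMXUp = Σ fᵢxᵢ / Σ fᵢ (top side), CoMXDown (bottom side),
  CoMX, CoMZ (all sensors, x- and z-axis), MPUp = Σ fᵢ / 10,
  MPDown = Σ fᵢ / 6,

  plus the time derivative of each (`dCoMZ`, …) — 12 channels.
* **Gait segmentation** — a rule-based state machine over a reference
  kinematics stream (foot speeds/angles, shank angle, inter-feet distance)
  splits each stride into seven phases using stance/swing speed thresholds
  (0.4 / 0.8 m/s), a toe-down angle (−9°), a feet-adjacent distance
  (0.4 m) and the tibia-vertical crossing (90°).
* **Stream synchronization** — the cane and reference streams free-run;
  their shared cane-inclination signal is normalized, trimmed to its first
  and last peak, upsampled, and cross-correlated to find the clock lag.
* **Event pipeline** — 3rd-order Savitzky–Golay smoothing, the 30 central
  strides, per-stride extrema of the 12 channels, and consolidation: an
  event is kept only if it recurs in ≥ 25 of 30 strides. Offsets are
  reported relative to phase onsets (0 s = phase start; negative =
  anticipates the phase).
* **Synthetic gait simulator** — ground-truthed recordings (kinematics,
  lagged cane-angle pair, 16-channel grip patterns with plantable extrema)
  so every stage is testable without any recorded data.

## Worked example

Simulate a recording with a 0.25 s clock offset between the cane and the
reference system and a grip event planted 5% of the cycle before
pre-swing, then run the full pipeline:

```r
library(canegait)

rep_ <- run_pipeline(pipeline_config(
  simulate = gait_sim_config(injected_lag = 0.25),
  seed = 4
))
rep_$sync
#> Stream sync: lag = +0.2500 s (add to cane timestamps), peak r = 0.9997

ev <- as.data.frame(rep_$events)
ev[ev$variable == "CoMZ" & ev$phase %in%
     c("pre_swing", "initial_contact_loading_response"),
   c("variable", "kind", "phase", "n_strides_detected",
     "median_offset", "iqr_offset")]
#>  variable kind                            phase n_strides_detected median_offset iqr_offset
#>      CoMZ  min initial_contact_loading_response                 28         -0.06     0.0125
#>      CoMZ  max                        pre_swing                 30         -0.06     0.0100
```

Reading this: the injected clock lag was recovered exactly. The planted
CoMZ maximum is found in all 30 analyzed strides, a median of 60 ms
*before* the pre-swing onset (the true planted offset is −55 ms; detection
is quantized to the 50 Hz cane clock) — a usable anticipating beacon for
pre-triggering an assistive device. The generator's second default event, a
CoMZ minimum in terminal swing, is likewise reported anticipating the next
initial contact.

A thin command-line front end wraps the same functions
(`inst/scripts/canegait.R`, verbs `simulate`, `segment`, `sync`, `events`,
`run`):

```sh
Rscript inst/scripts/canegait.R run --simulate --seed 4 --out-dir out/
```

which writes `report.json`, `events.tsv` and `timeline.tsv`.

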
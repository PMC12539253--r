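---
title: "Models and methods behind microdrive"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind microdrive}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microdrive)
```

This vignette is the package's own account of the science it implements:
the kinematic model of the implant's drive mechanism, the depth-tracking
and calibration conventions, the recording pre-processing and spike
detection chain, and the synthetic world used to test all of it. It also
records the design decisions taken where the problem admitted more than one
defensible answer.

## 1. Drive kinematics

The implant moves its probe shuttle along a fine-pitch drive screw. One
full screw rotation translates the shuttle by one thread pitch, so the
displacement for `T` direct turns is simply

> D = P · T

with `P = 0.3` mm for the stock M1.4 screw. Sub-millimetre accuracy by hand
is impractical at the screw, so the kit turns the screw through a
screwdriver containing two cascaded planetary gear stages. In each stage
the input is the sun gear, the output is the planet carrier and the ring
gear is fixed; the output makes

> S / (R + S)

turns per input turn, where `S` and `R` are the sun and ring tooth counts.
Stages multiply: two stages of sun 8 / ring 32 give (1/5)·(1/5) = 1/25, so
one input turn moves the shuttle P/25 = **0.012 mm**. A separate 10:1 stage
(sun 5, planets 20, ring 45) drives the turn-counter disk without altering
the drive path.

**Exact rational ratios.** Turn ratios are stored as integer fractions and
reduced with a gcd, converting to floating point only when a distance is
produced. A depth ledger accumulates dozens of adjustments; had each stage
ratio been a rounded double, the cumulative sums would drift. With
rationals, 25:1 is 25:1 exactly and the round-trip identities
(`turns ↔ distance`) hold to 1e-12 relative tolerance over the full working
range, which the property tests assert.

**Sign convention.** Positive turns are counterclockwise at the drive
screw and extend the probe out of the base, i.e. deeper into tissue. This
matches the calibration procedure (10 ccw turns displace the shank 3 mm out
of the base). Hardware variants with the opposite handedness can negate
turns at the call site; the arithmetic is odd-symmetric.

**Planet teeth.** The ratio does not involve the planet gears, but a
physically buildable stage must satisfy `R = S + 2 · planets`. When planet
teeth are supplied they are checked and a violation warns rather than
errors, since an informational mismatch should not block ratio
calculations. The counter stage (5, 20, 45) satisfies the identity.

One sentence in the source material states that moving the probe 3 mm takes
"25 turns (12 μm per turn)"; at 12 μm per input turn, 3 mm is 250 input
turns (or 10 direct screw turns). The package follows the displacement
equations; that sentence is treated as an erratum.

## 2. Depth ledger

Depths use the dorsoventral (DV) convention: negative numbers are deeper
below the reference surface, and adjustments into tissue are negative
distances. Published positive "μm adjustment" figures are therefore stored
as negative millimetres.

* **Draw length.** Before implantation the shank is drawn out of the base
  far enough that its tip reaches the target initial depth `DV0` after the
  implant sits on the skull: `L0 = |DV0| + A + B`, with `A` the measured
  skull thickness and `B` the 0.5 mm bottom wall of the skull interface.
  The draw is refused beyond the usable shank length, 9.5 mm by default
  (10 mm shank minus the bottom wall), configurable for other probes.
* **Cumulative depth.** After surgery the tip position is
  `DV = DV0 + Σ D_i` over all recorded micro-adjustments. The ledger is
  append-only; each record stores the turns applied, the signed distance,
  and the running depth, and the current depth is always recomputable from
  the raw records (asserted as the replay property). Because the depth is a
  sum, it is invariant under permutation of the records, while the indices
  preserve history.
* **Turn planning.** `plan_adjustment()` quantizes a target displacement to
  whole screwdriver input turns — the unit the counter disk displays — with
  ties rounded toward fewer turns (an under-shoot is recoverable, an
  over-shoot through tissue is not). The residual is then at most half a
  step (6 μm with the stock kit). A quarter-turn mode matches the
  0.25/0.5/0.75 marks on the counter knob.
* **Calibration.** 3D printing leaves a vertical tolerance between the
  fully retracted shuttle and the base. On the calibration block, the screw
  is turned ccw a reference 10 turns (a 3 mm stroke) and then further until
  the tip meets the 3 mm mark, counting total turns. The surplus
  `ET = counted − reference` measures the gap; `ED = P · ET` in
  millimetres. Applying `ET` turns after full retraction pre-loads the gap
  so subsequent 10-turn strokes land on the mark. In the simulated shuttle
  model (`position = −gap + P · turns`) the correction lands within 1e-9 mm
  of 3.0 mm for any gap in [0, 3] mm, which the acceptance suite checks. A
  counted total below the reference means the mark was overshot before the
  reference stroke finished and is reported as an error: the procedure must
  be re-run, there is no meaningful negative correction.
* **Dates and cadence** are free-text notes. Published cadence ("2–3 times
  per week", maintenance adjustments every other week) is lab practice, not
  arithmetic, and is not enforced. The source material itself reports the
  maintenance adjustment as 60 μm in one place and 50 μm in another; both
  are representable and the package asserts no default.

One published adjustment schedule (start −3.3 mm; seven −48 μm, four
−300 μm, one −39 μm steps) is described as reaching a −5.0 mm target, but
sums to −4.875 mm. The ledger reproduces the arithmetic sum; the
discrepancy is surfaced rather than patched.

## 3. Signal chain

The chain has a fixed canonical order — artifact masking, local common
average referencing, band-pass filtering, detection — recorded in the audit
log of every run.

* **Artifact masking** (stage 1) flags samples whose |z| against the whole
  raw channel reaches 10 SD, widens each flag by a ±2 ms guard window, and
  replaces flagged samples with the channel median. Replacement (rather
  than deletion) keeps sample indices aligned across stages, so timestamps
  remain valid. The z-score is computed on the raw input because the stage
  precedes filtering in the published order; on a raw in-vivo trace the SD
  is dominated by low-frequency field potentials, so genuine spikes sit far
  below 10 z while movement or stimulation artifacts exceed it. A
  zero-variance channel has no defined z and is left unmasked with a
  warning. The visual-inspection half of the published artifact step is a
  human procedure and out of scope.
* **Local averaging** (stage 2) subtracts from each channel the mean of up
  to 7 physical neighbors above and 7 below (self excluded, truncated at
  the array edges). "7 above and/or below" is read as *per side* (≤14
  total); a `total` mode is available for the other reading. Any signal
  common to all channels — line interference, common-mode LFP — is
  annihilated exactly (to 1e-9 μV, asserted), because each channel's
  neighbor mean then equals the channel itself. A single-channel block has
  no neighbors and passes through unchanged.
* **Band-pass** (stage 3) is an order-2 Butterworth, 300–5000 Hz, applied
  forward and backward. Zero-phase filtering preserves the trough timing
  that clip centering depends on; the effective magnitude response is the
  squared design response. No installed R package provides the design, so
  the bilinear-transform construction and the forward-backward pass (odd
  edge extension, steady-state initial conditions) are implemented here and
  verified against frozen reference values from an independent
  implementation (scipy), including an end-to-end forward-backward fixture.
  Band edges must respect Nyquist; the block's sampling rate is always read
  from metadata (30 kHz in all synthetic defaults, matching the action
  potential band of the target acquisition system).
* **Detection.** A candidate is a contiguous run of samples below −80 μV;
  its peak is the most negative sample (earliest on ties). Peaks within one
  clip length after an accepted peak are suppressed (the published
  procedure states no dead time; one clip length is the shortest lockout
  that guarantees clips do not share their center region). The secondary
  "z ≥ 1" filter is interpreted as the peak's |z| against the whole
  processed channel — a sanity filter that prunes threshold crossings on
  high-variance channels; where the published description is silent on
  what the z applies to, this choice is a documented configuration, not
  ground truth. Clips are `round(1.7 ms · rate)` samples forced odd (51 at
  30 kHz), inverted, with the peak exactly in the middle; events whose clip
  would overrun the block edge are dropped.
* **Footprints.** For each event, the clip window at the event's peak time
  is extracted on the ±1..±4 physical neighbors and the same detection
  criterion is applied within that window; neighbors that meet it
  contribute a clip and trough amplitude, others are recorded absent. With
  geometric amplitude decay across channels the detected amplitudes are
  non-increasing in distance, which the acceptance suite asserts. Note
  that local averaging leaks a fraction of a large spike into its
  neighbors' reference, so post-chain neighbor amplitudes run ~25–30%
  below the injected decay arithmetic; footprint examples in the
  documentation therefore distinguish raw-block from post-chain values.

## 4. The synthetic world

The generator exists so that every stage is testable against known ground
truth without any recorded data. It emulates, per the plan: per-channel
Gaussian background noise; scheduled spikes from a fixed biphasic template
(difference of Gaussians, 1.2 ms, trough at one third of the duration,
normalized to exactly −1 — any negative-dominant shape satisfies the
chain's assumptions and none is prescribed); geometric per-channel-step
amplitude decay, symmetric above and below the source channel (the
simplest model reproducing the observed cross-channel attenuation);
rectangular artifacts applied across all channels, scaled in units of the
noise SD; optional 50/60 Hz line interference; and int16 quantization
(0.195 μV/bit by default, typical of the target front end) applied last.
Identical plan and seed give bit-identical output, and the generator
restores the caller's RNG state.

**Why the recall world includes line interference.** The artifact stage
computes its z-score on the raw channel. On a *flat* Gaussian background of
≤10 μV SD, any supra-threshold spike (−120 μV and beyond) is itself a
12–30 SD excursion and would be masked as an artifact — a situation that
never arises in vivo, where the raw trace is dominated by LFP and line
power and the whole-channel SD is an order of magnitude above the AP-band
noise. The recall/precision test world therefore adds the generator's 50 Hz
component at 200 μV as the realistic raw background; the chain itself
removes it (local averaging annihilates the common mode, the band-pass
removes the residue) before detection. Injected troughs are drawn from
[−200, −150] μV over 8 μV AP-band noise — within the supra-threshold class
— because local-averaging leakage and the squared band-pass attenuate
troughs by ~25–30%, and the detection threshold applies to the processed
trace. These are statements about the world, fixed a priori; the 0.95
recall/precision bar is met with margin, not at the edge.

**Gain-test bench.** The saline-bath routine is 100 square pulses of
100 μs (3 samples at 30 kHz), 250 ms apart, recorded at nominal gain 1000:
the recorded amplitude is `true × actual_gain`, and the estimator reports
`gain = median per-pulse peak / true` with its relative deviation from
nominal (pass bound 10%, per the probe user manual; the published work
reports no measured values, so only the bound is checkable). Pulses are
located at half the expected amplitude. The bench block is not int16
quantized: the estimator divides medians of recorded units, where
quantization is irrelevant, and quantizing would break the exactness of
the noise-free case (actual = nominal must give deviation exactly 0). With
noise at 5% of the pulse amplitude the median-of-peaks estimator carries a
small positive bias (the peak of 3 noisy samples), ~4% — comfortably
inside the bound, and visible in the acceptance script's output rather
than assumed.

**What the generator does not emulate** — and hence what a green test does
not establish: biophysical spike shapes and their diversity, electrode
impedance and its drift, probe drift and motion artifacts beyond
rectangular pulses, overlapping spikes from distinct units (the scheduler
allows them, but the lockout then merges detections), and the spatial
statistics of real noise (correlated across neighboring channels). Recall
and precision on this world bound the chain's algorithmic correctness, not
its in-vivo performance.

## 5. Numerical and interface choices

* Gear ratios: exact rationals; distances: doubles. Round trips asserted at
  1e-12 relative tolerance.
* Ledger CSV stores all numbers as `%.17g`, so write → read → write is
  byte-identical and depths survive at full double precision.
* `plan_adjustment` ties (exactly half a step) round toward fewer turns;
  a 1e-9-step tolerance absorbs the binary representation of 0.012.
* Degenerate inputs: empty gear train (ratio exactly 1), single-channel
  blocks (referencing is a no-op), zero-variance channels (no artifact
  masking, warning), empty event lists (`average_waveform` errors, the
  evaluator returns recall/precision of `NA` where undefined).
* The recording file format is flat little-endian int16, sample-major,
  with a JSON sidecar (rate, channel count, scale, channel order); the
  reader cross-checks file size against the sidecar and refuses truncated
  files. Conversion to μV happens on read.
* The CLI is a thin layer over exported functions; configs are a strict
  TOML subset (no installed R TOML parser) where unknown keys are errors,
  so a typo cannot silently change a calibration constant.

## 6. Known limitations

Torque, backlash and thread-skip are not modeled (the fine pitch is chosen
by the kit precisely to avoid skipping); stereotaxic AP/ML transforms and
skull-surface geometry are out of scope; the chain is offline and
batch-oriented, not streaming; channel geometry is a linear shank order,
not a full probe map; and spike sorting begins where this package ends —
detected events and footprints are its terminal products.
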
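# microdrive

Computational companion to a 3D-printed chronic electrophysiology implant
kit for rats. The kit positions silicon probes (e.g. Neuropixels 1.0) with a
movable shuttle on a fine-pitch drive screw, turned through a two-stage
planetary-gear screwdriver for micron-scale control. This package
implements everything about that kit which is arithmetic rather than
plastic:

* **Gear/screw kinematics** — exact conversion between screwdriver turns
  and probe displacement. A planetary stage with sun input, carrier output
  and fixed ring has turn ratio `S / (R + S)`; cascaded stages multiply, so
  the stock two-stage train (sun 8 / ring 32 per stage) gives 25:1, and a
  0.3 mm pitch screw moves the shuttle `D = P · T_in / Gr` = **0.012 mm per
  input turn**. Ratios are kept as exact integer fractions.
* **Depth ledger** — tracking the probe tip's dorsoventral position from
  implantation onward: draw length `L0 = |DV0| + A + B` (target depth,
  skull thickness, implant bottom wall), cumulative depth
  `DV = DV0 + Σ D_i` over post-surgical micro-adjustments, whole-turn
  adjustment planning, electrode-row positions, and the calibration
  procedure that corrects 3D-print tolerance (error turns
  `ET = counted − reference`, error distance `ED = P · ET`).
* **Signal chain** — the recording pipeline used with the kit: artifact
  masking (|z| ≥ 10 against the whole raw channel), local common average
  referencing (7 channels per side), zero-phase order-2 Butterworth
  band-pass (300–5000 Hz), threshold spike detection (−80 μV, secondary
  z ≥ 1 filter), 1.7 ms peak-centered inverted clips, average waveforms,
  and cross-channel footprints over ±4 neighboring electrodes.
* **Synthetic data** — a seeded generator of Neuropixels-like recordings
  (Gaussian background, biphasic spike templates with geometric
  cross-channel decay, rectangular artifacts, optional 50/60 Hz line
  interference) and of the saline-bath gain-test pulse train (100 × 100 μs
  pulses, 250 ms apart, nominal gain 1000, pass bound: gain within 10% of
  nominal), with ground-truth logs and recall/precision scoring.

Intended users: labs running chronic extracellular recordings who want the
kit's positioning arithmetic, depth bookkeeping and pre-processing chain as
tested, scriptable functions instead of a spreadsheet and ad hoc scripts.

## Worked example

Kinematics and depth bookkeeping:

```r
library(microdrive)

kit <- kepler_drive_config()     # 0.3 mm pitch behind the 25:1 screwdriver
kit
#> <drive_config> pitch 0.3 mm, train ratio 1/25, step 0.012 mm per input turn

led <- depth_ledger(dv0_mm = -1.5, implant_geometry(skull_thickness_mm = 0.7), kit)
initial_draw_length(-1.5, implant_geometry(0.7))   # |DV0| + A + B
#> [1] 2.7                                          # mm, = 9 direct screw turns

p <- plan_adjustment(led, target_dv_mm = -1.56)    # descend 60 um
led <- record_adjustment(led, turns = p$turns, note = "day 1")
led
#> <depth_ledger> DV0 -1.5 mm, 1 adjustment(s), current DV -1.56 mm
#>  index   mode turns distance_mm cumulative_dv_mm  note
#>      1 kepler     5       -0.06            -1.56 day 1
```

Synthetic recording through the full chain:

```r
plan <- simulation_plan(n_channels = 15, duration_s = 2, noise_sd_uv = 8, seed = 42,
  spikes = data.frame(channel = c(4, 8, 11), time_s = c(0.5, 1.0, 1.5),
                      trough_uv = c(-180, -250, -200), decay = 0.5),
  line_noise = list(freq_hz = 50, amplitude_uv = 200))
sim <- simulate_recording(plan)
res <- run_chain(sim$block)      # artifacts -> local averaging -> band-pass -> detect
res
#> <chain_result> 15 channel(s), 3 event(s), 3 footprint(s)
res$events[[8]]
#> <spike_events> 1 event(s), clips of 51 samples @ 30000 Hz
#>  channel peak_sample   peak_uv
#>        8       30012 -193.2818
```

The −250 μV spike injected on channel 8 at 1.0 s (sample 30012) is found at
its trough; its amplitude after referencing and zero-phase filtering is
−193 μV. Scoring against the ground-truth log:

```r
evaluate_detection(res$events[[8]], sim$truth[2, ], tolerance_samples = 10)
#> recall 1, precision 1 on this channel (1/1 over the whole block per channel)
```

Cross-channel footprint of a −150 μV spike with per-step decay 0.6 (on the
raw block): the ±1 neighbors at −90 μV pass the −80 μV criterion, ±2 at
−54 μV do not —

```r
quiet <- simulate_recording(simulation_plan(15, 0.5, noise_sd_uv = 0, seed = 1,
  spikes = data.frame(channel = 8, time_s = 0.25, trough_uv = -150, decay = 0.6)))
ev <- detect_spikes(quiet$block, 8)
cross_channel_footprint(quiet$block, footprint_event(ev, 1))
#> <spike_footprint> channel 8 @ sample 7512
#>  offset detected peak_uv
#>      -1     TRUE  -90.09
#>       1     TRUE  -90.09
#>   (+-2..4  FALSE      NA)
```

Saline-bath gain check (noise SD at 5% of the recorded pulse amplitude):

```r
est <- estimate_gain(simulate_gain_test(
  gain_test_plan(true_amplitude_uv = 5, noise_sd_uv = 250, seed = 42)), 5)
#> gain 1041.2, relative deviation 0.041 (bound 0.10)
```

## Command line

A thin wrapper over the same functions lives at `inst/scripts/microdrive`
(installed under `system.file("scripts", package = "microdrive")`):

```sh
microdrive gears                       # stage ratios, total ratio, mm/turn
microdrive ledger init --dv0 -1.5 --skull 0.7 --out ledger.csv
microdrive ledger adjust --ledger ledger.csv --turns 5
microdrive ledger plan --ledger ledger.csv --target -3.45
microdrive calib --counted 12          # error turns / error distance
microdrive simulate --config kit.toml --seed 4 --out rec
microdrive detect --config kit.toml --in rec.bin --out events.csv
microdrive gaintest --seed 2
```

Configuration is a TOML-style file with `[screw]`, `[train]`, `[ledger]`,
`[chain]`, `[detect]`, `[simulate]` and `[gaintest]` sections; unknown keys
are rejected.

## Acceptance script

`scripts/acceptance.R` recomputes the kit's headline quantities from
scratch with the installed package — the per-turn displacement of the
stock drive, the turn counts and strokes of the draw/calibration
procedures, the gear-train ratios from tooth counts, and the median
relative gain deviation over 20 seeded synthetic saline-bath runs — and
writes them to JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/microdrive-methods.Rmd`) describes the
kinematic model, the depth and calibration conventions, each stage of the
signal chain with its defaults, what the synthetic generator does and does
not emulate, and the numerical choices (exact rational gear ratios,
zero-phase filtering, tie-breaking in turn planning).
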
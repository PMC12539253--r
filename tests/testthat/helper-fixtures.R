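# Shared fixtures: the kit's stock drive (0.3 mm pitch screw behind the
# two-stage 25:1 screwdriver) and compact synthetic-recording builders.

kit_drive <- function() kepler_drive_config(0.3)

kit_geometry <- function() implant_geometry(skull_thickness_mm = 0.7,
                                            base_wall_mm = 0.5)

# a quiet block with one injected spike, no noise, no quantization artifacts
# beyond the int16 grid
one_spike_plan <- function(channel = 8, trough_uv = -150, decay = 0.4,
                           n_channels = 15, noise_sd_uv = 0, seed = 1,
                           duration_s = 0.5, time_s = 0.25) {
  simulation_plan(
    n_channels = n_channels, duration_s = duration_s, noise_sd_uv = noise_sd_uv,
    seed = seed,
    spikes = data.frame(channel = channel, time_s = time_s,
                        trough_uv = trough_uv, decay = decay))
}

# recall-world plan: many supra-threshold spikes over realistic raw
# background (50 Hz line interference dominates the raw trace, as LFP does
# in vivo), so the artifact z-score sees a plausible whole-channel SD
recall_world_plan <- function(seed, n_spikes = 220, n_channels = 15,
                              duration_s = 10, noise_sd_uv = 8) {
  rate <- 30000
  sched <- local({
    set.seed(seed + 1000L)
    data.frame(
      channel = sample.int(n_channels, n_spikes, replace = TRUE),
      time_s = sort(stats::runif(n_spikes, 0.05, duration_s - 0.05)),
      trough_uv = stats::runif(n_spikes, -200, -150),
      decay = 0.4)
  })
  simulation_plan(n_channels = n_channels, duration_s = duration_s,
                  rate_hz = rate, noise_sd_uv = noise_sd_uv, seed = seed,
                  spikes = sched,
                  line_noise = list(freq_hz = 50, amplitude_uv = 200))
}

# run the CLI capturing stdout and suppressing log messages
capture_cli <- function(args) {
  out <- capture.output(status <- suppressMessages(microdrive_cli(args)),
                        type = "output")
  list(status = status, out = out)
}
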
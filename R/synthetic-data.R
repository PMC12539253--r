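# Seeded synthetic recordings with known ground truth: Gaussian background,
# negative-dominant spike templates with geometric cross-channel decay,
# rectangular artifacts, optional mains interference, and the saline-bath
# gain-test pulse train.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Biphasic spike template
#'
#' Unit-amplitude, negative-dominant difference-of-Gaussians: a sharp trough
#' at one third of the duration followed by a slower positive rebound,
#' normalised so the global extremum is exactly -1. Scaling by a (negative)
#' target trough amplitude yields the injected waveform.
#'
#' @param rate_hz Sampling rate in Hz (default 30000).
#' @param duration_ms Template duration in ms (default 1.2, inside the
#'   1.7 ms clip).
#' @param trough_frac Position of the trough as a fraction of the duration
#'   (default 1/3).
#' @return Numeric vector with `min == -1`.
#' @export
spike_template <- function(rate_hz = 30000, duration_ms = 1.2,
                           trough_frac = 1 / 3) {
  stopifnot(rate_hz > 0, duration_ms > 0, trough_frac > 0, trough_frac < 1)
  n <- max(3L, as.integer(round(duration_ms * rate_hz / 1000)))
  t <- seq(0, duration_ms, length.out = n)
  tc <- duration_ms * trough_frac
  s1 <- duration_ms / 9          # narrow trough
  s2 <- duration_ms / 4.5        # broad rebound
  w <- -exp(-(t - tc)^2 / (2 * s1^2)) +
    0.35 * exp(-(t - (tc + duration_ms / 3))^2 / (2 * s2^2))
  w / abs(min(w))
}

#' Simulation plan for a synthetic recording
#'
#' Declares everything about a synthetic multichannel recording: geometry,
#' background noise, a spike schedule with per-spike cross-channel geometric
#' amplitude decay, an artifact schedule and optional 50/60 Hz line
#' interference. The same plan and seed always produce a bit-identical
#' recording.
#'
#' @param n_channels Number of channels.
#' @param duration_s Duration in seconds.
#' @param rate_hz Sampling rate (default 30000).
#' @param noise_sd_uv Background Gaussian noise SD in uV.
#' @param seed Integer RNG seed.
#' @param spikes Data frame with columns `channel`, `time_s`, `trough_uv`
#'   (negative) and `decay` (per-channel-step amplitude factor in [0, 1)).
#' @param artifacts Data frame with columns `time_s`, `amplitude_sd` (in
#'   units of `noise_sd_uv`, signed) and `width_ms`; applied to all channels.
#' @param line_noise `NULL` or a list with `freq_hz` (50 or 60) and
#'   `amplitude_uv`.
#' @param scale_uv_per_bit int16 quantization step applied last
#'   (default 0.195).
#' @return An object of class `simulation_plan`.
#' @export
simulation_plan <- function(n_channels, duration_s, rate_hz = 30000,
                            noise_sd_uv = 5, seed = 1,
                            spikes = NULL, artifacts = NULL,
                            line_noise = NULL, scale_uv_per_bit = 0.195) {
  stopifnot(n_channels >= 1, duration_s > 0, rate_hz > 0, noise_sd_uv >= 0,
            scale_uv_per_bit > 0)
  if (is.null(spikes)) {
    spikes <- data.frame(channel = integer(0), time_s = numeric(0),
                         trough_uv = numeric(0), decay = numeric(0))
  }
  if (is.null(artifacts)) {
    artifacts <- data.frame(time_s = numeric(0), amplitude_sd = numeric(0),
                            width_ms = numeric(0))
  }
  stopifnot(all(c("channel", "time_s", "trough_uv", "decay") %in%
                  names(spikes)),
            all(c("time_s", "amplitude_sd", "width_ms") %in% names(artifacts)))
  if (nrow(spikes)) {
    stopifnot(all(spikes$trough_uv < 0),
              all(spikes$decay >= 0 & spikes$decay < 1),
              all(spikes$channel >= 1 & spikes$channel <= n_channels))
  }
  if (!is.null(line_noise)) {
    stopifnot(line_noise$freq_hz %in% c(50, 60), line_noise$amplitude_uv >= 0)
  }
  structure(list(n_channels = as.integer(n_channels),
                 duration_s = duration_s, rate_hz = rate_hz,
                 noise_sd_uv = noise_sd_uv, seed = as.integer(seed),
                 spikes = spikes, artifacts = artifacts,
                 line_noise = line_noise,
                 scale_uv_per_bit = scale_uv_per_bit),
            class = "simulation_plan")
}

#' Simulate a multichannel extracellular recording
#'
#' Renders the plan: Gaussian background, each scheduled spike added on its
#' channel and, attenuated geometrically (`decay^|offset|`), on physical
#' neighbors; rectangular artifacts across all channels; optional mains
#' sinusoid; int16 quantization last. Ground truth lists every injected
#' spike with its channel, trough sample and trough amplitude.
#'
#' @param plan A `simulation_plan`.
#' @return A list with `block` (a `recording_block`) and `truth` (data frame
#'   `channel`, `sample`, `amplitude_uv`).
#' @export
simulate_recording <- function(plan) {
  stopifnot(inherits(plan, "simulation_plan"))
  n <- as.integer(round(plan$duration_s * plan$rate_hz))
  nch <- plan$n_channels
  tmpl <- spike_template(plan$rate_hz)
  ltm <- length(tmpl)
  itrough <- which.min(tmpl)

  data <- with_seed(plan$seed, {
    matrix(stats::rnorm(n * nch, 0, plan$noise_sd_uv), n, nch)
  })
  if (!is.null(plan$line_noise) && plan$line_noise$amplitude_uv > 0) {
    tt <- (seq_len(n) - 1) / plan$rate_hz
    data <- data + plan$line_noise$amplitude_uv *
      sin(2 * pi * plan$line_noise$freq_hz * tt)
  }

  truth <- data.frame(channel = integer(0), sample = integer(0),
                      amplitude_uv = numeric(0))
  if (nrow(plan$spikes)) {
    for (i in seq_len(nrow(plan$spikes))) {
      sp <- plan$spikes[i, ]
      s0 <- as.integer(round(sp$time_s * plan$rate_hz)) + 1L
      if (s0 < 1L || s0 + ltm - 1L > n) {
        stop(sprintf("spike %d at %.4f s falls outside the recording", i,
                     sp$time_s), call. = FALSE)
      }
      idx <- s0:(s0 + ltm - 1L)
      for (ch in seq_len(nch)) {
        d <- abs(ch - sp$channel)
        amp <- abs(sp$trough_uv) * sp$decay^d
        if (amp < plan$scale_uv_per_bit / 2) next  # below quantization floor
        data[idx, ch] <- data[idx, ch] + tmpl * amp
      }
      truth <- rbind(truth, data.frame(channel = as.integer(sp$channel),
                                       sample = s0 + itrough - 1L,
                                       amplitude_uv = sp$trough_uv))
    }
  }
  if (nrow(plan$artifacts)) {
    for (i in seq_len(nrow(plan$artifacts))) {
      ar <- plan$artifacts[i, ]
      s0 <- as.integer(round(ar$time_s * plan$rate_hz)) + 1L
      w <- max(1L, as.integer(round(ar$width_ms * plan$rate_hz / 1000)))
      if (s0 < 1L || s0 + w - 1L > n) {
        stop(sprintf("artifact %d at %.4f s falls outside the recording", i,
                     ar$time_s), call. = FALSE)
      }
      data[s0:(s0 + w - 1L), ] <- data[s0:(s0 + w - 1L), ] +
        ar$amplitude_sd * plan$noise_sd_uv
    }
  }
  data <- quantize_int16(data, plan$scale_uv_per_bit)
  list(block = recording_block(data, plan$rate_hz,
                               scale_uv_per_bit = plan$scale_uv_per_bit),
       truth = truth)
}

quantize_int16 <- function(x, scale) {
  q <- pmin(pmax(round(x / scale), -32768), 32767)
  q * scale
}

#' Saline-bath gain-test plan
#'
#' The bench routine for verifying the acquisition gain: a stimulator drives
#' a train of square pulses (100 pulses of 100 us, spaced 250 ms apart by
#' default) through the bath while the probe records at a nominal gain of
#' 1000. The recorded pulse amplitude equals the true amplitude times the
#' actual gain; a healthy system deviates from nominal by at most 10%.
#'
#' @param true_amplitude_uv True pulse amplitude at the electrode, in uV.
#' @param n_pulses Number of pulses (default 100).
#' @param pulse_width_us Pulse width in us (default 100).
#' @param pulse_spacing_ms Pulse spacing in ms (default 250).
#' @param nominal_gain Gain set on the acquisition system (default 1000).
#' @param actual_gain True gain realised by the hardware; defaults to
#'   `nominal_gain`.
#' @param noise_sd_uv Recorded background noise SD (in recorded units).
#' @param rate_hz Sampling rate (default 30000).
#' @param seed Integer RNG seed.
#' @param scale_uv_per_bit Quantization step of the recording (default 0.195).
#' @return An object of class `gain_test_plan`.
#' @export
gain_test_plan <- function(true_amplitude_uv = 5, n_pulses = 100,
                           pulse_width_us = 100, pulse_spacing_ms = 250,
                           nominal_gain = 1000, actual_gain = NULL,
                           noise_sd_uv = 0, rate_hz = 30000, seed = 1,
                           scale_uv_per_bit = 0.195) {
  stopifnot(true_amplitude_uv > 0, n_pulses >= 0, pulse_width_us > 0,
            pulse_spacing_ms > 0, nominal_gain > 0, noise_sd_uv >= 0,
            rate_hz > 0)
  if (is.null(actual_gain)) actual_gain <- nominal_gain
  structure(list(true_amplitude_uv = true_amplitude_uv,
                 n_pulses = as.integer(n_pulses),
                 pulse_width_us = pulse_width_us,
                 pulse_spacing_ms = pulse_spacing_ms,
                 nominal_gain = nominal_gain, actual_gain = actual_gain,
                 noise_sd_uv = noise_sd_uv, rate_hz = rate_hz,
                 seed = as.integer(seed),
                 scale_uv_per_bit = scale_uv_per_bit),
            class = "gain_test_plan")
}

#' Simulate a saline-bath gain-test recording
#'
#' One channel of Gaussian noise with `n_pulses` rectangular deflections of
#' amplitude `true_amplitude_uv * actual_gain`, at exactly the planned width
#' and spacing, quantized to the int16 grid.
#'
#' @param plan A `gain_test_plan`.
#' @return A single-channel `recording_block`.
#' @export
simulate_gain_test <- function(plan) {
  stopifnot(inherits(plan, "gain_test_plan"))
  spacing <- as.integer(round(plan$pulse_spacing_ms * plan$rate_hz / 1000))
  width <- max(1L, as.integer(round(plan$pulse_width_us * 1e-6 * plan$rate_hz)))
  n <- spacing * max(plan$n_pulses, 1L) + spacing
  x <- with_seed(plan$seed, stats::rnorm(n, 0, plan$noise_sd_uv))
  amp <- plan$true_amplitude_uv * plan$actual_gain
  if (plan$n_pulses > 0) {
    starts <- spacing %/% 2L + (seq_len(plan$n_pulses) - 1L) * spacing + 1L
    for (s in starts) x[s:(s + width - 1L)] <- x[s:(s + width - 1L)] + amp
  }
  # bench signal kept at float precision: the estimator compares medians of
  # recorded units, where int16 quantization is irrelevant and would break
  # the exactness of the noise-free case
  recording_block(matrix(x, ncol = 1), plan$rate_hz,
                  scale_uv_per_bit = plan$scale_uv_per_bit)
}

#' Estimate gain from a gain-test recording
#'
#' Pulses are located by thresholding at half the expected recorded
#' amplitude (`0.5 * true * nominal`); the measured amplitude is the median
#' of the per-pulse peak deflections, the gain is measured over true, and
#' the relative deviation is `|gain - nominal| / nominal` (the user-manual
#' acceptance bound is 0.10).
#'
#' @param block A single-channel `recording_block` from the gain test.
#' @param true_amplitude_uv True pulse amplitude in uV.
#' @param nominal_gain Gain set on the system (default 1000).
#' @return A list with `gain`, `relative_deviation`, `n_pulses_detected`
#'   and `measured_amplitude`.
#' @export
estimate_gain <- function(block, true_amplitude_uv, nominal_gain = 1000) {
  stopifnot(inherits(block, "recording_block"), true_amplitude_uv > 0,
            nominal_gain > 0)
  x <- block$data[, 1]
  thr <- 0.5 * true_amplitude_uv * nominal_gain
  above <- x > thr
  if (!any(above)) {
    stop("no pulses detected above half the expected amplitude", call. = FALSE)
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  starts <- starts[r$values]
  ends <- ends[r$values]
  peaks <- mapply(function(s, e) max(x[s:e]), starts, ends)
  measured <- stats::median(peaks)
  gain <- measured / true_amplitude_uv
  list(gain = gain,
       relative_deviation = abs(gain - nominal_gain) / nominal_gain,
       n_pulses_detected = length(peaks),
       measured_amplitude = measured)
}

#' Score detections against injected ground truth
#'
#' Greedy nearest matching per channel: candidate truth/event pairs within
#' `tolerance_samples` are matched in order of increasing time difference,
#' each truth entry and each event used at most once.
#'
#' @param events A `spike_events` object (or a data frame with `channel` and
#'   `peak_sample`).
#' @param truth Ground-truth data frame with `channel` and `sample`.
#' @param tolerance_samples Maximum |event - truth| distance in samples.
#' @return A list with `recall`, `precision`, `n_matched` and a `matches`
#'   data frame.
#' @export
evaluate_detection <- function(events, truth, tolerance_samples = 15) {
  stopifnot(tolerance_samples >= 0)
  if (inherits(events, "spike_events")) {
    ev <- data.frame(channel = events$channel,
                     peak_sample = events$peak_sample)
  } else {
    ev <- as.data.frame(events)
  }
  n_truth <- nrow(truth)
  n_event <- nrow(ev)
  matches <- data.frame(truth_row = integer(0), event_row = integer(0),
                        distance = integer(0))
  if (n_truth > 0 && n_event > 0) {
    pairs <- do.call(rbind, lapply(seq_len(n_truth), function(i) {
      j <- which(ev$channel == truth$channel[i] &
                   abs(ev$peak_sample - truth$sample[i]) <= tolerance_samples)
      if (!length(j)) return(NULL)
      data.frame(truth_row = i, event_row = j,
                 distance = abs(ev$peak_sample[j] - truth$sample[i]))
    }))
    if (!is.null(pairs) && nrow(pairs)) {
      pairs <- pairs[order(pairs$distance, pairs$truth_row, pairs$event_row), ]
      used_t <- logical(n_truth)
      used_e <- logical(n_event)
      for (k in seq_len(nrow(pairs))) {
        i <- pairs$truth_row[k]
        j <- pairs$event_row[k]
        if (used_t[i] || used_e[j]) next
        used_t[i] <- TRUE
        used_e[j] <- TRUE
        matches <- rbind(matches, pairs[k, ])
      }
    }
  }
  list(recall = if (n_truth) nrow(matches) / n_truth else NA_real_,
       precision = if (n_event) nrow(matches) / n_event else NA_real_,
       n_matched = nrow(matches),
       matches = matches)
}
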
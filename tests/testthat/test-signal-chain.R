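test_that("band-pass design matches an independent reference design", {
  # frozen from scipy.signal.butter(2, c(300, 5000), 'bandpass', fs = 30000)
  b_ref <- c(0.14053445464506825, 0, -0.2810689092901365, 0,
             0.14053445464506825)
  a_ref <- c(1.0, -2.6004355380789437, 2.5148793863637153,
             -1.1706416812029927, 0.2586815534454941)
  co <- butter_bandpass(300, 5000, 30000, 2)
  expect_equal(co$b, b_ref, tolerance = 1e-12)
  expect_equal(co$a, a_ref, tolerance = 1e-12)
  expect_error(butter_bandpass(300, 20000, 30000), "Nyquist")
  expect_error(butter_bandpass(0, 5000, 30000), "Nyquist")
})

test_that("zero-phase filtering matches a reference forward-backward filter", {
  # frozen scipy.signal.filtfilt output for the design above
  x <- c(0, 6.442, 9.854, 8.632, 3.35, -3.508, -8.716, -9.825, -6.313,
         0.168, 6.57, 9.882, 8.546, 3.191, -3.665, -8.797, -9.792, -6.181,
         0.336, 6.696, 9.906, 8.457, 3.031, -3.821, -8.876, -9.756, -6.048,
         0.504, 6.82, 9.928, 8.367, 2.871, -3.976, -8.952, -9.718, -5.914,
         0.672, 6.942, 9.946, 8.273)
  y_ref <- c(0.3015602924, 6.2744419875, 9.5099434986, 8.5630882481,
             3.9502809595, -2.0938923499, -6.6679490717, -7.568539245,
             -4.3271645606, 1.5690549242, 7.3764028737, 10.3846135242,
             9.1911881138, 4.3606029313, -1.8416235834, -6.5148752279,
             -7.488056805, -4.3411047316, 1.3970518724, 6.9671536816,
             9.6769086629, 8.1668260422, 3.0491908904, -3.3803006113,
             -8.2225609191, -9.3389615233, -6.3576609262, -0.8492052874,
             4.4112137317, 6.7487954274, 4.8493467898, -0.6175463652,
             -7.3095998864, -12.3224895883, -13.5916395996, -10.9188799337,
             -6.0750215216, -1.7929021715, -0.0241321334, -0.521249973)
  co <- butter_bandpass(300, 5000, 30000, 2)
  expect_equal(microdrive:::filtfilt_fb(co$b, co$a, x), y_ref,
               tolerance = 1e-8)
})

test_that("band-pass kills DC, passes 1 kHz, rejects 10 Hz", {
  rate <- 30000
  n <- rate  # 1 s
  t <- (seq_len(n) - 1) / rate
  mk <- function(x) recording_block(matrix(x, ncol = 1), rate)
  margin <- seq.int(floor(0.05 * n), ceiling(0.95 * n))

  dc <- bandpass_filter(mk(rep(100, n)))
  expect_lt(max(abs(dc$data[margin, 1])), 100 * 1e-6)

  s1k <- bandpass_filter(mk(sin(2 * pi * 1000 * t)))
  g <- max(abs(s1k$data[seq.int(floor(0.1 * n), ceiling(0.9 * n)), 1]))
  expect_gte(g, 0.95)
  expect_lte(g, 1.0)

  s10 <- bandpass_filter(mk(sin(2 * pi * 10 * t)))
  expect_lt(max(abs(s10$data[margin, 1])), 0.05)
})

test_that("artifact masking flags rectangular excursions and spares noise", {
  rate <- 30000
  n <- 2 * rate
  set.seed(21)
  sigma <- 10
  x <- matrix(stats::rnorm(2 * n, 0, sigma), n, 2)
  a0 <- rate  # artifact at 1 s, 10 ms, +15 sigma, channel 1 only
  aw <- round(0.010 * rate)
  x[a0:(a0 + aw - 1), 1] <- x[a0:(a0 + aw - 1), 1] + 15 * sigma
  blk <- recording_block(x, rate)
  res <- remove_artifacts(blk, artifact_z = 10, guard_ms = 2)
  expect_true(all(res$mask[a0:(a0 + aw - 1), 1]))
  # mask confined to the artifact plus its guard window
  guard <- round(0.002 * rate)
  outside <- setdiff(seq_len(n), (a0 - guard):(a0 + aw - 1 + guard))
  expect_false(any(res$mask[outside, 1]))
  # clean channel untouched (P(|z| >= 10) is negligible at this n)
  expect_false(any(res$mask[, 2]))
  expect_identical(res$block$data[, 2], x[, 2])
  # masked samples were replaced by the channel median
  expect_true(all(res$block$data[a0:(a0 + aw - 1), 1] ==
                    stats::median(x[, 1])))
  # all-constant channel: no masking, warning
  cblk <- recording_block(matrix(5, 1000, 1), rate)
  expect_warning(cres <- remove_artifacts(cblk), "zero variance")
  expect_identical(cres$block$data, cblk$data)
  expect_false(any(cres$mask))
})

test_that("local averaging cancels common-mode signal and spares singletons", {
  rate <- 30000
  n <- 3000
  common <- sin(2 * pi * 50 * (seq_len(n) - 1) / rate) * 200
  blk <- recording_block(matrix(common, n, 15), rate)
  out <- local_average_reference(blk, 7)
  expect_lt(max(abs(out$data)), 1e-9)
  one <- recording_block(matrix(common, n, 1), rate)
  expect_identical(local_average_reference(one, 7)$data, one$data)
})

test_that("local averaging spreads -signal/k onto neighbors", {
  n <- 1000
  nch <- 15
  sig <- sin(seq_len(n) / 20) * 50
  x <- matrix(0, n, nch)
  c0 <- 8
  x[, c0] <- sig
  out <- local_average_reference(recording_block(x, 30000), 7)
  # channel c0: none of its neighbors carry signal, so it is unchanged
  expect_equal(out$data[, c0], sig, tolerance = 1e-12)
  for (ch in seq_len(nch)[-c0]) {
    d <- abs(ch - c0)
    # neighbor count of channel ch: up to 7 on each side, truncated at edges
    k <- length(setdiff(intersect((ch - 7):(ch + 7), 1:nch), ch))
    expected <- if (d <= 7) -sig / k else rep(0, n)
    expect_equal(out$data[, ch], expected, tolerance = 1e-12)
  }
})

test_that("threshold detection finds injected troughs and centers clips", {
  rate <- 30000
  sim <- simulate_recording(one_spike_plan(channel = 8, trough_uv = -100,
                                           noise_sd_uv = 5, seed = 5))
  ev <- detect_spikes(sim$block, 8)
  expect_identical(length(ev$peak_sample), 1L)
  # noise at the trough can promote the adjacent sample by one position
  expect_lte(abs(ev$peak_sample - sim$truth$sample), 1L)
  expect_equal(ev$peak_uv, sim$truth$amplitude_uv, tolerance = 0.2)
  # inverted clip: center sample is the maximum
  expect_identical(which.max(ev$clips[1, ]), (ev$clip_samples + 1L) %/% 2L)
  expect_identical(ev$clip_samples, 51L)  # 1.7 ms at 30 kHz, forced odd

  # same template at -70 uV stays above the -80 uV threshold: no events
  sim70 <- simulate_recording(one_spike_plan(channel = 8, trough_uv = -70,
                                             noise_sd_uv = 5, seed = 5))
  expect_identical(length(detect_spikes(sim70$block, 8)$peak_sample), 0L)

  # flat trace: no events; bad channel: error
  zero <- recording_block(matrix(0, rate, 2), rate)
  expect_identical(length(detect_spikes(zero, 1)$peak_sample), 0L)
  expect_error(detect_spikes(zero, 9), "out of range")
})

test_that("average waveform is the pointwise mean with CLT-scale error", {
  rate <- 30000
  nclip <- clip_length_samples(1.7, rate)
  tmpl <- spike_template(rate)
  # peak-centered inverted clip of the scaled template
  half <- (nclip - 1L) %/% 2L
  itr <- which.min(tmpl)
  idx <- (itr - half):(itr + half)
  base <- -120 * ifelse(idx >= 1 & idx <= length(tmpl),
                        tmpl[pmax(pmin(idx, length(tmpl)), 1)], 0)
  mk_events <- function(clips) {
    structure(list(channel = rep(1L, nrow(clips)),
                   peak_sample = seq_len(nrow(clips)) * 1000L,
                   peak_uv = rep(-120, nrow(clips)),
                   clips = clips, clip_samples = nclip, rate_hz = rate),
              class = "spike_events")
  }
  # 100 noisy aligned copies: mean within 4*sigma/sqrt(n) per sample
  sigma <- 4
  nrep <- 100
  set.seed(9)
  noisy <- matrix(rep(base, each = nrep), nrep, nclip) +
    matrix(stats::rnorm(nrep * nclip, 0, sigma), nrep, nclip)
  avg <- average_waveform(mk_events(noisy))
  expect_equal(avg$n, nrep)
  expect_lt(max(abs(avg$mean - base)), 4 * sigma / sqrt(nrep))
  expect_equal(mean(avg$sd), sigma, tolerance = 0.15)
  # two clips: pointwise (a + b) / 2
  a <- base + 1
  b <- base - 3
  avg2 <- average_waveform(mk_events(rbind(a, b)))
  expect_equal(avg2$mean, (a + b) / 2)
  # identical clips: mean equals the clip, sd 0
  avg3 <- average_waveform(mk_events(rbind(a, a)))
  expect_equal(avg3$mean, a)
  expect_identical(max(avg3$sd), 0)
  empty <- detect_spikes(recording_block(matrix(0, rate, 1), rate), 1)
  expect_error(average_waveform(empty), "no events")
})

test_that("footprints follow the geometric decay and the threshold cutoff", {
  # trough -150, decay 0.6: neighbors +-1 at -90 detected, +-2 at -54 absent
  sim <- simulate_recording(one_spike_plan(channel = 8, trough_uv = -150,
                                           decay = 0.6, noise_sd_uv = 0))
  ev <- detect_spikes(sim$block, 8)
  fp <- cross_channel_footprint(sim$block, footprint_event(ev, 1))
  expect_identical(fp$offsets, setdiff(-4:4, 0))
  d1 <- fp$detected[abs(fp$offsets) == 1]
  d2plus <- fp$detected[abs(fp$offsets) >= 2]
  expect_true(all(d1))
  expect_false(any(d2plus))
  expect_equal(fp$peak_uv[fp$offsets == 1], -90, tolerance = 0.2)
  expect_equal(fp$peak_uv[fp$offsets == -1], -90, tolerance = 0.2)

  # single-channel block: empty footprint
  one <- simulate_recording(one_spike_plan(channel = 1, n_channels = 1,
                                           trough_uv = -150, noise_sd_uv = 0))
  ev1 <- detect_spikes(one$block, 1)
  fp1 <- cross_channel_footprint(one$block, footprint_event(ev1, 1))
  expect_identical(length(fp1$offsets), 0L)

  # uncorrelated noise on neighbors: absent (threshold tail probability)
  set.seed(13)
  x <- matrix(stats::rnorm(30000 * 3, 0, 5), 30000, 3)
  tmpl <- spike_template(30000)
  x[1000:(999 + length(tmpl)), 2] <- x[1000:(999 + length(tmpl)), 2] +
    150 * tmpl
  blk <- recording_block(x, 30000)
  evn <- detect_spikes(blk, 2)
  fpn <- cross_channel_footprint(blk, footprint_event(evn, 1))
  expect_false(any(fpn$detected))
})

test_that("footprint amplitudes decay monotonically with channel distance", {
  sim <- simulate_recording(one_spike_plan(channel = 8, trough_uv = -400,
                                           decay = 0.75, noise_sd_uv = 0))
  ev <- detect_spikes(sim$block, 8)
  fp <- cross_channel_footprint(sim$block, footprint_event(ev, 1))
  for (side in list(fp$offsets > 0, fp$offsets < 0)) {
    amps <- abs(fp$peak_uv[side][order(abs(fp$offsets[side]))])
    amps <- amps[!is.na(amps)]
    if (length(amps) > 1) expect_true(all(diff(amps) <= 1e-9))
  }
  expect_true(any(fp$detected))
})

test_that("full chain is deterministic, ordered, and linear without artifacts", {
  plan <- recall_world_plan(seed = 2, n_spikes = 12, duration_s = 1.2)
  sim <- simulate_recording(plan)
  r1 <- run_chain(sim$block, footprints = FALSE)
  r2 <- run_chain(sim$block, footprints = FALSE)
  expect_identical(r1$block$data, r2$block$data)
  expect_identical(r1$audit$n_events_per_channel,
                   r2$audit$n_events_per_channel)
  expect_identical(r1$audit$stage_order,
                   c("artifacts", "local_average_reference", "bandpass",
                     "detect"))
  # zero input: zero events
  zero <- recording_block(matrix(0, 30000, 4), 30000)
  rz <- suppressWarnings(run_chain(zero, footprints = FALSE))
  expect_identical(sum(rz$audit$n_events_per_channel), 0L)
  # linearity of the pre-processing stages (artifact stage cannot trigger)
  pre <- function(m) {
    blk <- recording_block(m, 30000)
    st2 <- local_average_reference(blk, 7)
    bandpass_filter(st2)$data
  }
  set.seed(31)
  a <- matrix(stats::rnorm(8000 * 4, 0, 5), 8000, 4)
  b <- matrix(stats::rnorm(8000 * 4, 0, 5), 8000, 4)
  expect_equal(pre(a + b), pre(a) + pre(b), tolerance = 1e-6)
})
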
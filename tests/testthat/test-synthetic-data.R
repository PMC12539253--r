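test_that("spike template is unit-amplitude and negative-dominant", {
  tmpl <- spike_template(30000)
  expect_identical(min(tmpl), -1)
  expect_lt(max(tmpl), 1)
  expect_lte(length(tmpl) / 30000 * 1000, 1.7)  # fits inside the clip
  # trough sits at roughly a third of the duration
  expect_equal(which.min(tmpl) / length(tmpl), 1 / 3, tolerance = 0.1)
})

test_that("simulated recordings honor the plan exactly", {
  # no spikes, no artifacts, no noise: all zeros
  quiet <- simulate_recording(simulation_plan(4, 0.05, noise_sd_uv = 0,
                                              seed = 1))
  expect_true(all(quiet$block$data == 0))
  expect_identical(nrow(quiet$truth), 0L)

  # cross-channel decay arithmetic: -150 trough, decay 0.6
  sim <- simulate_recording(one_spike_plan(channel = 8, trough_uv = -150,
                                           decay = 0.6, noise_sd_uv = 0))
  mins <- apply(sim$block$data, 2, min)
  q <- sim$block$scale_uv_per_bit
  expect_equal(mins[8], -150, tolerance = q)
  expect_equal(mins[7], -90, tolerance = q)
  expect_equal(mins[9], -90, tolerance = q)
  expect_equal(mins[6], -54, tolerance = q)
  expect_equal(mins[10], -54, tolerance = q)
  # trough lands where the truth log says
  expect_identical(which.min(sim$block$data[, 8]), sim$truth$sample)

  # injected-amplitude conservation within one quantization step
  for (tr in c(-120, -199.7, -83.3)) {
    s <- simulate_recording(one_spike_plan(channel = 3, trough_uv = tr,
                                           noise_sd_uv = 0))
    expect_equal(min(s$block$data[, 3]), tr, tolerance = q)
  }

  # schedule outside the duration is refused
  bad <- one_spike_plan(time_s = 0.4999)
  expect_error(simulate_recording(bad), "outside the recording")
})

test_that("identical plan and seed are bit-identical; seeds differ", {
  plan <- recall_world_plan(seed = 5, n_spikes = 10, duration_s = 0.6)
  a <- simulate_recording(plan)
  b <- simulate_recording(plan)
  expect_identical(a$block$data, b$block$data)
  expect_identical(a$truth, b$truth)
  plan2 <- recall_world_plan(seed = 6, n_spikes = 10, duration_s = 0.6)
  expect_false(identical(simulate_recording(plan2)$block$data, a$block$data))
  # the generator must not disturb the caller's RNG stream
  set.seed(123)
  before <- stats::runif(1)
  set.seed(123)
  invisible(simulate_recording(plan))
  expect_identical(stats::runif(1), before)
})

test_that("line interference and artifacts are injected as planned", {
  rate <- 30000
  plan <- simulation_plan(3, 0.2, rate_hz = rate, noise_sd_uv = 0, seed = 2,
                          artifacts = data.frame(time_s = 0.1,
                                                 amplitude_sd = 15,
                                                 width_ms = 10),
                          line_noise = list(freq_hz = 60, amplitude_uv = 50))
  # artifacts scale with noise_sd; with zero noise only the sinusoid remains
  sim <- simulate_recording(plan)
  x <- sim$block$data[, 1]
  t <- (seq_along(x) - 1) / rate
  expect_equal(x, 50 * sin(2 * pi * 60 * t),
               tolerance = sim$block$scale_uv_per_bit)
  # with unit noise SD the artifact plateau is visible at +15
  plan2 <- simulation_plan(1, 0.2, rate_hz = rate, noise_sd_uv = 1, seed = 2,
                           artifacts = data.frame(time_s = 0.1,
                                                  amplitude_sd = 15,
                                                  width_ms = 10))
  sim2 <- simulate_recording(plan2)
  a0 <- round(0.1 * rate) + 1
  seg <- sim2$block$data[a0:(a0 + round(0.01 * rate) - 1), 1]
  expect_gt(mean(seg), 10)
  expect_lt(mean(sim2$block$data[1:(a0 - 10), 1]), 2)
})

test_that("gain test bench: exact pulse train and measured-over-true gain", {
  plan <- gain_test_plan(true_amplitude_uv = 5, n_pulses = 100,
                         noise_sd_uv = 0, seed = 1)
  blk <- simulate_gain_test(plan)
  x <- blk$data[, 1]
  runs <- rle(x > 0.5 * 5 * 1000)
  expect_identical(sum(runs$values), 100L)            # exactly 100 pulses
  expect_true(all(runs$lengths[runs$values] == 3L))   # 100 us at 30 kHz
  starts <- cumsum(c(1, runs$lengths))[which(runs$values)]
  expect_true(all(diff(starts) == round(0.250 * 30000)))

  est <- estimate_gain(blk, 5, 1000)
  expect_identical(est$gain, 1000)
  expect_identical(est$relative_deviation, 0)
  expect_identical(est$n_pulses_detected, 100L)

  # recording synthesized at 0.95 x nominal: deviation 0.05 by construction
  low <- simulate_gain_test(gain_test_plan(true_amplitude_uv = 5,
                                           actual_gain = 950,
                                           noise_sd_uv = 0))
  est_low <- estimate_gain(low, 5, 1000)
  expect_equal(est_low$relative_deviation, 0.05, tolerance = 1e-12)

  # no pulses: pure noise errors out
  none <- simulate_gain_test(gain_test_plan(true_amplitude_uv = 5,
                                            n_pulses = 0, noise_sd_uv = 1))
  expect_error(estimate_gain(none, 5, 1000), "no pulses")
})

test_that("gain recovery stays within the 10% bound across seeds", {
  # noise SD at 5% of the recorded pulse amplitude, 20 seeds
  amp <- 5 * 1000
  devs <- vapply(1:20, function(s) {
    plan <- gain_test_plan(true_amplitude_uv = 5, noise_sd_uv = 0.05 * amp,
                           seed = s)
    estimate_gain(simulate_gain_test(plan), 5, 1000)$relative_deviation
  }, numeric(1))
  expect_gte(sum(devs <= 0.10), 19)
})

test_that("detection scoring: greedy matching agrees with brute force", {
  # events == truth: perfect scores
  truth <- data.frame(channel = c(1L, 1L, 2L), sample = c(100L, 500L, 300L))
  ev <- data.frame(channel = truth$channel, peak_sample = truth$sample)
  sc <- evaluate_detection(ev, truth, 5)
  expect_identical(c(sc$recall, sc$precision), c(1, 1))

  # empty events: recall 0
  sc0 <- evaluate_detection(data.frame(channel = integer(0),
                                       peak_sample = integer(0)), truth, 5)
  expect_identical(sc0$recall, 0)

  # 3 truths / 2 events, one pair beyond tolerance; oracle enumerates all
  # one-to-one assignments and takes the maximum matching
  truth3 <- data.frame(channel = c(1L, 1L, 1L), sample = c(100L, 200L, 300L))
  ev2 <- data.frame(channel = c(1L, 1L), peak_sample = c(104L, 330L))
  brute_max_matching <- function(ev, truth, tol) {
    ok <- outer(seq_len(nrow(truth)), seq_len(nrow(ev)), function(i, j)
      truth$channel[i] == ev$channel[j] &
        abs(truth$sample[i] - ev$peak_sample[j]) <= tol)
    # exhaustive search over one-to-one assignments of events to truths
    rec <- function(j, used) {
      if (j > nrow(ev)) return(0L)
      best <- rec(j + 1L, used)  # leave event j unmatched
      for (i in setdiff(which(ok[, j]), used)) {
        best <- max(best, 1L + rec(j + 1L, c(used, i)))
      }
      best
    }
    rec(1L, integer(0))
  }
  for (tol in c(5, 40)) {
    sc <- evaluate_detection(ev2, truth3, tol)
    expect_equal(sc$n_matched, brute_max_matching(ev2, truth3, tol))
    expect_equal(sc$recall, sc$n_matched / 3)
  }
})
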
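#' Multichannel recording block
#'
#' In-memory container for an extracellular recording: a samples x channels
#' matrix in microvolts, the sampling rate, the physical channel order along
#' the shank (index distance = electrode distance) and the integer scale of
#' the backing file format.
#'
#' @param data Numeric matrix, samples in rows, channels in columns, in uV.
#' @param rate_hz Sampling rate in Hz.
#' @param channel_order Integer permutation of `1:ncol(data)` giving the
#'   physical order of the columns along the shank (default identity).
#' @param scale_uv_per_bit uV per integer step of the int16 storage format
#'   (default 0.195).
#' @return An object of class `recording_block`.
#' @export
recording_block <- function(data, rate_hz, channel_order = seq_len(ncol(data)),
                            scale_uv_per_bit = 0.195) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric matrix (samples x channels)", call. = FALSE)
  }
  stopifnot(is.numeric(rate_hz), length(rate_hz) == 1L, rate_hz > 0,
            is.numeric(scale_uv_per_bit), scale_uv_per_bit > 0)
  channel_order <- as.integer(channel_order)
  if (!identical(sort(channel_order), seq_len(ncol(data)))) {
    stop("`channel_order` must be a permutation of 1:n_channels",
         call. = FALSE)
  }
  structure(list(data = data, rate_hz = as.numeric(rate_hz),
                 channel_order = channel_order,
                 scale_uv_per_bit = as.numeric(scale_uv_per_bit)),
            class = "recording_block")
}

#' @export
print.recording_block <- function(x, ...) {
  cat(sprintf(
    "<recording_block> %d samples x %d channels @ %g Hz (%.3f s), %.4g uV/bit\n",
    nrow(x$data), ncol(x$data), x$rate_hz, nrow(x$data) / x$rate_hz,
    x$scale_uv_per_bit))
  invisible(x)
}

#' Pre-processing chain configuration
#'
#' Parameters of the three ordered pre-processing stages: artifact masking
#' (z >= 10 against the whole-channel distribution), local common average
#' referencing over 7 channels per side, and a zero-phase order-2
#' Butterworth band-pass at 300-5000 Hz.
#'
#' @param artifact_z Artifact threshold in SDs of the whole channel
#'   (default 10).
#' @param car_neighbors Channels per side used for local referencing
#'   (default 7).
#' @param bp_low_hz,bp_high_hz Band-pass edges in Hz (defaults 300 and 5000).
#' @param filter_order Butterworth prototype order (default 2).
#' @param artifact_guard_ms Guard window masked around each flagged sample,
#'   in ms per side (default 2).
#' @param car_mode `"per_side"` (up to `car_neighbors` above and below,
#'   default) or `"total"` (`car_neighbors` nearest channels in total).
#' @return An object of class `chain_config`.
#' @export
chain_config <- function(artifact_z = 10, car_neighbors = 7,
                         bp_low_hz = 300, bp_high_hz = 5000,
                         filter_order = 2, artifact_guard_ms = 2,
                         car_mode = c("per_side", "total")) {
  stopifnot(artifact_z > 0, car_neighbors >= 0,
            bp_low_hz > 0, bp_high_hz > bp_low_hz, filter_order >= 1,
            artifact_guard_ms >= 0)
  structure(list(artifact_z = artifact_z, car_neighbors = car_neighbors,
                 bp_low_hz = bp_low_hz, bp_high_hz = bp_high_hz,
                 filter_order = filter_order,
                 artifact_guard_ms = artifact_guard_ms,
                 car_mode = match.arg(car_mode)),
            class = "chain_config")
}

#' Spike detection configuration
#'
#' Spikes are negative threshold crossings: a contiguous run of samples below
#' `threshold_uv` (default -80 uV) whose most-negative sample also sits at
#' least `peak_z_min` SDs (default 1) from the whole-channel mean. Accepted
#' events are cut to `clip_ms` (default 1.7 ms) clips, inverted, with the
#' peak as the exact middle sample, and related to the nearest
#' `footprint_neighbors` (default 4) channels per side.
#'
#' @param threshold_uv Negative detection threshold in uV (default -80).
#' @param peak_z_min Secondary z-score filter on the peak (default 1).
#' @param clip_ms Clip duration in ms (default 1.7).
#' @param footprint_neighbors Channels per side for footprints (default 4).
#' @param lockout_samples Dead time after an accepted peak; `NULL` (default)
#'   means one clip length.
#' @return An object of class `detect_config`.
#' @export
detect_config <- function(threshold_uv = -80, peak_z_min = 1, clip_ms = 1.7,
                          footprint_neighbors = 4, lockout_samples = NULL) {
  stopifnot(threshold_uv < 0, peak_z_min >= 0, clip_ms > 0,
            footprint_neighbors >= 0)
  structure(list(threshold_uv = threshold_uv, peak_z_min = peak_z_min,
                 clip_ms = clip_ms, footprint_neighbors = footprint_neighbors,
                 lockout_samples = lockout_samples),
            class = "detect_config")
}

#' Clip length in samples
#'
#' `round(clip_ms * rate / 1000)`, forced odd (one added if even) so the
#' clip has a true median sample for peak centering. At 30 kHz the default
#' 1.7 ms clip is 51 samples.
#'
#' @param clip_ms Clip duration in ms.
#' @param rate_hz Sampling rate in Hz.
#' @return Odd integer number of samples.
#' @export
clip_length_samples <- function(clip_ms, rate_hz) {
  n <- as.integer(round(clip_ms * rate_hz / 1000))
  if (n %% 2L == 0L) n <- n + 1L
  max(n, 1L)
}

check_nyquist <- function(block, config) {
  if (block$rate_hz <= 2 * config$bp_high_hz) {
    stop(sprintf(
      "sampling rate %g Hz must exceed twice the band-pass upper edge (%g Hz)",
      block$rate_hz, config$bp_high_hz), call. = FALSE)
  }
  invisible(TRUE)
}

#' Stage 1: artifact masking
#'
#' Per channel, samples whose z-score against the whole-channel mean and SD
#' reaches `artifact_z` are flagged, a guard window of `guard_ms` per side is
#' added, and flagged samples are replaced by the channel median so sample
#' indices stay aligned across stages. Channels with zero variance are left
#' untouched (with a warning): the z-score is undefined and treated as 0.
#'
#' @param block A `recording_block`.
#' @param artifact_z Threshold in SDs (default 10).
#' @param guard_ms Guard window per side in ms (default 2).
#' @return A list with `block` (cleaned) and `mask` (logical samples x
#'   channels matrix of replaced samples).
#' @export
remove_artifacts <- function(block, artifact_z = 10, guard_ms = 2) {
  stopifnot(inherits(block, "recording_block"), artifact_z > 0)
  x <- block$data
  if (length(x) == 0) stop("empty recording block", call. = FALSE)
  guard <- as.integer(round(guard_ms * block$rate_hz / 1000))
  mask <- matrix(FALSE, nrow(x), ncol(x))
  for (ch in seq_len(ncol(x))) {
    v <- x[, ch]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      warning(sprintf("channel %d has zero variance; no artifact masking", ch),
              call. = FALSE)
      next
    }
    z <- abs(v - mean(v)) / s
    hit <- which(z >= artifact_z)
    if (!length(hit)) next
    m <- logical(length(v))
    for (h in hit) {
      m[max(1L, h - guard):min(length(v), h + guard)] <- TRUE
    }
    x[m, ch] <- stats::median(v)
    mask[, ch] <- m
  }
  list(block = recording_block(x, block$rate_hz, block$channel_order,
                               block$scale_uv_per_bit),
       mask = mask)
}

# positions along the shank: pos[i] = physical position of data column i
shank_positions <- function(block) {
  order(block$channel_order)
}

#' Stage 2: local common average referencing
#'
#' From each channel, subtracts the mean of its physical neighbors along the
#' shank: up to `car_neighbors` channels above and the same below (self
#' excluded), truncated at the array edges. Signal common to all channels is
#' annihilated; a single-channel block is returned unchanged.
#'
#' @param block A `recording_block`.
#' @param car_neighbors Channels per side (default 7).
#' @param mode `"per_side"` (default) or `"total"` (nearest `car_neighbors`
#'   channels in total, split across sides).
#' @return A re-referenced `recording_block`.
#' @export
local_average_reference <- function(block, car_neighbors = 7,
                                    mode = c("per_side", "total")) {
  stopifnot(inherits(block, "recording_block"), car_neighbors >= 0)
  mode <- match.arg(mode)
  nch <- ncol(block$data)
  if (nch <= 1 || car_neighbors == 0) return(block)
  # column index of the channel at each physical position
  col_at_pos <- order(shank_positions(block))
  out <- block$data
  for (pos in seq_len(nch)) {
    if (mode == "per_side") {
      nb_pos <- c(seq(pos - car_neighbors, pos - 1), seq(pos + 1, pos + car_neighbors))
    } else {
      k <- car_neighbors
      cand <- setdiff(order(abs(seq_len(nch) - pos)), pos)
      nb_pos <- cand[seq_len(min(k, length(cand)))]
    }
    nb_pos <- nb_pos[nb_pos >= 1 & nb_pos <= nch]
    if (!length(nb_pos)) next
    nb_cols <- col_at_pos[nb_pos]
    ref <- rowMeans(block$data[, nb_cols, drop = FALSE])
    out[, col_at_pos[pos]] <- block$data[, col_at_pos[pos]] - ref
  }
  recording_block(out, block$rate_hz, block$channel_order,
                  block$scale_uv_per_bit)
}

#' Stage 3: zero-phase Butterworth band-pass
#'
#' Applies the configured Butterworth band-pass forward and backward
#' (zero phase), so spike peak timing is preserved; the effective magnitude
#' response is the square of the designed filter.
#'
#' @param block A `recording_block`.
#' @param low_hz,high_hz Band edges in Hz (defaults 300 and 5000).
#' @param order Prototype order (default 2).
#' @return A filtered `recording_block`.
#' @export
bandpass_filter <- function(block, low_hz = 300, high_hz = 5000, order = 2) {
  stopifnot(inherits(block, "recording_block"))
  coefs <- butter_bandpass(low_hz, high_hz, block$rate_hz, order)
  out <- block$data
  for (ch in seq_len(ncol(out))) {
    out[, ch] <- filtfilt_fb(coefs$b, coefs$a, block$data[, ch])
  }
  recording_block(out, block$rate_hz, block$channel_order,
                  block$scale_uv_per_bit)
}

#' Threshold spike detection on one channel
#'
#' Candidates are contiguous runs of samples below the voltage threshold;
#' each run's peak is its most negative sample (earliest on ties). Peaks
#' within the lockout window after an accepted peak are skipped, peaks whose
#' |z| against the whole-channel distribution falls below `peak_z_min` are
#' discarded, and events whose clip would overrun the block edges are
#' dropped. Clips are inverted (spikes point up) and peak-centered.
#'
#' @param block A pre-processed `recording_block`.
#' @param channel Column index of the channel to scan.
#' @param config A `detect_config`.
#' @return An object of class `spike_events`: vectors `channel`,
#'   `peak_sample`, `peak_uv` and a clips matrix (one row per event,
#'   inverted waveform).
#' @export
detect_spikes <- function(block, channel, config = detect_config()) {
  stopifnot(inherits(block, "recording_block"),
            inherits(config, "detect_config"))
  if (!(channel %in% seq_len(ncol(block$data)))) {
    stop(sprintf("channel %s out of range (block has %d channels)",
                 as.character(channel), ncol(block$data)), call. = FALSE)
  }
  x <- block$data[, channel]
  nclip <- clip_length_samples(config$clip_ms, block$rate_hz)
  half <- (nclip - 1L) %/% 2L
  lockout <- if (is.null(config$lockout_samples)) nclip else
    as.integer(config$lockout_samples)

  below <- x < config$threshold_uv
  ev_peak <- integer(0)
  ev_uv <- numeric(0)
  if (any(below)) {
    r <- rle(below)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    starts <- starts[r$values]
    ends <- ends[r$values]
    peaks <- mapply(function(s, e) s + which.min(x[s:e]) - 1L, starts, ends)
    mu <- mean(x)
    s <- stats::sd(x)
    zok <- if (is.finite(s) && s > 0) {
      abs(x[peaks] - mu) / s >= config$peak_z_min
    } else rep(TRUE, length(peaks))
    peaks <- peaks[zok]
    last <- -Inf
    for (p in peaks) {
      if (p <= last + lockout) next
      if (p - half < 1L || p + half > length(x)) next  # clip would overrun
      ev_peak <- c(ev_peak, p)
      ev_uv <- c(ev_uv, x[p])
      last <- p
    }
  }
  clips <- if (length(ev_peak)) {
    t(vapply(ev_peak, function(p) -x[(p - half):(p + half)], numeric(nclip)))
  } else matrix(numeric(0), 0, nclip)
  structure(list(channel = rep(as.integer(channel), length(ev_peak)),
                 peak_sample = as.integer(ev_peak),
                 peak_uv = ev_uv,
                 clips = clips,
                 clip_samples = nclip,
                 rate_hz = block$rate_hz),
            class = "spike_events")
}

#' @export
print.spike_events <- function(x, ...) {
  cat(sprintf("<spike_events> %d event(s), clips of %d samples @ %g Hz\n",
              length(x$peak_sample), x$clip_samples, x$rate_hz))
  if (length(x$peak_sample)) {
    print(utils::head(data.frame(channel = x$channel,
                                 peak_sample = x$peak_sample,
                                 peak_uv = x$peak_uv), 10), row.names = FALSE)
    if (length(x$peak_sample) > 10) cat("...\n")
  }
  invisible(x)
}

# concatenate spike_events objects (same clip geometry)
combine_events <- function(events_list) {
  events_list <- Filter(function(e) length(e$peak_sample) > 0, events_list)
  if (!length(events_list)) return(NULL)
  structure(list(
    channel = unlist(lapply(events_list, `[[`, "channel")),
    peak_sample = unlist(lapply(events_list, `[[`, "peak_sample")),
    peak_uv = unlist(lapply(events_list, `[[`, "peak_uv")),
    clips = do.call(rbind, lapply(events_list, `[[`, "clips")),
    clip_samples = events_list[[1]]$clip_samples,
    rate_hz = events_list[[1]]$rate_hz),
    class = "spike_events")
}

#' Average spike waveform
#'
#' Pointwise mean and SD across the (already peak-centered, inverted) clips
#' of a set of events.
#'
#' @param events A `spike_events` object with at least one event.
#' @return A list with `mean` and `sd` vectors of clip length, and `n`.
#' @export
average_waveform <- function(events) {
  stopifnot(inherits(events, "spike_events"))
  n <- nrow(events$clips)
  if (n < 1) stop("no events to average", call. = FALSE)
  m <- colMeans(events$clips)
  s <- if (n > 1) apply(events$clips, 2, stats::sd) else numeric(length(m)) * 0
  list(mean = m, sd = s, n = n)
}

#' Cross-channel footprint of a detected spike
#'
#' For each physical neighbor within `footprint_neighbors` steps of the
#' event's channel, extracts the clip window centered at the event's peak
#' sample and applies the same detection criterion (voltage threshold plus
#' peak z-score) restricted to that window. Neighbors where the criterion is
#' met contribute a clip and a peak amplitude; others are recorded absent.
#'
#' @param block The pre-processed `recording_block` the event came from.
#' @param event A single-event slice: list with `channel` and `peak_sample`
#'   (a `spike_events` object of length one works, as does picking index
#'   `i` via `footprint_event(events, i)`).
#' @param config A `detect_config`.
#' @return An object of class `spike_footprint`: `offsets` (signed physical
#'   steps), `detected` (logical), `peak_uv` (NA where absent) and `clips`
#'   (list of inverted clips or NULL).
#' @export
cross_channel_footprint <- function(block, event, config = detect_config()) {
  stopifnot(inherits(block, "recording_block"),
            inherits(config, "detect_config"))
  ch <- event$channel[1]
  peak <- event$peak_sample[1]
  nch <- ncol(block$data)
  nclip <- clip_length_samples(config$clip_ms, block$rate_hz)
  half <- (nclip - 1L) %/% 2L
  pos <- shank_positions(block)
  col_at_pos <- order(pos)
  my_pos <- pos[ch]
  k <- config$footprint_neighbors
  offsets <- setdiff(seq(-k, k), 0)
  offsets <- offsets[my_pos + offsets >= 1 & my_pos + offsets <= nch]
  detected <- logical(length(offsets))
  peak_uv <- rep(NA_real_, length(offsets))
  clips <- vector("list", length(offsets))
  lo <- max(1L, peak - half)
  hi <- min(nrow(block$data), peak + half)
  for (i in seq_along(offsets)) {
    nb_col <- col_at_pos[my_pos + offsets[i]]
    v <- block$data[, nb_col]
    w <- v[lo:hi]
    trough <- min(w)
    mu <- mean(v)
    s <- stats::sd(v)
    zok <- !(is.finite(s) && s > 0) ||
      abs(trough - mu) / s >= config$peak_z_min
    if (trough < config$threshold_uv && zok) {
      detected[i] <- TRUE
      peak_uv[i] <- trough
      clips[[i]] <- -w
    }
  }
  structure(list(channel = ch, peak_sample = peak, offsets = offsets,
                 detected = detected, peak_uv = peak_uv, clips = clips),
            class = "spike_footprint")
}

#' Extract one event from a `spike_events` set
#'
#' @param events A `spike_events` object.
#' @param i Event index.
#' @return A list with `channel`, `peak_sample`, `peak_uv` and `clip`.
#' @export
footprint_event <- function(events, i) {
  stopifnot(inherits(events, "spike_events"),
            i >= 1, i <= length(events$peak_sample))
  list(channel = events$channel[i], peak_sample = events$peak_sample[i],
       peak_uv = events$peak_uv[i], clip = events$clips[i, ])
}

#' @export
print.spike_footprint <- function(x, ...) {
  cat(sprintf("<spike_footprint> channel %d @ sample %d\n", x$channel,
              x$peak_sample))
  df <- data.frame(offset = x$offsets, detected = x$detected,
                   peak_uv = x$peak_uv)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Run the full pre-processing and detection chain
#'
#' Fixed canonical stage order: artifact masking, local common average
#' referencing, band-pass filtering, then per-channel threshold detection
#' and cross-channel footprints. Deterministic given the input block. The
#' audit log records the stage order, all stage parameters, the artifact
#' mask counts and per-channel event counts.
#'
#' @param block A raw `recording_block`.
#' @param chain A `chain_config`.
#' @param detect A `detect_config`.
#' @param footprints Compute per-event footprints (default TRUE; can be
#'   disabled for speed).
#' @return An object of class `chain_result`: `events` (per-channel list of
#'   `spike_events`), `footprints` (flat list of `spike_footprint`),
#'   `block` (the processed block) and `audit`.
#' @export
run_chain <- function(block, chain = chain_config(), detect = detect_config(),
                      footprints = TRUE) {
  stopifnot(inherits(block, "recording_block"),
            inherits(chain, "chain_config"),
            inherits(detect, "detect_config"))
  check_nyquist(block, chain)
  st1 <- remove_artifacts(block, chain$artifact_z, chain$artifact_guard_ms)
  st2 <- local_average_reference(st1$block, chain$car_neighbors,
                                 chain$car_mode)
  st3 <- bandpass_filter(st2, chain$bp_low_hz, chain$bp_high_hz,
                         chain$filter_order)
  events <- lapply(seq_len(ncol(st3$data)), function(ch)
    detect_spikes(st3, ch, detect))
  fps <- list()
  if (footprints) {
    for (ev in events) {
      for (i in seq_along(ev$peak_sample)) {
        fps[[length(fps) + 1L]] <-
          cross_channel_footprint(st3, footprint_event(ev, i), detect)
      }
    }
  }
  audit <- list(
    stage_order = c("artifacts", "local_average_reference", "bandpass",
                    "detect"),
    chain_config = unclass(chain),
    detect_config = unclass(detect),
    artifact_samples_masked = colSums(st1$mask),
    n_events_per_channel = vapply(events, function(e)
      length(e$peak_sample), integer(1)))
  structure(list(events = events, footprints = fps, block = st3,
                 artifact_mask = st1$mask, audit = audit),
            class = "chain_result")
}

#' @export
print.chain_result <- function(x, ...) {
  cat(sprintf("<chain_result> %d channel(s), %d event(s), %d footprint(s)\n",
              length(x$events), sum(x$audit$n_events_per_channel),
              length(x$footprints)))
  invisible(x)
}
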
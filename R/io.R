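# Recording file format: flat little-endian signed-16-bit binary,
# sample-major (all channels of sample 1, then sample 2, ...), with a JSON
# sidecar (<base>.json) carrying rate_hz, n_channels, scale_uv_per_bit and
# channel_order. This is the common raw-ephys dump dialect.

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Write a recording block to disk
#'
#' Quantizes to int16 using the block's uV-per-bit scale and writes the flat
#' binary plus its JSON sidecar. Reading back reproduces the block exactly
#' when its data already sit on the quantization grid (as the synthetic
#' generator guarantees).
#'
#' @param block A `recording_block`.
#' @param path Path of the binary file; the sidecar is written next to it
#'   with a `.json` extension.
#' @return `path`, invisibly.
#' @export
write_recording <- function(block, path) {
  stopifnot(inherits(block, "recording_block"))
  q <- round(block$data / block$scale_uv_per_bit)
  if (any(q < -32768 | q > 32767)) {
    stop("data exceed the int16 range at this uV-per-bit scale", call. = FALSE)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(t(q)), con, size = 2L, endian = "little")
  meta <- list(rate_hz = block$rate_hz,
               n_channels = ncol(block$data),
               n_samples = nrow(block$data),
               scale_uv_per_bit = block$scale_uv_per_bit,
               channel_order = block$channel_order)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording block from disk
#'
#' Validates the sidecar against the binary size (`samples * channels * 2`
#' bytes) and converts to uV on read.
#'
#' @param path Path of the binary file written by [write_recording()].
#' @return A `recording_block`.
#' @export
read_recording <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(path)) stop("recording file not found: ", path,
                               call. = FALSE)
  if (!file.exists(sc)) stop("sidecar metadata not found: ", sc,
                             call. = FALSE)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  need <- c("rate_hz", "n_channels", "scale_uv_per_bit", "channel_order")
  if (!all(need %in% names(meta))) {
    stop("sidecar is missing fields: ",
         paste(setdiff(need, names(meta)), collapse = ", "), call. = FALSE)
  }
  nch <- as.integer(meta$n_channels)
  sz <- file.info(path)$size
  if (sz %% (2L * nch) != 0) {
    stop(sprintf(
      "file size %d bytes is not a whole number of %d-channel int16 frames",
      sz, nch), call. = FALSE)
  }
  nsamp <- as.integer(sz / (2L * nch))
  if (!is.null(meta$n_samples) && as.integer(meta$n_samples) != nsamp) {
    stop(sprintf(
      "sidecar declares %d samples but the file holds %d (size %d bytes)",
      as.integer(meta$n_samples), nsamp, sz), call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  q <- readBin(con, "integer", n = nsamp * nch, size = 2L, signed = TRUE,
               endian = "little")
  data <- t(matrix(as.numeric(q), nrow = nch)) * meta$scale_uv_per_bit
  recording_block(data, meta$rate_hz,
                  channel_order = as.integer(meta$channel_order),
                  scale_uv_per_bit = meta$scale_uv_per_bit)
}

#' Write detected events (and clips) to disk
#'
#' Events go to a CSV (`channel`, `peak_sample`, `peak_uv`); the inverted
#' clips go to a sibling flat float store (little-endian float64, one row
#' per event) described by a small JSON sidecar.
#'
#' @param events A `spike_events` object.
#' @param path CSV path; the clip store uses the same base name with
#'   `_clips.bin` / `_clips.json`.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  stopifnot(inherits(events, "spike_events"))
  df <- data.frame(channel = events$channel, peak_sample = events$peak_sample,
                   peak_uv = events$peak_uv)
  utils::write.csv(df, path, row.names = FALSE)
  base <- tools::file_path_sans_ext(path)
  con <- file(paste0(base, "_clips.bin"), "wb")
  writeBin(as.numeric(t(events$clips)), con, size = 8L, endian = "little")
  close(con)
  jsonlite::write_json(list(n_events = nrow(events$clips),
                            clip_samples = events$clip_samples,
                            rate_hz = events$rate_hz),
                       paste0(base, "_clips.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a ground-truth spike log to CSV
#'
#' @param truth Ground-truth data frame from [simulate_recording()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Minimal TOML-subset config reader: [section] headers, `key = value` pairs,
# scalars (number, "string", true/false) and flat arrays. Unknown keys are
# errors so that typos cannot silently change calibration constants.

parse_toml_value <- function(v) {
  v <- trimws(v)
  if (grepl("^\\[.*\\]$", v)) {
    inner <- trimws(sub("^\\[", "", sub("\\]$", "", v)))
    if (inner == "") return(list())
    parts <- strsplit(inner, ",")[[1]]
    return(unlist(lapply(parts, parse_toml_value)))
  }
  if (grepl('^".*"$', v)) return(gsub('^"|"$', "", v))
  if (v %in% c("true", "false")) return(v == "true")
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) return(num)
  stop("cannot parse config value: ", v, call. = FALSE)
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[[A-Za-z0-9_]+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(cfg[[section]])) cfg[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", ln))
      val <- parse_toml_value(sub("^[^=]*=", "", ln))
      if (is.null(section)) {
        cfg[[key]] <- val
      } else {
        cfg[[section]][[key]] <- val
      }
    } else {
      stop("cannot parse config line: ", ln, call. = FALSE)
    }
  }
  cfg
}

config_schema <- list(
  screw = c("pitch_mm"),
  train = c("sun_teeth", "ring_teeth", "planet_teeth"),
  ledger = c("dv0_mm", "skull_thickness_mm", "base_wall_mm", "max_draw_mm"),
  chain = c("artifact_z", "car_neighbors", "bp_low_hz", "bp_high_hz",
            "filter_order", "artifact_guard_ms", "car_mode"),
  detect = c("threshold_uv", "peak_z_min", "clip_ms", "footprint_neighbors",
             "lockout_samples"),
  simulate = c("n_channels", "duration_s", "rate_hz", "noise_sd_uv",
               "scale_uv_per_bit", "n_spikes", "trough_uv", "decay",
               "line_freq_hz", "line_amplitude_uv"),
  gaintest = c("true_amplitude_uv", "n_pulses", "pulse_width_us",
               "pulse_spacing_ms", "nominal_gain", "actual_gain",
               "noise_sd_uv", "rate_hz"))

#' Read and validate a run configuration
#'
#' Reads a TOML-style config file with sections `[screw]`, `[train]`,
#' `[ledger]`, `[chain]`, `[detect]`, `[simulate]` and `[gaintest]` (all
#' optional; defaults fill the rest). Unknown sections or keys are errors.
#'
#' @param path Config file path.
#' @return A named list of validated section lists, with a `drive` element
#'   holding the assembled `drive_config`.
#' @export
read_run_config <- function(path) {
  cfg <- read_config_file(path)
  for (sec in names(cfg)) {
    if (!sec %in% names(config_schema)) {
      stop("unknown config section: [", sec, "]", call. = FALSE)
    }
    bad <- setdiff(names(cfg[[sec]]), config_schema[[sec]])
    if (length(bad)) {
      stop("unknown key(s) in [", sec, "]: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  pitch <- cfg$screw$pitch_mm %||% 0.3
  screw <- screw_spec(pitch)
  train <- if (!is.null(cfg$train$sun_teeth)) {
    suns <- as.integer(cfg$train$sun_teeth)
    rings <- as.integer(cfg$train$ring_teeth)
    if (length(suns) != length(rings)) {
      stop("[train] sun_teeth and ring_teeth must have the same length",
           call. = FALSE)
    }
    gear_train(mapply(gear_stage, suns, rings, SIMPLIFY = FALSE))
  } else {
    gear_train(gear_stage(8, 32), gear_stage(8, 32))
  }
  cfg$drive <- drive_config(screw, train)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
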
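#' Implant geometry at the skull
#'
#' The two thicknesses between the implant's reference surface and the brain:
#' measured skull thickness `A` (calipers on the trephined bone) and the
#' implant's bottom-wall thickness `B` (0.5 mm in the stock print).
#'
#' @param skull_thickness_mm Skull thickness A in mm, >= 0.
#' @param base_wall_mm Implant bottom-wall thickness B in mm, >= 0
#'   (default 0.5).
#' @return An object of class `implant_geometry`.
#' @export
implant_geometry <- function(skull_thickness_mm, base_wall_mm = 0.5) {
  if (!is.numeric(skull_thickness_mm) || length(skull_thickness_mm) != 1L ||
      !is.finite(skull_thickness_mm) || skull_thickness_mm < 0) {
    stop("`skull_thickness_mm` must be a single non-negative number",
         call. = FALSE)
  }
  if (!is.numeric(base_wall_mm) || length(base_wall_mm) != 1L ||
      !is.finite(base_wall_mm) || base_wall_mm < 0) {
    stop("`base_wall_mm` must be a single non-negative number", call. = FALSE)
  }
  structure(list(skull_thickness_mm = as.numeric(skull_thickness_mm),
                 base_wall_mm = as.numeric(base_wall_mm)),
            class = "implant_geometry")
}

#' Initial draw length of the probe shank
#'
#' How far the shank must be drawn out of the implant before lowering, to
#' land the tip at the target initial depth: `L0 = |DV0| + A + B`. The draw
#' is refused when it exceeds the usable shank length (10 mm shank minus the
#' 0.5 mm bottom wall by default).
#'
#' @param dv0_mm Target initial implantation depth DV0 in mm (negative is
#'   deeper; the absolute value is used).
#' @param geometry An `implant_geometry`.
#' @param max_draw_mm Usable shank length in mm (default 9.5).
#' @return Draw length L0 in mm.
#' @examples
#' initial_draw_length(-1.4, implant_geometry(0.7))  # 2.6 mm
#' @export
initial_draw_length <- function(dv0_mm, geometry, max_draw_mm = 9.5) {
  stopifnot(inherits(geometry, "implant_geometry"),
            is.numeric(dv0_mm), length(dv0_mm) == 1L, is.finite(dv0_mm))
  l0 <- abs(dv0_mm) + geometry$skull_thickness_mm + geometry$base_wall_mm
  if (l0 > max_draw_mm) {
    stop(sprintf(
      "draw length %.3f mm exceeds the usable shank length of %.3f mm (10 mm shank minus bottom wall); choose a shallower target",
      l0, max_draw_mm), call. = FALSE)
  }
  l0
}

#' Direct screw turns to draw the shank
#'
#' Convenience wrapper: the number of direct drive-screw turns that produce
#' the draw length `L0`, i.e. [turns_for_distance()] applied to `L0`.
#'
#' @param l0_mm Draw length in mm.
#' @param screw A `screw_spec`.
#' @return Turns of the drive screw.
#' @examples
#' draw_turns(2.6, screw_spec(0.3))  # 8.67 turns
#' @export
draw_turns <- function(l0_mm, screw) {
  turns_for_distance(screw, l0_mm)
}

#' Probe-depth ledger
#'
#' Append-only record of the probe tip's dorsoventral (DV) position: the
#' initial implantation depth plus every signed post-surgical
#' micro-adjustment. Depths are negative below the brain surface and
#' adjustments into tissue are negative. The current depth is always
#' recomputable from the full record list.
#'
#' @param dv0_mm Initial implantation depth DV0 in mm (<= 0 by convention).
#' @param geometry An `implant_geometry`.
#' @param drive A `drive_config` used to convert between turns and distance.
#' @param max_draw_mm Usable shank length guard in mm (default 9.5).
#' @return An object of class `depth_ledger`.
#' @examples
#' led <- depth_ledger(-1.4, implant_geometry(0.7), kepler_drive_config())
#' led <- record_adjustment(led, turns = 5)   # 5 input turns = -0.06 mm
#' current_depth(led)
#' @export
depth_ledger <- function(dv0_mm, geometry, drive = kepler_drive_config(),
                         max_draw_mm = 9.5) {
  stopifnot(is.numeric(dv0_mm), length(dv0_mm) == 1L, is.finite(dv0_mm),
            inherits(geometry, "implant_geometry"),
            inherits(drive, "drive_config"))
  led <- structure(list(
    dv0_mm = as.numeric(dv0_mm),
    geometry = geometry,
    drive = drive,
    max_draw_mm = max_draw_mm,
    adjustments = data.frame(
      index = integer(0), mode = character(0), turns = numeric(0),
      distance_mm = numeric(0), cumulative_dv_mm = numeric(0),
      note = character(0), stringsAsFactors = FALSE)),
    class = "depth_ledger")
  check_depth_limit(led, dv0_mm)
  led
}

check_depth_limit <- function(ledger, dv_mm) {
  reach <- abs(dv_mm) + ledger$geometry$skull_thickness_mm +
    ledger$geometry$base_wall_mm
  if (reach > ledger$max_draw_mm + 1e-12) {
    stop(sprintf(
      "depth %.3f mm requires %.3f mm of shank but only %.3f mm is usable",
      dv_mm, reach, ledger$max_draw_mm), call. = FALSE)
  }
  invisible(TRUE)
}

#' Current probe-tip depth
#'
#' The tip depth is the initial implantation depth plus the sum of all
#' recorded micro-adjustment distances: `DV = DV0 + sum(D_i)`.
#'
#' @param ledger A `depth_ledger`.
#' @return Current DV in mm.
#' @export
current_depth <- function(ledger) {
  stopifnot(inherits(ledger, "depth_ledger"))
  ledger$dv0_mm + sum(ledger$adjustments$distance_mm)
}

#' Record a micro-adjustment
#'
#' Appends one adjustment to the ledger. Give exactly one of `distance_mm`
#' (signed; negative = deeper) or `turns` (positive = counterclockwise =
#' deeper); the other is derived through the ledger's drive configuration.
#' `mode` selects whether `turns` are counted at the screwdriver input
#' (`"kepler"`, the default, 0.012 mm per turn with the stock kit) or
#' directly at the drive screw (`"screw"`, one pitch per turn).
#'
#' @param ledger A `depth_ledger`.
#' @param distance_mm Signed displacement in mm, or `NULL`.
#' @param turns Turns applied, or `NULL`.
#' @param mode `"kepler"` or `"screw"`.
#' @param note Optional free-text note (e.g. a date).
#' @return The updated ledger (prior records untouched).
#' @export
record_adjustment <- function(ledger, distance_mm = NULL, turns = NULL,
                              mode = c("kepler", "screw"), note = "") {
  stopifnot(inherits(ledger, "depth_ledger"))
  mode <- match.arg(mode)
  if (is.null(distance_mm) == is.null(turns)) {
    stop("give exactly one of `distance_mm` or `turns`", call. = FALSE)
  }
  step <- switch(mode,
                 kepler = ledger$drive$min_step_mm,
                 screw = ledger$drive$screw$pitch_mm)
  if (is.null(distance_mm)) {
    stopifnot(is.numeric(turns), length(turns) == 1L, is.finite(turns))
    # positive (ccw) turns extend the probe -> deeper -> negative DV change
    distance_mm <- -turns * step
  } else {
    stopifnot(is.numeric(distance_mm), length(distance_mm) == 1L,
              is.finite(distance_mm))
    turns <- -distance_mm / step
  }
  new_dv <- current_depth(ledger) + distance_mm
  check_depth_limit(ledger, new_dv)
  rec <- data.frame(index = nrow(ledger$adjustments) + 1L, mode = mode,
                    turns = turns, distance_mm = distance_mm,
                    cumulative_dv_mm = new_dv, note = note,
                    stringsAsFactors = FALSE)
  ledger$adjustments <- rbind(ledger$adjustments, rec)
  ledger
}

#' Plan the turns for a target depth
#'
#' Quantizes the distance from the current tip depth to `target_dv_mm` into
#' whole screwdriver input turns (the unit the counter disk displays), or
#' quarter turns via `resolution = "quarter"` (the counter knob marks
#' 0.25/0.5/0.75). Rounds to the nearest representable turn count with ties
#' toward fewer turns, so the residual never exceeds half a step.
#'
#' @param ledger A `depth_ledger`.
#' @param target_dv_mm Target DV in mm.
#' @param resolution `"whole"` (default) or `"quarter"` turns.
#' @return A list with `turns` (signed; positive = ccw/deeper), `achieved_dv_mm`
#'   and `residual_mm` (target minus achieved).
#' @examples
#' led <- depth_ledger(-2.68, implant_geometry(0.7), kepler_drive_config())
#' plan_adjustment(led, -2.74)  # 5 input turns, residual 0
#' @export
plan_adjustment <- function(ledger, target_dv_mm,
                            resolution = c("whole", "quarter")) {
  stopifnot(inherits(ledger, "depth_ledger"),
            is.numeric(target_dv_mm), length(target_dv_mm) == 1L,
            is.finite(target_dv_mm))
  resolution <- match.arg(resolution)
  check_depth_limit(ledger, target_dv_mm)
  step <- ledger$drive$min_step_mm
  if (resolution == "quarter") step <- step / 4
  need_mm <- target_dv_mm - current_depth(ledger)  # negative = descend
  t_exact <- -need_mm / step                       # positive = ccw turns
  t_quant <- round_half_to_zero(t_exact)
  if (resolution == "quarter") t_quant <- t_quant / 4
  turns_units <- if (resolution == "quarter") t_quant * 4 else t_quant
  achieved <- current_depth(ledger) - turns_units * step
  list(turns = t_quant,
       achieved_dv_mm = achieved,
       residual_mm = target_dv_mm - achieved)
}

# round to nearest integer, exact .5 ties toward zero (fewer turns);
# a tolerance absorbs floating-point representation of the step size
round_half_to_zero <- function(x, tol = 1e-9) {
  frac <- x - trunc(x)
  ifelse(abs(abs(frac) - 0.5) <= tol, trunc(x), round(x))
}

#' Depth of an electrode row on the shank
#'
#' Electrode rows sit above the tip at a fixed pitch; row `i` is at
#' `DV_tip + tip_offset + i * row_pitch` (rows are shallower than the tip,
#' so the offset and pitch add toward zero).
#'
#' @param ledger A `depth_ledger`.
#' @param row_index Row index, 0 = the row closest to the tip.
#' @param row_pitch_mm Vertical spacing between rows in mm.
#' @param tip_offset_mm Distance from the physical tip to row 0 in mm.
#' @return DV of the row in mm (vectorised over `row_index`).
#' @export
electrode_row_depth <- function(ledger, row_index, row_pitch_mm,
                                tip_offset_mm = 0) {
  stopifnot(inherits(ledger, "depth_ledger"),
            is.numeric(row_index), all(row_index >= 0),
            is.numeric(row_pitch_mm), row_pitch_mm >= 0,
            is.numeric(tip_offset_mm), tip_offset_mm >= 0)
  current_depth(ledger) + tip_offset_mm + row_index * row_pitch_mm
}

#' Calibration error from the reference-mark procedure
#'
#' After assembly the implant is calibrated against a block with a 3 mm
#' reference mark: the screw is turned counterclockwise a reference number
#' of times (10 turns = 3 mm at 0.3 mm pitch), then further until the tip
#' aligns with the mark, counting all turns. The surplus over the reference
#' are the error turns `ET = counted - reference`; the error distance is
#' `ED = pitch * ET`. Applying `ET` turns after full retraction pre-offsets
#' the print tolerance so subsequent 10-turn strokes land on the mark.
#'
#' @param counted_turns Total counterclockwise turns until mark alignment.
#' @param reference_turns Reference turn count (default 10).
#' @param screw A `screw_spec`.
#' @return An object of class `calibration_result` with `reference_turns`,
#'   `counted_turns`, `error_turns` and `error_distance_mm`.
#' @examples
#' calibration_error(12, 10, screw_spec(0.3))  # ET 2, ED 0.6 mm
#' @export
calibration_error <- function(counted_turns, reference_turns = 10,
                              screw = screw_spec()) {
  stopifnot(is.numeric(counted_turns), length(counted_turns) == 1L,
            is.numeric(reference_turns), length(reference_turns) == 1L,
            reference_turns >= 0, inherits(screw, "screw_spec"))
  if (counted_turns < reference_turns) {
    stop("counted turns fall short of the reference count: the mark was overshot before the reference stroke completed; re-run the calibration",
         call. = FALSE)
  }
  et <- counted_turns - reference_turns
  structure(list(reference_turns = reference_turns,
                 counted_turns = counted_turns,
                 error_turns = et,
                 error_distance_mm = distance_from_turns(screw, et)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration_result> ET = %.4g turns (ED = %.4g mm); apply %.4g ccw turns after full retraction\n",
    x$error_turns, x$error_distance_mm, x$error_turns))
  invisible(x)
}

#' @export
print.depth_ledger <- function(x, ...) {
  cat(sprintf("<depth_ledger> DV0 %.4g mm, %d adjustment(s), current DV %.6g mm\n",
              x$dv0_mm, nrow(x$adjustments), current_depth(x)))
  if (nrow(x$adjustments) > 0) {
    print(x$adjustments, row.names = FALSE)
  }
  invisible(x)
}

#' Write / read a depth ledger as CSV
#'
#' The ledger is persisted as a plain CSV with a commented header carrying
#' the scalar state (DV0, geometry, drive parameters) followed by one row
#' per adjustment (index, mode, turns, distance_mm, cumulative_dv_mm, note).
#' Numbers are stored at full double precision so a write/read round trip is
#' bit-identical.
#'
#' @param ledger A `depth_ledger`.
#' @param path File path.
#' @return `write_ledger_csv()` returns `path` invisibly; `read_ledger_csv()`
#'   returns a `depth_ledger`.
#' @export
write_ledger_csv <- function(ledger, path) {
  stopifnot(inherits(ledger, "depth_ledger"))
  num <- function(x) sprintf("%.17g", x)
  tr <- ledger$drive$train
  suns <- vapply(tr$stages, function(s) s$sun_teeth, integer(1))
  rings <- vapply(tr$stages, function(s) s$ring_teeth, integer(1))
  hdr <- c(
    paste0("# dv0_mm=", num(ledger$dv0_mm)),
    paste0("# skull_thickness_mm=", num(ledger$geometry$skull_thickness_mm)),
    paste0("# base_wall_mm=", num(ledger$geometry$base_wall_mm)),
    paste0("# max_draw_mm=", num(ledger$max_draw_mm)),
    paste0("# pitch_mm=", num(ledger$drive$screw$pitch_mm)),
    paste0("# sun_teeth=", paste(suns, collapse = ";")),
    paste0("# ring_teeth=", paste(rings, collapse = ";")))
  adj <- ledger$adjustments
  rows <- sprintf("%d,%s,%s,%s,%s,%s",
                  adj$index, adj$mode, num(adj$turns), num(adj$distance_mm),
                  num(adj$cumulative_dv_mm), csv_quote(adj$note))
  writeLines(c(hdr,
               "index,mode,turns,distance_mm,cumulative_dv_mm,note",
               rows), path)
  invisible(path)
}

csv_quote <- function(x) {
  needs <- grepl('[",]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

#' @rdname write_ledger_csv
#' @export
read_ledger_csv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  kv <- sub("^# ", "", hdr)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  names(vals) <- keys
  need <- c("dv0_mm", "skull_thickness_mm", "base_wall_mm", "max_draw_mm",
            "pitch_mm", "sun_teeth", "ring_teeth")
  if (!all(need %in% keys)) {
    stop("ledger file is missing header fields: ",
         paste(setdiff(need, keys), collapse = ", "), call. = FALSE)
  }
  suns <- as.integer(strsplit(vals[["sun_teeth"]], ";")[[1]])
  rings <- as.integer(strsplit(vals[["ring_teeth"]], ";")[[1]])
  suns <- suns[!is.na(suns)]
  rings <- rings[!is.na(rings)]
  stages <- mapply(gear_stage, suns, rings, SIMPLIFY = FALSE)
  led <- depth_ledger(
    dv0_mm = as.numeric(vals[["dv0_mm"]]),
    geometry = implant_geometry(as.numeric(vals[["skull_thickness_mm"]]),
                                as.numeric(vals[["base_wall_mm"]])),
    drive = drive_config(screw_spec(as.numeric(vals[["pitch_mm"]])),
                         gear_train(stages)),
    max_draw_mm = as.numeric(vals[["max_draw_mm"]]))
  body <- lines[!startsWith(lines, "# ")]
  adj <- utils::read.csv(text = paste(body, collapse = "\n"),
                         colClasses = c(index = "integer", mode = "character",
                                        turns = "numeric",
                                        distance_mm = "numeric",
                                        cumulative_dv_mm = "numeric",
                                        note = "character"))
  led$adjustments <- adj
  led
}
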
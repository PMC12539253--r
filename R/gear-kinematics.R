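#' Drive screw specification
#'
#' A fine-pitch drive screw translates rotation into linear travel of the
#' probe shuttle: one full rotation moves the shuttle by one thread pitch.
#' The implant kit uses an M1.4 screw with a 0.3 mm pitch; pitches at or
#' below 0.5 mm are recommended to avoid thread skipping.
#'
#' @param pitch_mm Linear travel per full screw rotation, in mm/turn.
#'   Must be positive.
#' @return An object of class `screw_spec`.
#' @examples
#' screw_spec(0.3)
#' @export
screw_spec <- function(pitch_mm = 0.3) {
  if (!is.numeric(pitch_mm) || length(pitch_mm) != 1L || !is.finite(pitch_mm) ||
      pitch_mm <= 0) {
    stop("`pitch_mm` must be a single positive finite number", call. = FALSE)
  }
  structure(list(pitch_mm = as.numeric(pitch_mm)), class = "screw_spec")
}

#' @export
print.screw_spec <- function(x, ...) {
  cat(sprintf("<screw_spec> pitch %.4g mm/turn\n", x$pitch_mm))
  invisible(x)
}

#' Planetary gear stage
#'
#' One planetary stage: input at the sun gear, output at the planet carrier,
#' ring gear fixed. Its turn ratio (output turns per input turn) is
#' `S / (R + S)` where `S` and `R` are sun and ring tooth counts. Planet
#' tooth counts do not enter the ratio; when supplied they are only checked
#' for geometric consistency (`R = S + 2 * planets`), and a violation is a
#' warning rather than an error.
#'
#' @param sun_teeth Integer tooth count of the sun gear (input), >= 1.
#' @param ring_teeth Integer tooth count of the fixed ring gear, >= 1.
#' @param planet_teeth Optional integer tooth count of each planet gear;
#'   informational.
#' @return An object of class `gear_stage`.
#' @examples
#' gear_stage(8, 32)        # the screwdriver's 5:1 stage
#' gear_stage(5, 45, 20)    # the 10:1 turn-counter stage
#' @export
gear_stage <- function(sun_teeth, ring_teeth, planet_teeth = NULL) {
  check_teeth <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 ||
        x != round(x)) {
      stop(sprintf("`%s` must be a single positive integer", what),
           call. = FALSE)
    }
    as.integer(x)
  }
  sun_teeth <- check_teeth(sun_teeth, "sun_teeth")
  ring_teeth <- check_teeth(ring_teeth, "ring_teeth")
  if (!is.null(planet_teeth)) {
    planet_teeth <- check_teeth(planet_teeth, "planet_teeth")
    if (ring_teeth != sun_teeth + 2L * planet_teeth) {
      warning(sprintf(
        "tooth counts are geometrically inconsistent: ring (%d) != sun (%d) + 2 * planets (%d)",
        ring_teeth, sun_teeth, planet_teeth), call. = FALSE)
    }
  }
  structure(list(sun_teeth = sun_teeth, ring_teeth = ring_teeth,
                 planet_teeth = planet_teeth),
            class = "gear_stage")
}

#' @export
print.gear_stage <- function(x, ...) {
  r <- stage_turn_ratio(x)
  cat(sprintf("<gear_stage> sun %d / ring %d teeth -> turn ratio %s (%d:1)\n",
              x$sun_teeth, x$ring_teeth, format(r),
              as.integer(r$den / r$num)))
  invisible(x)
}

#' Exact turn ratio
#'
#' Turn ratios (output turns per input turn) are kept as exact integer
#' fractions so that cascaded stages and cumulative depth arithmetic do not
#' accumulate floating-point drift; conversion to a real number happens only
#' at the distance boundary.
#'
#' @param num,den Integer numerator and denominator; `den` > 0.
#' @return An object of class `turn_ratio` with fields `num` and `den`
#'   (coprime, `den` > 0).
#' @examples
#' as.double(turn_ratio(8, 40))  # reduced to 1/5
#' @export
turn_ratio <- function(num, den) {
  if (den == 0) stop("turn ratio denominator must be non-zero", call. = FALSE)
  num <- as.numeric(num)
  den <- as.numeric(den)
  if (num != round(num) || den != round(den)) {
    stop("turn ratio components must be integers", call. = FALSE)
  }
  if (den < 0) {
    num <- -num
    den <- -den
  }
  g <- gcd_int(abs(num), den)
  if (g > 0) {
    num <- num / g
    den <- den / g
  }
  structure(list(num = num, den = den), class = "turn_ratio")
}

gcd_int <- function(a, b) {
  while (b != 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

#' @export
as.double.turn_ratio <- function(x, ...) x$num / x$den

ratio_value <- function(x) x$num / x$den

#' @export
format.turn_ratio <- function(x, ...) {
  if (x$den == 1) sprintf("%g", x$num) else sprintf("%g/%g", x$num, x$den)
}

#' @export
print.turn_ratio <- function(x, ...) {
  cat(sprintf("<turn_ratio> %s (= %.10g)\n", format(x), as.numeric(x)))
  invisible(x)
}

#' Gear train
#'
#' An ordered cascade of planetary stages; the output of each stage feeds
#' the input of the next, so the overall turn ratio is the product of the
#' per-stage ratios. An empty train is a direct drive (ratio exactly 1).
#'
#' @param ... `gear_stage` objects (or a single list of them), in input to
#'   output order.
#' @return An object of class `gear_train`.
#' @examples
#' gear_train(gear_stage(8, 32), gear_stage(8, 32))  # 25:1 screwdriver
#' gear_train()                                      # direct drive
#' @export
gear_train <- function(...) {
  stages <- list(...)
  if (length(stages) == 1L && is.list(stages[[1L]]) &&
      !inherits(stages[[1L]], "gear_stage")) {
    stages <- stages[[1L]]
  }
  ok <- vapply(stages, inherits, logical(1), what = "gear_stage")
  if (!all(ok)) stop("all train stages must be `gear_stage` objects",
                     call. = FALSE)
  structure(list(stages = stages), class = "gear_train")
}

#' @export
print.gear_train <- function(x, ...) {
  r <- train_turn_ratio(x)
  cat(sprintf("<gear_train> %d stage(s), turn ratio %s\n",
              length(x$stages), format(r)))
  invisible(x)
}

#' Turn ratio of one planetary stage
#'
#' With input on the sun, output on the carrier and the ring fixed, one
#' input turn yields `S / (R + S)` output turns. The screwdriver's stages
#' (sun 8, ring 32) give 1/5; the counter stage (sun 5, ring 45) gives 1/10.
#'
#' @param stage A `gear_stage`.
#' @return A `turn_ratio`, strictly between 0 and 1.
#' @examples
#' stage_turn_ratio(gear_stage(8, 32))  # 1/5
#' @export
stage_turn_ratio <- function(stage) {
  stopifnot(inherits(stage, "gear_stage"))
  turn_ratio(stage$sun_teeth, stage$ring_teeth + stage$sun_teeth)
}

#' Turn ratio of a cascaded gear train
#'
#' Cascading stages multiplies their turn ratios: two 1/5 stages give 1/25,
#' i.e. 25 input turns per output turn. The empty train has ratio exactly 1.
#'
#' @param train A `gear_train`.
#' @return A `turn_ratio`.
#' @examples
#' train_turn_ratio(gear_train(gear_stage(8, 32), gear_stage(8, 32)))
#' @export
train_turn_ratio <- function(train) {
  stopifnot(inherits(train, "gear_train"))
  num <- 1
  den <- 1
  for (st in train$stages) {
    r <- stage_turn_ratio(st)
    num <- num * r$num
    den <- den * r$den
  }
  turn_ratio(num, den)
}

#' Drive configuration: screw plus screwdriver gear train
#'
#' Combines a drive screw with the gear train of the screwdriver turning it.
#' The minimum step (mm per whole input turn) is pitch times the train's
#' turn ratio: 0.012 mm for the default 0.3 mm pitch and 25:1 train.
#' Sign convention: positive turns are counterclockwise at the drive screw
#' and extend the probe (probe tip descends).
#'
#' @param screw A `screw_spec`.
#' @param train A `gear_train`; defaults to direct drive.
#' @return An object of class `drive_config` with a precomputed
#'   `min_step_mm`.
#' @examples
#' kepler_drive_config()
#' @export
drive_config <- function(screw = screw_spec(), train = gear_train()) {
  stopifnot(inherits(screw, "screw_spec"), inherits(train, "gear_train"))
  ratio <- train_turn_ratio(train)
  min_step <- screw$pitch_mm * ratio_value(ratio)
  if (min_step <= 0) stop("drive configuration has a non-positive step",
                          call. = FALSE)
  structure(list(screw = screw, train = train, ratio = ratio,
                 min_step_mm = min_step),
            class = "drive_config")
}

#' @rdname drive_config
#' @param pitch_mm Drive screw pitch for the kit default (0.3 mm).
#' @details `kepler_drive_config()` builds the kit's default: a 0.3 mm pitch
#'   screw driven through the two-stage 25:1 planetary screwdriver
#'   (sun 8 / ring 32 teeth per stage, planets 12).
#' @export
kepler_drive_config <- function(pitch_mm = 0.3) {
  drive_config(screw_spec(pitch_mm),
               gear_train(gear_stage(8, 32, 12), gear_stage(8, 32, 12)))
}

#' @export
print.drive_config <- function(x, ...) {
  cat(sprintf(
    "<drive_config> pitch %.4g mm, train ratio %s, step %.6g mm per input turn\n",
    x$screw$pitch_mm, format(x$ratio), x$min_step_mm))
  invisible(x)
}

#' Shuttle travel from direct drive-screw turns
#'
#' Linear shuttle displacement is pitch times turns: `D = P * T`. Positive
#' (counterclockwise) turns extend the probe.
#'
#' @param screw A `screw_spec`.
#' @param turns Signed number of direct screw turns (vectorised).
#' @return Displacement in mm, same sign as `turns`.
#' @examples
#' distance_from_turns(screw_spec(0.3), 0.2)  # 0.06 mm
#' distance_from_turns(screw_spec(0.3), 10)   # 3 mm (calibration stroke)
#' @export
distance_from_turns <- function(screw, turns) {
  stopifnot(inherits(screw, "screw_spec"), is.numeric(turns))
  screw$pitch_mm * turns
}

#' Direct screw turns for a target travel
#'
#' Inverse of [distance_from_turns()]: `T = D / P`.
#'
#' @param screw A `screw_spec`.
#' @param distance_mm Signed displacement in mm (vectorised).
#' @return Turns of the drive screw.
#' @examples
#' turns_for_distance(screw_spec(0.3), 0.06)  # 0.2 turns
#' turns_for_distance(screw_spec(0.3), 2.6)   # 8.67 turns (draw length)
#' @export
turns_for_distance <- function(screw, distance_mm) {
  stopifnot(inherits(screw, "screw_spec"), is.numeric(distance_mm))
  distance_mm / screw$pitch_mm
}

#' Shuttle travel from screwdriver input turns
#'
#' Through the gear train, `D = P * T_in * ratio`. With the 25:1 train and
#' a 0.3 mm pitch screw, one input turn moves the shuttle 0.012 mm.
#'
#' @param config A `drive_config`.
#' @param input_turns Signed turns at the screwdriver input (vectorised).
#' @return Displacement in mm.
#' @examples
#' distance_from_input_turns(kepler_drive_config(), 5)  # 0.06 mm
#' @export
distance_from_input_turns <- function(config, input_turns) {
  stopifnot(inherits(config, "drive_config"), is.numeric(input_turns))
  config$min_step_mm * input_turns
}

#' Screwdriver input turns for a target travel
#'
#' Inverse of [distance_from_input_turns()]: `T_in = D / (P * ratio)`.
#'
#' @param config A `drive_config`.
#' @param distance_mm Signed displacement in mm (vectorised).
#' @return Turns at the screwdriver input.
#' @examples
#' input_turns_for_distance(kepler_drive_config(), 0.06)  # 5 turns
#' @export
input_turns_for_distance <- function(config, distance_mm) {
  stopifnot(inherits(config, "drive_config"), is.numeric(distance_mm))
  distance_mm / config$min_step_mm
}
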
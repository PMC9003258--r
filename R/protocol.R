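#' Staged LBNP protocol schedule
#'
#' The standard hemorrhage-tolerance protocol: a resting baseline followed by
#' progressively stronger lower-body negative pressure (LBNP) stages, each held
#' for a fixed duration until the subject decompensates.  LBNP levels are
#' stored as positive suction magnitudes in mmHg; the conventional negative
#' sign is presentation only.
#'
#' @param baseline_duration Baseline rest before the first stage, seconds.
#' @param stage_levels Ordered LBNP magnitudes (mmHg), strictly increasing.
#' @param stage_duration Duration of each stage, seconds.
#' @return An object of class `stage_schedule`.
#' @examples
#' sch <- stage_schedule()
#' protocol_lbnp(sch, c(120, 310, 1499))
#' @export
stage_schedule <- function(baseline_duration = 300,
                           stage_levels = c(15, 30, 45, 60, 70, 80, 90, 100),
                           stage_duration = 300) {
  stopifnot(baseline_duration > 0, stage_duration > 0,
            length(stage_levels) >= 1, all(diff(stage_levels) > 0),
            all(stage_levels > 0))
  structure(list(baseline_duration = baseline_duration,
                 stage_levels = as.numeric(stage_levels),
                 stage_duration = stage_duration),
            class = "stage_schedule")
}

#' Total protocol duration of a schedule, seconds
#' @param schedule A [stage_schedule()].
#' @return Seconds from protocol start to the end of the last stage.
#' @export
schedule_end <- function(schedule) {
  schedule$baseline_duration +
    length(schedule$stage_levels) * schedule$stage_duration
}

#' LBNP magnitude applied at time t
#'
#' Piecewise-constant lookup of the active LBNP level: 0 during baseline,
#' then `stage_levels[k]` on the k-th stage window.
#'
#' @param schedule A [stage_schedule()].
#' @param t Time(s) from protocol start, seconds.  Vectorized.
#' @return LBNP magnitude(s) in mmHg.
#' @export
protocol_lbnp <- function(schedule, t) {
  stopifnot(inherits(schedule, "stage_schedule"), is.numeric(t))
  if (any(t < 0)) stop("protocol time must be non-negative")
  if (any(t >= schedule_end(schedule)))
    stop("protocol overrun: t beyond the end of the schedule")
  k <- floor((t - schedule$baseline_duration) / schedule$stage_duration)
  out <- numeric(length(t))
  active <- t >= schedule$baseline_duration
  out[active] <- schedule$stage_levels[k[active] + 1]
  out
}

#' Protocol time at which a given LBNP level is completed
#'
#' Links stage levels to cumulative protocol time, e.g. completing the
#' 60 mmHg stage of the default schedule takes 1500 s including baseline.
#'
#' @param schedule A [stage_schedule()].
#' @param level An LBNP magnitude present in `schedule$stage_levels`.
#' @return Seconds from protocol start to the end of that stage.
#' @export
stage_completion_time <- function(schedule, level) {
  stopifnot(inherits(schedule, "stage_schedule"), length(level) == 1)
  i <- match(level, schedule$stage_levels)
  if (is.na(i)) stop("unknown LBNP level: ", level)
  schedule$baseline_duration + i * schedule$stage_duration
}

#' Map an LBNP magnitude to an equivalent blood-loss volume
#'
#' Piecewise-linear interpolation through the experimentally established
#' anchor points (0, 0), (30, 450), (60, 1000) and (90, 1600) mL for a 70 kg
#' human, linearly extrapolated beyond 90 mmHg and scaled proportionally to
#' body mass.
#'
#' @param lbnp LBNP magnitude(s), mmHg (non-negative).  Vectorized.
#' @param body_mass Body mass in kg (default 70, the reference human).
#' @return Estimated blood-loss volume(s), mL.
#' @examples
#' lbnp_to_blood_loss(60, 70)   # 1000
#' lbnp_to_blood_loss(45, 70)   # 725, midpoint of the 30-60 chord
#' @export
lbnp_to_blood_loss <- function(lbnp, body_mass = 70) {
  stopifnot(is.numeric(lbnp), length(body_mass) == 1, body_mass > 0)
  if (any(lbnp < 0)) stop("LBNP magnitude must be non-negative")
  xs <- c(0, 30, 60, 90)
  ys <- c(0, 450, 1000, 1600)
  base <- ifelse(lbnp <= 90,
                 approx(xs, ys, xout = pmin(lbnp, 90))$y,
                 1600 + (lbnp - 90) * (1600 - 1000) / 30)
  base * body_mass / 70
}
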
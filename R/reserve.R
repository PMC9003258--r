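#' Compensatory reserve from blood-loss volume
#'
#' The reserve is the remaining fraction of an individual's capacity to
#' compensate for blood-volume loss: `1 - BLV / BLV@HD`, where BLV is the
#' current blood-loss volume and BLV@HD the volume at which hemodynamic
#' decompensation occurs.
#'
#' @param blv Current blood-loss volume(s), mL.  Vectorized.
#' @param blv_at_hd Blood-loss volume at decompensation, mL (positive scalar).
#' @return Reserve fraction(s) in \[0, 1\].
#' @export
reserve_from_blv <- function(blv, blv_at_hd) {
  stopifnot(is.numeric(blv), length(blv_at_hd) == 1)
  if (blv_at_hd <= 0) stop("blv_at_hd must be positive")
  if (any(blv < 0)) stop("blood-loss volume must be non-negative")
  if (any(blv > blv_at_hd))
    stop("blv exceeds blv_at_hd: reserve cannot be negative")
  1 - blv / blv_at_hd
}

#' Compensatory reserve from the LBNP surrogate
#'
#' Because staged LBNP closely mimics graded hemorrhage, the reserve can be
#' approximated directly from suction levels: `1 - LBNP(t) / LBNP@HD`.
#' Both arguments are magnitudes (positive mmHg).
#'
#' @param lbnp Current LBNP magnitude(s), mmHg.  Vectorized.
#' @param lbnp_at_hd LBNP magnitude at decompensation, mmHg (positive scalar).
#' @return Reserve fraction(s) in \[0, 1\].
#' @examples
#' reserve_from_lbnp(30, 60)  # 0.5
#' @export
reserve_from_lbnp <- function(lbnp, lbnp_at_hd) {
  stopifnot(is.numeric(lbnp), length(lbnp_at_hd) == 1)
  if (lbnp_at_hd <= 0) stop("lbnp_at_hd must be positive")
  if (any(lbnp < 0)) stop("LBNP magnitude must be non-negative")
  if (any(lbnp > lbnp_at_hd))
    stop("lbnp exceeds lbnp_at_hd: reserve cannot be negative")
  1 - lbnp / lbnp_at_hd
}

#' Stepwise oracle reserve of a simulated subject
#'
#' The ground-truth training/evaluation target: the LBNP-surrogate reserve of
#' the stage active at time `t`.  It equals 1 throughout baseline, steps down
#' at each stage transition, and is 0 on the stage during which the subject
#' decompensates.
#'
#' @param subject A `subject_profile` (see [sample_subject()]).
#' @param schedule A [stage_schedule()].
#' @param t Time(s) in `[0, tolerance_time]`, seconds.  Vectorized.
#' @return Reserve fraction(s) in \[0, 1\].
#' @export
true_reserve <- function(subject, schedule, t) {
  stopifnot(inherits(subject, "subject_profile"))
  if (subject$lbnp_at_hd <= 0) stop("undefined subject: lbnp_at_hd is zero")
  if (any(t < 0) || any(t > subject$tolerance_time))
    stop("t outside [0, tolerance_time]")
  reserve_from_lbnp(protocol_lbnp(schedule, t), subject$lbnp_at_hd)
}

#' Continuous depletion driver used for waveform morphology
#'
#' Linear interpolation of the stepwise reserve: knots sit at the protocol
#' start (reserve 1), at the end of every completed stage (that stage's
#' stepwise reserve), and at the tolerance time (reserve 0).  The returned
#' value is the depletion `d(t) = 1 - reserve`, a continuous non-decreasing
#' ramp that reaches exactly 1 at decompensation.  Training targets stay
#' stepwise; only the synthetic morphology follows this driver, so that the
#' within-stage physiological deterioration is a learnable signal.
#'
#' @inheritParams true_reserve
#' @return Depletion fraction(s) in \[0, 1\].
#' @export
depletion_driver <- function(subject, schedule, t) {
  stopifnot(inherits(subject, "subject_profile"))
  tt <- subject$tolerance_time
  if (any(t < 0) || any(t > tt)) stop("t outside [0, tolerance_time]")
  b <- schedule$baseline_duration
  sd_ <- schedule$stage_duration
  ends <- b + sd_ * seq_along(schedule$stage_levels)
  ends <- ends[ends < tt]
  knots_t <- c(0, b, ends, tt)
  knots_r <- c(1, 1,
               if (length(ends)) true_reserve(subject, schedule, ends - 1e-9),
               0)
  1 - approx(knots_t, knots_r, xout = t, rule = 2)$y
}
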
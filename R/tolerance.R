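#' Classify tolerance to central hypovolemia
#'
#' Subjects who decompensate before completing the 60 mmHg stage (total
#' protocol time under 1500 s including baseline rest) are low tolerant (LT);
#' subjects who tolerate beyond that level are high tolerant (HT).  A
#' tolerance time of exactly 1500 s means the 60 mmHg stage was completed and
#' is classified HT.
#'
#' @param tolerance_time Seconds from protocol start to decompensation.
#'   Vectorized.
#' @param threshold Classification threshold in seconds; the default 1500
#'   corresponds to completing the 60 mmHg stage of the default schedule.
#'   Use [stage_completion_time()] to derive it for shortened schedules.
#' @return Character vector of `"HT"` / `"LT"` labels.
#' @examples
#' classify_tolerance(c(1286, 1838))
#' @export
classify_tolerance <- function(tolerance_time, threshold = 1500) {
  stopifnot(is.numeric(tolerance_time), length(threshold) == 1, threshold > 0)
  if (any(tolerance_time <= 0)) stop("tolerance time must be positive")
  ifelse(tolerance_time < threshold, "LT", "HT")
}
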
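#' Truncate a waveform record to a time interval
#'
#' Keeps samples with times in `[start, end)`.  Values are never altered or
#' filtered; only the extent changes.  The decompensation time is preserved
#' when it lies inside the retained range.
#'
#' @param record A [waveform_record()].
#' @param start,end Interval bounds in record time, seconds.
#' @return A [waveform_record()] spanning `[start, end)`.
#' @export
truncate_record <- function(record, start = record$start_time,
                            end = record$decomp_time) {
  stopifnot(inherits(record, "waveform_record"))
  if (start >= end) stop("empty truncation interval")
  if (end > record$start_time + (length(record$pressure) + 1) /
        record$sampling_rate)
    stop("truncation end beyond record end")
  fs <- record$sampling_rate
  k <- seq_along(record$pressure)
  t <- record$start_time + (k - 1) / fs
  keep <- t >= start - 1e-12 & t < end - 1e-12
  onsets <- record$beat_onsets
  if (!is.null(onsets)) onsets <- onsets[onsets >= start & onsets < end]
  waveform_record(record$subject_id, record$pressure[keep], fs,
                  start_time = start,
                  decomp_time = min(record$decomp_time, end),
                  normalized = record$normalized, beat_onsets = onsets)
}

#' Downsample a record to 100 samples per second
#'
#' 1-D linear interpolation onto the grid `start_time + k / rate`,
#' `k = 0, 1, ...`; the duration is preserved to within one input sample
#' period.  Higher acquisition rates carry no extra information for reserve
#' estimation, and 100 samples/s keeps segment tensors small.
#'
#' @param record A [waveform_record()] sampled at >= `rate`.
#' @param rate Output sampling rate, samples/s (default 100).
#' @return A [waveform_record()] at `rate`.
#' @export
resample_100hz <- function(record, rate = 100) {
  stopifnot(inherits(record, "waveform_record"))
  if (record$sampling_rate < rate)
    stop("input sampling rate below the target rate")
  if (length(record$pressure) < 2) stop("need at least 2 samples")
  fs <- record$sampling_rate
  t_in <- record$start_time + (seq_along(record$pressure) - 1) / fs
  n_out <- round((record$decomp_time - record$start_time) * rate)
  t_out <- record$start_time + (seq_len(n_out) - 1) / rate
  t_out <- pmin(t_out, t_in[length(t_in)])  # clamp final grid point
  p <- approx(t_in, record$pressure, xout = t_out, method = "linear")$y
  waveform_record(record$subject_id, p, rate,
                  start_time = record$start_time,
                  decomp_time = record$decomp_time,
                  normalized = record$normalized,
                  beat_onsets = record$beat_onsets)
}

#' Min/max normalize a record to the 0-1 range
#'
#' Scaling constants are taken over the subject's whole (truncated) record,
#' not per segment, so relative pulse-pressure information across the
#' experiment is preserved.  The output attains both 0 and 1.
#'
#' @param record A [waveform_record()].
#' @return A normalized [waveform_record()] with attribute fields
#'   `norm_min`, `norm_max` recording the original range.
#' @export
normalize_minmax <- function(record) {
  stopifnot(inherits(record, "waveform_record"))
  lo <- min(record$pressure); hi <- max(record$pressure)
  if (hi <= lo) stop("degenerate input: flat record cannot be normalized")
  out <- waveform_record(record$subject_id, (record$pressure - lo) / (hi - lo),
                         record$sampling_rate, record$start_time,
                         record$decomp_time, normalized = TRUE,
                         beat_onsets = record$beat_onsets)
  out$norm_min <- lo; out$norm_max <- hi
  out
}

#' Segment a normalized 100 samples/s record into fixed windows
#'
#' Consecutive non-overlapping windows of `seg_seconds` from the record
#' start; a trailing remainder shorter than one window is dropped, and the
#' last retained segment carries the decompensation flag.
#'
#' @param record A [waveform_record()] at 100 samples/s.
#' @param seg_seconds Window length, seconds (default 20).
#' @return An object of class `segment_set`: list with `samples` (matrix,
#'   one row per segment) and `meta` (data frame with `subject_id`,
#'   `segment_index`, `start_time`, `target`, `decomp_flag`).
#' @export
segment_record <- function(record, seg_seconds = 20) {
  stopifnot(inherits(record, "waveform_record"))
  if (record$sampling_rate != 100)
    stop("segmentation expects a 100 samples/s record")
  len <- seg_seconds * record$sampling_rate
  n_seg <- floor(length(record$pressure) / len)
  if (n_seg < 1) stop("record shorter than one segment")
  m <- t(matrix(record$pressure[seq_len(n_seg * len)], nrow = len))
  meta <- data.frame(
    subject_id = record$subject_id,
    segment_index = seq_len(n_seg),
    start_time = record$start_time + (seq_len(n_seg) - 1) * seg_seconds,
    target = NA_real_,
    decomp_flag = c(rep(FALSE, n_seg - 1), TRUE),
    stringsAsFactors = FALSE)
  structure(list(samples = m, meta = meta, seg_seconds = seg_seconds,
                 rate = record$sampling_rate),
            class = "segment_set")
}

#' Assign stepwise reserve targets to segments
#'
#' Each segment's target is the oracle stepwise reserve evaluated at the
#' segment's start time; the decompensation-flagged final segment is pinned
#' to 0 (the subject decompensates within it).  Targets start at 1, are
#' non-increasing, and end at 0.
#'
#' @param segments A `segment_set` from [segment_record()].
#' @param subject The matching `subject_profile`.
#' @param schedule A [stage_schedule()].
#' @return The `segment_set` with `meta$target` filled in.
#' @export
assign_targets <- function(segments, subject, schedule) {
  stopifnot(inherits(segments, "segment_set"),
            inherits(subject, "subject_profile"))
  st <- segments$meta$start_time
  if (is.unsorted(st)) stop("segments must be ordered by time")
  if (any(st > subject$tolerance_time))
    stop("consistency error: segment starts beyond tolerance_time")
  tgt <- true_reserve(subject, schedule, st)
  tgt[segments$meta$decomp_flag] <- 0
  if (any(diff(tgt) > 1e-12)) stop("targets must be non-increasing")
  segments$meta$target <- tgt
  segments
}

#' Run the full preprocessing pipeline for one record
#'
#' Fixed composition order: truncate, resample to 100 samples/s, min/max
#' normalize, segment, assign stepwise targets.
#'
#' @param record A raw [waveform_record()].
#' @param subject The matching `subject_profile`.
#' @param schedule A [stage_schedule()].
#' @param seg_seconds Segment length, seconds.
#' @param rate Target sampling rate, samples/s.
#' @return A `segment_set` with targets.
#' @export
preprocess_record <- function(record, subject, schedule,
                              seg_seconds = 20, rate = 100) {
  record |>
    truncate_record() |>
    resample_100hz(rate = rate) |>
    normalize_minmax() |>
    segment_record(seg_seconds = seg_seconds) |>
    assign_targets(subject, schedule)
}

#' Combine segment sets from several subjects
#' @param ... `segment_set` objects (or a single list of them).
#' @return One `segment_set` with row-bound samples and metadata.
#' @export
bind_segments <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && !inherits(sets[[1]], "segment_set"))
    sets <- sets[[1]]
  stopifnot(all(vapply(sets, inherits, TRUE, "segment_set")))
  structure(list(samples = do.call(rbind, lapply(sets, `[[`, "samples")),
                 meta = do.call(rbind, lapply(sets, `[[`, "meta")),
                 seg_seconds = sets[[1]]$seg_seconds,
                 rate = sets[[1]]$rate),
            class = "segment_set")
}

#' Preprocess every record of a cohort
#'
#' @param cohort An `lbnp_cohort` with waveforms.
#' @param seg_seconds,rate See [preprocess_record()].
#' @return A combined `segment_set` across subjects.
#' @export
preprocess_cohort <- function(cohort, seg_seconds = 20, rate = 100) {
  stopifnot(inherits(cohort, "lbnp_cohort"), !is.null(cohort$records))
  sch <- cohort$config$schedule
  sets <- lapply(seq_along(cohort$subjects), function(i)
    preprocess_record(cohort$records[[i]], cohort$subjects[[i]], sch,
                      seg_seconds = seg_seconds, rate = rate))
  bind_segments(sets)
}
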
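#' Write a waveform record to delimited text
#'
#' Tab-separated UTF-8 with header columns `time_s`, `pressure_mmHg` and a
#' `.` decimal separator; one file per subject.
#'
#' @param record A [waveform_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(record, path) {
  stopifnot(inherits(record, "waveform_record"))
  t <- record$start_time +
    (seq_along(record$pressure) - 1) / record$sampling_rate
  data.table::fwrite(data.table::data.table(time_s = t,
                                            pressure_mmHg = record$pressure),
                     path, sep = "\t")
  invisible(path)
}

#' Read a waveform record from delimited text
#'
#' @param path File written by [write_waveform()] (or any two-column
#'   time/pressure table with that header).
#' @param subject_id Identifier (default: file stem).
#' @return A [waveform_record()]; the sampling rate is inferred from the
#'   time column.
#' @export
read_waveform <- function(path, subject_id = NULL) {
  d <- data.table::fread(path)
  stopifnot(all(c("time_s", "pressure_mmHg") %in% names(d)))
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  fs <- round(1 / median(diff(d$time_s)))
  waveform_record(subject_id, d$pressure_mmHg, fs, start_time = d$time_s[1])
}

#' Write cohort metadata sidecar
#'
#' @param cohort An `lbnp_cohort`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_meta <- function(cohort, path) {
  stopifnot(inherits(cohort, "lbnp_cohort"))
  meta <- cohort$profiles
  meta$seed <- cohort$config$seed
  data.table::fwrite(meta, path)
  invisible(path)
}

#' Read cohort metadata sidecar
#' @param path CSV written by [write_cohort_meta()].
#' @return Data frame of subject profiles.
#' @export
read_cohort_meta <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Write a reserve series to CSV (columns `time_s`, `reserve`)
#' @param series A `reserve_series`.
#' @param path CSV path.
#' @export
write_series <- function(series, path) {
  data.table::fwrite(
    data.table::data.table(subject_id = series$subject_id,
                           time_s = series$time, reserve = series$value,
                           source = series$source), path)
  invisible(path)
}

#' Read a reserve series CSV
#' @param path CSV written by [write_series()].
#' @param cadence Cadence attribute to attach, seconds.
#' @return A `reserve_series`.
#' @export
read_series <- function(path, cadence = 10) {
  d <- as.data.frame(data.table::fread(path))
  reserve_series(d$subject_id, d$time_s, d$reserve, d$source, cadence)
}

#' Save a segment store (versioned container)
#'
#' Metadata travels as a data frame and the fixed-length sample arrays as a
#' numeric matrix; the container is an RDS file with an explicit format
#' version.
#'
#' @param segments A `segment_set`.
#' @param path Output path (`.rds`).
#' @export
write_segments <- function(segments, path) {
  stopifnot(inherits(segments, "segment_set"))
  saveRDS(list(format = "crwave_segments", version = 1L,
               meta = segments$meta, samples = segments$samples,
               seg_seconds = segments$seg_seconds, rate = segments$rate),
          path)
  invisible(path)
}

#' Load a segment store
#' @param path Path written by [write_segments()].
#' @return A `segment_set`.
#' @export
read_segments <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "crwave_segments"))
    stop("not a crwave segment store")
  structure(list(samples = x$samples, meta = x$meta,
                 seg_seconds = x$seg_seconds, rate = x$rate),
            class = "segment_set")
}
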
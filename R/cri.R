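#' Detect beat onsets in an arterial pressure record
#'
#' Onsets are the local minima preceding each systolic upstroke.  The signal
#' is lightly smoothed, candidate minima are found between successive
#' crossings of an adaptive mid-level threshold, and inter-onset intervals
#' are constrained to the physiologic band (0.3-2.0 s).
#'
#' @param record A [waveform_record()] (normalized 100 samples/s expected;
#'   any uniformly sampled record works).
#' @return Numeric vector of onset times (seconds), strictly increasing.
#' @export
detect_beats <- function(record) {
  stopifnot(inherits(record, "waveform_record"))
  fs <- record$sampling_rate
  n <- length(record$pressure)
  p <- .moving_average(record$pressure, max(3L, as.integer(fs * 0.04)))
  rng <- range(p)
  if (diff(rng) < 1e-6 * max(1, abs(rng[2])))
    stop("signal-quality error: no detectable beats in a flat record")
  d <- c(0, diff(p))
  # slope threshold adapts per 10-s block so late, low-amplitude beats are
  # still caught; the dicrotic upstroke stays below half the systolic slope
  block <- as.integer(10 * fs)
  thr <- numeric(n)
  for (i0 in seq(1, n, by = block)) {
    i1 <- min(n, i0 + block - 1)
    thr[i0:i1] <- 0.5 * quantile(d[i0:i1], 0.99, names = FALSE)
  }
  cand <- which(d > pmax(thr, 1e-12))
  if (length(cand) < 2) stop("signal-quality error: no detectable beats")
  grp <- cumsum(c(TRUE, diff(cand) > 0.25 * fs))
  upstroke <- vapply(split(cand, grp),
                     function(ii) ii[which.max(d[ii])], 0)
  onsets <- vapply(upstroke, function(u) {
    lo <- max(1, u - as.integer(0.3 * fs))
    lo + which.min(p[lo:u]) - 1
  }, 0)
  onsets <- sort(unique(onsets))
  # enforce physiologic spacing (at least 0.25 s between onsets)
  keep <- c(TRUE, diff(onsets) > 0.25 * fs)
  onsets <- onsets[keep]
  if (length(onsets) < 2) stop("signal-quality error: no detectable beats")
  record$start_time + (onsets - 1) / fs
}

#' Extract per-beat morphology features
#'
#' One feature vector per complete beat (onset to next onset): beat interval,
#' pulse amplitude, systolic upstroke slope, time-to-peak fraction,
#' dicrotic-notch relative amplitude (secondary-peak rise after the systolic
#' peak), and the systolic/diastolic area ratio.  Beats with non-finite
#' features are skipped and counted.
#'
#' @param record A [waveform_record()].
#' @param onsets Beat onset times from [detect_beats()].
#' @return A data frame with one row per beat (`time` = onset), feature
#'   columns, and attribute `n_skipped`.
#' @export
extract_beat_features <- function(record, onsets) {
  stopifnot(inherits(record, "waveform_record"), length(onsets) >= 2)
  fs <- record$sampling_rate
  p <- .moving_average(record$pressure, max(3L, as.integer(fs * 0.04)))
  idx <- as.integer(round((onsets - record$start_time) * fs)) + 1L
  n <- length(onsets) - 1L
  feats <- matrix(NA_real_, n, 6)
  for (j in seq_len(n)) {
    i0 <- idx[j]; i1 <- idx[j + 1] - 1L
    beat <- p[i0:i1]
    m <- length(beat)
    interval <- m / fs
    pk <- which.max(beat)
    amp <- beat[pk] - beat[1]
    slope <- if (pk > 1) amp / ((pk - 1) / fs) else NA_real_
    ttp <- (pk - 1) / m
    # secondary (dicrotic) peak after the systolic peak
    notch <- 0
    if (pk < m - 2) {
      post <- beat[pk:m]
      d <- diff(post)
      rises <- which(d[-1] > 0 & d[-length(d)] <= 0)  # local minima then rise
      if (length(rises)) {
        tr <- rises[1] + 1L
        sec_pk <- tr + which.max(post[tr:length(post)]) - 1L
        notch <- (max(post[tr:sec_pk]) - post[tr]) / max(amp, 1e-12)
      }
    }
    cut <- max(2L, as.integer(0.4 * m))
    base <- min(beat)
    area_s <- sum(beat[1:cut] - base)
    area_d <- sum(beat[(cut + 1):m] - base)
    feats[j, ] <- c(interval, amp, slope, ttp, notch,
                    area_s / max(area_d, 1e-12))
  }
  ok <- apply(is.finite(feats), 1, all) &
    feats[, 1] > 0.3 & feats[, 1] < 2.0
  out <- data.frame(subject_id = record$subject_id,
                    time = onsets[seq_len(n)][ok],
                    interval = feats[ok, 1], amplitude = feats[ok, 2],
                    upstroke = feats[ok, 3], time_to_peak = feats[ok, 4],
                    notch_amp = feats[ok, 5], area_ratio = feats[ok, 6],
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(!ok)
  out
}

.cri_feature_cols <- c("interval", "amplitude", "upstroke", "time_to_peak",
                       "notch_amp", "area_ratio")

#' Build the per-beat training table for a cohort
#'
#' Preprocesses each record (truncate, resample, normalize), detects beats,
#' extracts features, and attaches the stepwise oracle reserve at each beat
#' onset as the regression target.
#'
#' @param cohort An `lbnp_cohort` with waveforms.
#' @return A data frame of features plus `target`.
#' @export
beat_training_table <- function(cohort) {
  stopifnot(inherits(cohort, "lbnp_cohort"), !is.null(cohort$records))
  sch <- cohort$config$schedule
  tabs <- lapply(seq_along(cohort$subjects), function(i) {
    rec <- normalize_minmax(resample_100hz(truncate_record(
      cohort$records[[i]])))
    f <- extract_beat_features(rec, detect_beats(rec))
    f$target <- true_reserve(cohort$subjects[[i]], sch,
                             pmin(f$time, cohort$subjects[[i]]$tolerance_time))
    f
  })
  do.call(rbind, tabs)
}

#' Train the beat-feature reserve estimator
#'
#' Ridge regression of the stepwise reserve target on the six standardized
#' beat features.  Transparent and deterministic; it stands in for the
#' proprietary feature-based algorithm it emulates.
#'
#' @param features Data frame from [extract_beat_features()] /
#'   [beat_training_table()].
#' @param targets Reserve fractions, one per row of `features` (defaults to
#'   `features$target`).
#' @param lambda Ridge penalty.
#' @return An object of class `cri_estimator`.
#' @export
cri_train <- function(features, targets = features$target, lambda = 1) {
  X <- as.matrix(features[, .cri_feature_cols])
  stopifnot(nrow(X) == length(targets), lambda >= 0)
  if (!all(is.finite(X))) stop("degenerate features: non-finite values")
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv < 1e-12] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  Za <- cbind(1, Z)
  A <- crossprod(Za) + lambda * diag(c(0, rep(1, ncol(Z))))
  beta <- solve(A, crossprod(Za, targets))
  structure(list(beta = drop(beta), mu = mu, sd = sdv, lambda = lambda),
            class = "cri_estimator")
}

#' Per-beat predictions from the feature estimator
#' @param estimator A `cri_estimator`.
#' @param features Data frame of beat features.
#' @param clip Clip into \[0, 1\].
#' @return Numeric vector, one prediction per beat.
#' @export
cri_predict <- function(estimator, features, clip = TRUE) {
  stopifnot(inherits(estimator, "cri_estimator"))
  X <- as.matrix(features[, .cri_feature_cols])
  Z <- sweep(sweep(X, 2, estimator$mu), 2, estimator$sd, "/")
  out <- drop(cbind(1, Z) %*% estimator$beta)
  if (clip) out <- pmin(1, pmax(0, out))
  out
}

#' Reserve time series from the beat-feature estimator
#'
#' Per-beat predictions are averaged over a trailing 30-beat sliding window
#' and resampled to the 10-s cadence.  Before 30 beats have elapsed the
#' running mean over all beats so far is used (documented warm-up).
#'
#' @param estimator A `cri_estimator`.
#' @param record A normalized [waveform_record()] at 100 samples/s.
#' @param cadence Seconds between estimates (default 10).
#' @param window Number of beats in the sliding mean (default 30).
#' @param win Warm-up before the first estimate, seconds (matches the
#'   convolutional estimator's first window).
#' @return A `reserve_series` with source `"cri_like"`.
#' @export
cri_predict_series <- function(estimator, record, cadence = 10, window = 30,
                               win = 20) {
  stopifnot(inherits(estimator, "cri_estimator"),
            inherits(record, "waveform_record"))
  onsets <- detect_beats(record)
  feats <- extract_beat_features(record, onsets)
  pb <- cri_predict(estimator, feats, clip = FALSE)
  roll <- .trailing_mean(pb, window)
  dur <- floor(record_duration(record) / cadence) * cadence
  ends <- record$start_time + seq(win, dur, by = cadence)
  ji <- findInterval(ends, feats$time)
  ji[ji < 1] <- 1
  reserve_series(record$subject_id, ends, pmin(1, pmax(0, roll[ji])),
                 "cri_like", cadence)
}

# trailing running mean over at most `window` previous values
.trailing_mean <- function(x, window) {
  cs <- cumsum(x)
  n <- length(x)
  i <- seq_len(n)
  lo <- pmax(0, i - window)
  (cs - c(0, cs)[lo + 1]) / (i - lo)
}
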
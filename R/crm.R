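#' Architecture of the convolutional reserve estimator
#'
#' The network follows the published block structure: one input convolutional
#' layer, seven convolutional/pooling blocks, two fully connected layers and
#' a final linear unit.  With kernel width 7 and pooling factor 2 per block,
#' a 2000-sample segment is reduced to 15 time steps before the dense head.
#' Channel counts, kernel width and dense sizes are configurable; the
#' defaults are the smallest stack that trains in minutes on one CPU.
#'
#' @param channels Channel count of the input conv layer followed by the
#'   seven conv/pool blocks (length 8).
#' @param kernel Convolution kernel width (odd).
#' @param fc Sizes of the two fully connected layers.
#' @param input_len Segment length in samples.
#' @return An object of class `crm_architecture`.
#' @export
crm_architecture <- function(channels = c(8, 16, 16, 32, 32, 64, 64, 64),
                             kernel = 7, fc = c(64, 32), input_len = 2000) {
  stopifnot(length(channels) == 8, kernel %% 2 == 1, length(fc) == 2,
            all(channels >= 1), all(fc >= 1))
  L <- input_len
  for (i in 2:8) L <- L %/% 2
  if (L < 1)
    stop("architecture error: input length incompatible with pooling chain")
  structure(list(channels = as.integer(channels), kernel = as.integer(kernel),
                 fc = as.integer(fc), input_len = as.integer(input_len),
                 final_len = as.integer(L)),
            class = "crm_architecture")
}

#' Number of named blocks of an architecture
#'
#' Input conv + seven conv/pool blocks + two fully connected layers + one
#' linear output = 11 for the default stack.
#'
#' @param arch A [crm_architecture()].
#' @export
n_blocks <- function(arch) {
  stopifnot(inherits(arch, "crm_architecture"))
  1L + 7L + length(arch$fc) + 1L
}

.he_init <- function(nr, nc, fan_in) {
  matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

#' Build an untrained convolutional reserve model
#'
#' Parameter initialization (He-scaled Gaussians) is fully determined by the
#' seed.  The model maps a length-`input_len` single-channel segment to one
#' unbounded scalar; clipping to the reserve range happens at inference.
#'
#' @param arch A [crm_architecture()].
#' @param seed Integer seed for initialization.
#' @return An object of class `crm_model`.
#' @export
crm_build <- function(arch = crm_architecture(), seed = 1) {
  stopifnot(inherits(arch, "crm_architecture"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  K <- arch$kernel
  ch <- arch$channels
  convs <- vector("list", 8)
  c_in <- 1L
  for (l in 1:8) {
    convs[[l]] <- list(W = .he_init(c_in * K, ch[l], c_in * K),
                       b = rep(0, ch[l]),
                       pool = l > 1)
    c_in <- ch[l]
  }
  flat <- arch$final_len * ch[8]
  params <- list(convs = convs,
                 W1 = .he_init(flat, arch$fc[1], flat),
                 b1 = rep(0, arch$fc[1]),
                 W2 = .he_init(arch$fc[1], arch$fc[2], arch$fc[1]),
                 b2 = rep(0, arch$fc[2]),
                 Wo = .he_init(arch$fc[2], 1, arch$fc[2]),
                 bo = 0.5,  # start near mid-reserve
                 kernel = arch$kernel, input_len = arch$input_len)
  structure(list(arch = arch, params = params, seed = as.integer(seed),
                 history = numeric(0), trained = FALSE),
            class = "crm_model")
}

#' @export
print.crm_model <- function(x, ...) {
  cat(sprintf(
    "<crm_model: %d blocks, %s%s>\n", n_blocks(x$arch),
    if (x$trained) sprintf("trained (%d epochs, final loss %.4g)",
                           length(x$history), tail(x$history, 1))
    else "untrained",
    sprintf(", seed %d", x$seed)))
  invisible(x)
}

#' Split subjects into training and validation sets
#'
#' The split is always by subject, never by segment, so no subject
#' contributes to both sides.
#'
#' @param subject_ids Character vector of unique subject ids.
#' @param val_fraction Fraction of subjects held out.
#' @param seed Integer seed.
#' @return List with `train` and `val` character vectors.
#' @export
subject_split <- function(subject_ids, val_fraction = 0.2, seed = 1) {
  ids <- unique(subject_ids)
  stopifnot(length(ids) >= 2, val_fraction > 0, val_fraction < 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  n_val <- max(1L, round(length(ids) * val_fraction))
  val <- sample(ids, n_val)
  list(train = setdiff(ids, val), val = val)
}

#' Train the convolutional reserve model
#'
#' Mean-squared-error regression of segment samples onto their stepwise
#' reserve targets, optimized with Adam.  Subjects are split (not segments)
#' into training and validation sets; epoch shuffling comes from R's RNG so
#' training is reproducible bit for bit in single-threaded BLAS (multi-
#' threaded runs agree to within about 1e-3 validation loss).
#'
#' @param model A [crm_build()] model.
#' @param segments A `segment_set` with targets (multiple subjects).
#' @param epochs,batch,lr Optimization settings.
#' @param val_fraction Fraction of subjects held out for validation.
#' @param seed Seed for the split and the shuffling.
#' @return The trained `crm_model`, with `history` (per-epoch training
#'   loss), `val_loss`, and the subject split recorded.
#' @export
crm_train <- function(model, segments, epochs = 10, batch = 64, lr = 1e-3,
                      val_fraction = 0.2, seed = 1) {
  stopifnot(inherits(model, "crm_model"), inherits(segments, "segment_set"),
            epochs >= 0, batch >= 1, lr > 0)
  if (anyNA(segments$meta$target)) stop("segments carry no targets")
  sp <- subject_split(segments$meta$subject_id, val_fraction, seed)
  if (length(intersect(sp$train, sp$val)))
    stop("validation error: subject leakage between splits")
  tr <- segments$meta$subject_id %in% sp$train
  X <- segments$samples[tr, , drop = FALSE]
  y <- segments$meta$target[tr]
  model$split <- sp
  if (epochs == 0) {
    model$history <- numeric(0)
    return(model)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  ord <- t(replicate(epochs, sample.int(nrow(X))))
  ord <- matrix(as.integer(ord), nrow = epochs)
  fit <- cpp_cnn_train(model$params, X, y, ord, as.integer(batch), lr)
  model$params <- fit$params
  model$history <- as.numeric(fit$history)
  model$trained <- TRUE
  va <- !tr
  if (any(va)) {
    pv <- crm_predict(model, segments$samples[va, , drop = FALSE])
    model$val_loss <- mean((pv - segments$meta$target[va])^2)
  }
  model
}

#' Score segments with the convolutional model
#'
#' @param model A `crm_model`.
#' @param samples Matrix with one length-`input_len` normalized segment per
#'   row (or a single vector).
#' @param clip Clip outputs into \[0, 1\] (default TRUE).
#' @return Numeric vector of reserve estimates.
#' @export
crm_predict <- function(model, samples, clip = TRUE) {
  stopifnot(inherits(model, "crm_model"))
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1)
  if (ncol(samples) != model$arch$input_len)
    stop("segment length does not match the architecture input length")
  out <- cpp_cnn_forward(model$params, samples)
  if (clip) out <- pmin(1, pmax(0, out))
  out
}

#' Reserve time series from the convolutional model
#'
#' At each 10-s cadence point `t = 20, 30, 40, ...` the trailing 20-s window
#' of the normalized 100 samples/s record is scored; training windows are
#' non-overlapping, but inference slides by the cadence.  Outputs are
#' clipped to \[0, 1\] and the series ends at the decompensation time.
#'
#' @param model A trained `crm_model`.
#' @param record A normalized [waveform_record()] at 100 samples/s.
#' @param cadence Seconds between estimates (default 10).
#' @return A data frame (`reserve_series`) with columns `subject_id`,
#'   `time`, `value`, `source`.
#' @export
crm_predict_series <- function(model, record, cadence = 10) {
  stopifnot(inherits(model, "crm_model"), inherits(record, "waveform_record"))
  if (record$sampling_rate != 100 || !record$normalized)
    stop("record must be preprocessed to 100 samples/s and normalized")
  win <- model$arch$input_len / record$sampling_rate
  dur <- floor(record_duration(record) / cadence) * cadence
  if (dur < win) stop("record shorter than one inference window")
  ends <- seq(win, dur, by = cadence)
  fs <- record$sampling_rate
  idx0 <- as.integer(round((ends - win) * fs))
  X <- t(vapply(idx0, function(i)
    record$pressure[(i + 1):(i + win * fs)], numeric(win * fs)))
  vals <- crm_predict(model, X)
  reserve_series(record$subject_id, record$start_time + ends, vals, "crm",
                 cadence)
}

#' Construct a reserve time series
#'
#' @param subject_id Identifier.
#' @param time Times of the estimates, seconds.
#' @param value Reserve fractions in \[0, 1\].
#' @param source Estimator name (`"oracle"`, `"crm"`, `"cri_like"`).
#' @param cadence Seconds between estimates.
#' @return A data frame of class `reserve_series`.
#' @export
reserve_series <- function(subject_id, time, value, source, cadence = 10) {
  stopifnot(length(time) == length(value),
            all(value >= -1e-9), all(value <= 1 + 1e-9))
  out <- data.frame(subject_id = subject_id, time = time,
                    value = pmin(1, pmax(0, value)),
                    source = source, stringsAsFactors = FALSE)
  attr(out, "cadence") <- cadence
  class(out) <- c("reserve_series", "data.frame")
  out
}

#' Oracle (ground-truth) reserve series on the inference cadence
#'
#' @param subject A `subject_profile`.
#' @param schedule A [stage_schedule()].
#' @param cadence Seconds between estimates.
#' @param win Warm-up window before the first estimate, seconds.
#' @return A `reserve_series` with source `"oracle"`.
#' @export
oracle_series <- function(subject, schedule, cadence = 10, win = 20) {
  dur <- floor(subject$tolerance_time / cadence) * cadence
  ends <- seq(win, dur, by = cadence)
  reserve_series(subject$subject_id, ends,
                 true_reserve(subject, schedule, ends), "oracle", cadence)
}
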
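#' Configuration of a full simulate-train-evaluate run
#'
#' A single global seed drives every stochastic step through documented
#' per-module derivations, so a run is reproducible from its persisted
#' configuration alone.
#'
#' @param simulator A [simulator_config()].
#' @param arch A [crm_architecture()].
#' @param epochs,batch,lr,val_fraction Training settings for the
#'   convolutional estimator.
#' @param ridge_lambda Penalty of the beat-feature estimator.
#' @param seg_seconds,rate Preprocessing parameters.
#' @param seed Global seed.
#' @param out_dir Output directory for artifacts (NULL = no persistence).
#' @return An object of class `run_config`.
#' @export
run_config <- function(simulator = simulator_config(n_subjects = 48),
                       arch = crm_architecture(),
                       epochs = 10, batch = 64, lr = 1e-3,
                       val_fraction = 0.2, ridge_lambda = 1,
                       seg_seconds = 20, rate = 100,
                       seed = 1, out_dir = NULL) {
  structure(list(simulator = simulator, arch = arch, epochs = epochs,
                 batch = batch, lr = lr, val_fraction = val_fraction,
                 ridge_lambda = ridge_lambda, seg_seconds = seg_seconds,
                 rate = rate, seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

.log <- function(fmt, ..., logfile = NULL) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                 sprintf(fmt, ...))
  message(msg)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE)
}

#' Run the full pipeline: simulate, preprocess, train, predict, evaluate
#'
#' Orchestrates cohort simulation, the preprocessing chain, training of both
#' estimators on the training-subject split, cadence inference for every
#' subject with the single trained models, and the head-to-head statistical
#' evaluation.  When `out_dir` is set, intermediate artifacts (cohort
#' metadata, waveforms, segment store, series, report tables) are persisted
#' with MD5 checksums and a run log.
#'
#' @param config A [run_config()].
#' @param cohort Optional pre-built `lbnp_cohort` (skips simulation).
#' @return A list with the `cr_evaluation` report, trained models, series,
#'   the cohort, and artifact paths (class `crwave_run`).
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  logfile <- NULL
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    logfile <- file.path(out, "run.log")
    cat(sprintf("crwave run, seed %d\n", config$seed), file = logfile)
  }
  if (is.null(cohort)) {
    .log("simulating cohort of %d subjects",
         config$simulator$n_subjects, logfile = logfile)
    cohort <- generate_cohort(config$simulator)
  }
  sch <- cohort$config$schedule
  if (config$simulator$n_subjects < 6)
    warning("very small cohort: downstream statistics will be unstable")
  .log("preprocessing %d records", length(cohort$records), logfile = logfile)
  segments <- preprocess_cohort(cohort, config$seg_seconds, config$rate)
  .log("training convolutional estimator (%d epochs)", config$epochs,
       logfile = logfile)
  crm <- crm_build(config$arch, seed = config$seed)
  crm <- crm_train(crm, segments, epochs = config$epochs,
                   batch = config$batch, lr = config$lr,
                   val_fraction = config$val_fraction, seed = config$seed)
  .log("training beat-feature estimator", logfile = logfile)
  beats <- beat_training_table(cohort)
  cri <- cri_train(beats[beats$subject_id %in% crm$split$train, ],
                   lambda = config$ridge_lambda)
  .log("predicting reserve series for all subjects", logfile = logfile)
  prep <- lapply(cohort$records, function(r)
    normalize_minmax(resample_100hz(truncate_record(r))))
  series_crm <- do.call(rbind, lapply(prep, function(r)
    crm_predict_series(crm, r)))
  series_cri <- do.call(rbind, lapply(prep, function(r)
    cri_predict_series(cri, r)))
  class(series_crm) <- class(series_cri) <- c("reserve_series", "data.frame")
  attr(series_crm, "cadence") <- attr(series_cri, "cadence") <- 10
  .log("evaluating head to head", logfile = logfile)
  report <- evaluate_head_to_head(series_crm, series_cri,
                                  cohort$profiles, sch)
  paths <- NULL
  if (!is.null(out)) {
    wdir <- file.path(out, "waveforms")
    dir.create(wdir, showWarnings = FALSE)
    for (id in names(cohort$records))
      write_waveform(cohort$records[[id]],
                     file.path(wdir, paste0(id, ".tsv")))
    paths <- c(meta = file.path(out, "cohort_meta.csv"),
               segments = file.path(out, "segments.rds"),
               series_a = file.path(out, "series_crm.csv"),
               series_b = file.path(out, "series_cri.csv"),
               table = file.path(out, "evaluation_table.csv"),
               report = file.path(out, "report.json"))
    write_cohort_meta(cohort, paths["meta"])
    write_segments(segments, paths["segments"])
    write_series(series_crm, paths["series_a"])
    write_series(series_cri, paths["series_b"])
    data.table::fwrite(evaluation_table(report), paths["table"])
    jsonlite::write_json(.report_summary(report), paths["report"],
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    checks <- tools::md5sum(c(paths, list.files(wdir, full.names = TRUE)))
    writeLines(sprintf("%s  %s", checks, names(checks)),
               file.path(out, "MD5SUMS"))
    counts <- table(cohort$profiles$tolerance_class)
    .log("classes: %s", paste(names(counts), counts, collapse = ", "),
         logfile = logfile)
  }
  structure(list(report = report, crm = crm, cri = cri,
                 series = list(crm = series_crm, cri_like = series_cri),
                 segments = segments, cohort = cohort, config = config,
                 paths = paths),
            class = "crwave_run")
}

.report_summary <- function(report) {
  lapply(report$strata, function(s) {
    if (is.null(s)) return(NULL)
    list(n_subjects = s$n_subjects,
         auc = lapply(s$auc, function(a)
           list(auc = a$auc, se = a$se, ci = a$ci)),
         auc_comparison = s$auc_comparison[c("difference", "z", "p")],
         end_of_stage_r2 = lapply(s$end_of_stage, `[[`, "r2"),
         steiger = s$dependent_correlation)
  })
}

#' Build the standard test fixtures
#'
#' `tiny`: 6 subjects on a shortened schedule (60-s baseline and stages) for
#' fast unit tests; `desk`: 48 subjects on the full schedule, the scale used
#' for the estimator-quality acceptance checks.  Fixed seeds make fixtures
#' stable across runs.
#'
#' @param scale `"tiny"` or `"desk"`.
#' @param dir Output directory (NULL: return the cohort without writing).
#' @param waveforms Synthesize waveforms.
#' @return The `lbnp_cohort`, invisibly when writing.
#' @export
make_fixtures <- function(scale = c("tiny", "desk"), dir = NULL,
                          waveforms = TRUE) {
  scale <- match.arg(scale)
  cfg <- fixture_config(scale)
  cohort <- generate_cohort(cfg, waveforms = waveforms)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort_meta(cohort, file.path(dir, "cohort_meta.csv"))
    if (waveforms)
      for (id in names(cohort$records))
        write_waveform(cohort$records[[id]],
                       file.path(dir, paste0(id, ".tsv")))
    return(invisible(cohort))
  }
  cohort
}

#' Simulator configuration of a named fixture scale
#' @param scale `"tiny"` or `"desk"`.
#' @return A [simulator_config()].
#' @export
fixture_config <- function(scale = c("tiny", "desk")) {
  scale <- match.arg(scale)
  if (scale == "tiny") {
    sch <- stage_schedule(baseline_duration = 60, stage_duration = 60)
    # class tolerance moments scaled by the schedule compression (60/300)
    simulator_config(n_subjects = 6, schedule = sch,
                     ht_tolerance_mean = 1838 / 5, ht_tolerance_sd = 262 / 5,
                     lt_tolerance_mean = 1286 / 5, lt_tolerance_sd = 193 / 5,
                     seed = 2024)
  } else {
    simulator_config(n_subjects = 48, seed = 2024)
  }
}
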
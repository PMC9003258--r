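# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# tiny cohort: 6 subjects on the shortened (60 s) schedule
tiny_cohort <- function() memo("tiny", function() make_fixtures("tiny"))

# a single mid-range subject on the full schedule, with and without noise
demo_subject <- function() memo("demo_subject", function() {
  cfg <- simulator_config(seed = 99)
  sample_subject(cfg, 3)
})

demo_config <- function(noise = 1) {
  simulator_config(seed = 99, noise_sd = noise)
}

demo_record <- function() memo("demo_record", function() {
  synthesize_waveform(demo_subject(), demo_config(), seed = 5)
})

demo_record_clean <- function() memo("demo_record_clean", function() {
  synthesize_waveform(demo_subject(), demo_config(noise = 0), seed = 5)
})

# preprocessed (100 Hz, normalized) version of the demo record
demo_prep <- function() memo("demo_prep", function() {
  normalize_minmax(resample_100hz(truncate_record(demo_record())))
})

# small trained models on the tiny cohort, reused across test files
tiny_models <- function() memo("tiny_models", function() {
  co <- tiny_cohort()
  segs <- preprocess_cohort(co)
  crm <- crm_train(crm_build(crm_architecture(), seed = 1), segs,
                   epochs = 2, seed = 1)
  beats <- beat_training_table(co)
  cri <- cri_train(beats[beats$subject_id %in% crm$split$train, ])
  list(cohort = co, segments = segs, crm = crm, cri = cri, beats = beats)
})
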
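test_that("architecture matches the stated block structure", {
  arch <- crm_architecture()
  expect_equal(n_blocks(arch), 11)  # 1 input conv + 7 conv/pool + 2 fc + 1
  expect_equal(arch$final_len, 15)  # 2000 through seven pool-by-2 stages
  expect_error(crm_architecture(input_len = 64), "pooling")
})

test_that("initialization is seed-deterministic and forward is finite", {
  m1 <- crm_build(crm_architecture(), seed = 3)
  m2 <- crm_build(crm_architecture(), seed = 3)
  expect_identical(m1$params, m2$params)
  m3 <- crm_build(crm_architecture(), seed = 4)
  expect_false(identical(m1$params$W1, m3$params$W1))
  p <- crm_predict(m1, rep(0, 2000), clip = FALSE)
  expect_true(is.finite(p))
  # batched and single-row forward agree
  set.seed(5)
  X <- matrix(runif(3 * 2000), 3, 2000)
  batched <- crm_predict(m1, X, clip = FALSE)
  single <- vapply(1:3, function(i) crm_predict(m1, X[i, ], clip = FALSE), 0)
  expect_equal(batched, single, tolerance = 1e-12)
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(11)
  m <- crm_build(crm_architecture(), seed = 5)
  X <- matrix(rnorm(2 * 2000), 2, 2000)
  y <- runif(2)
  g <- crwave:::cpp_cnn_loss_grad(m$params, X, y)
  eps <- 1e-6
  numgrad <- function(mutate) {
    p1 <- mutate(m$params, eps); p2 <- mutate(m$params, -eps)
    (crwave:::cpp_cnn_loss_grad(p1, X, y)$loss -
       crwave:::cpp_cnn_loss_grad(p2, X, y)$loss) / (2 * eps)
  }
  checks <- list()
  for (l in c(1, 4, 8)) for (k in 1:3) {
    i <- sample(length(m$params$convs[[l]]$W), 1)
    a <- g$convs[[l]]$W[i]
    n <- numgrad(function(p, e) { p$convs[[l]]$W[i] <- p$convs[[l]]$W[i] + e; p })
    checks[[length(checks) + 1]] <- c(a, n)
  }
  for (nm in c("W1", "W2", "Wo", "b1", "bo")) for (k in 1:2) {
    i <- sample(length(m$params[[nm]]), 1)
    a <- g[[nm]][i]
    n <- numgrad(function(p, e) { p[[nm]][i] <- p[[nm]][i] + e; p })
    checks[[length(checks) + 1]] <- c(a, n)
  }
  M <- do.call(rbind, checks)
  relerr <- abs(M[, 1] - M[, 2]) / pmax(1e-6, abs(M[, 1]) + abs(M[, 2]))
  expect_lt(max(relerr), 1e-4)
})

test_that("training is reproducible, improves the loss, and can overfit", {
  ms <- tiny_models()
  m <- ms$crm
  expect_true(m$trained)
  expect_lt(tail(m$history, 1), m$history[1])
  # identical seed, identical history
  m2 <- crm_train(crm_build(crm_architecture(), seed = 1), ms$segments,
                  epochs = 2, seed = 1)
  expect_identical(m2$history, m$history)
  expect_identical(m2$params, m$params)
  # zero epochs leaves parameters at initialization
  m0 <- crm_train(crm_build(crm_architecture(), seed = 1), ms$segments,
                  epochs = 0, seed = 1)
  expect_identical(m0$params, crm_build(crm_architecture(), seed = 1)$params)
  # no subject appears on both sides of the split
  expect_length(intersect(m$split$train, m$split$val), 0)
})

test_that("predictions are clipped and invariant to pre-normalization shift", {
  ms <- tiny_models()
  co <- ms$cohort
  rec <- co$records[[1]]
  shifted <- rec
  shifted$pressure <- rec$pressure + 25  # constant offset before scaling
  prep <- function(r) normalize_minmax(resample_100hz(truncate_record(r)))
  s1 <- crm_predict_series(ms$crm, prep(rec))
  s2 <- crm_predict_series(ms$crm, prep(shifted))
  expect_equal(s1$value, s2$value, tolerance = 1e-10)
  expect_true(all(s1$value >= 0 & s1$value <= 1))
})

test_that("series cadence and window-count arithmetic are exact", {
  ms <- tiny_models()
  rec <- waveform_record("x", rep(c(0, 1), 75000), 100, decomp_time = 1500,
                         normalized = TRUE)
  s <- crm_predict_series(ms$crm, rec)
  expect_equal(nrow(s), 149)              # t = 20, 30, ..., 1500
  expect_equal(s$time, seq(20, 1500, by = 10))
  short <- waveform_record("y", rep(c(0, 1), 500), 100, decomp_time = 10,
                           normalized = TRUE)
  expect_error(crm_predict_series(ms$crm, short), "shorter")
  raw <- waveform_record("z", rep(c(0, 1), 75000), 100, decomp_time = 1500)
  expect_error(crm_predict_series(ms$crm, raw), "normalized")
})
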
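# brute-force AUC oracle: concordant-pair counting with ties at 1/2
auc_brute <- function(scores, outcomes) {
  pos <- scores[outcomes == 1]; neg <- scores[outcomes == 0]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

test_that("labeling marks exactly the final observation as the event", {
  s <- reserve_series("S1", seq(20, 1500, 10), rep(0.5, 149), "oracle")
  obs <- label_observations(s)
  expect_equal(sum(obs$outcome == 0), 148)
  expect_equal(sum(obs$outcome == 1), 1)
  expect_equal(obs$time[obs$outcome == 1], 1500)
  empty <- s[0, ]; class(empty) <- c("reserve_series", "data.frame")
  expect_error(label_observations(empty), "empty")
})

test_that("roc_auc equals brute-force pair counting", {
  # toy: perfectly separated, then one swapped pair
  p1 <- c(.9, .8, .7, .6, .5, .4); y <- c(1, 1, 0, 0, 0, 0)
  expect_equal(roc_auc(p1, y)$auc, 1)
  p2 <- c(.9, .7, .8, .6, .5, .4)
  expect_equal(roc_auc(p2, y)$auc, 0.875)
  expect_equal(roc_auc(rep(0.3, 6), y)$auc, 0.5)  # no discrimination
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(10:300, 1)
    sc <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # with ties
    yy <- rbinom(n, 1, 0.3)
    if (length(unique(yy)) < 2) next
    expect_equal(roc_auc(sc, yy)$auc, auc_brute(sc, yy), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "both outcome classes")
  a <- roc_auc(p2, y)
  expect_true(a$ci[1] <= a$auc && a$auc <= a$ci[2])
})

test_that("paired AUC comparison is symmetric and sane on degenerate input", {
  p <- c(.9, .7, .8, .6, .5, .4); y <- c(1, 1, 0, 0, 0, 0)
  same <- compare_auc_paired(p, p, y)
  expect_equal(same$difference, 0)
  expect_equal(same$p, 1)
  set.seed(3)
  q <- runif(6)
  ab <- compare_auc_paired(p, q, y)
  ba <- compare_auc_paired(q, p, y)
  expect_equal(ab$p, ba$p)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$difference, -ba$difference)
})

test_that("paired DeLong p is close to a bootstrap oracle", {
  set.seed(14)
  n <- 120
  y <- rep(c(1, 0), c(30, 90))
  latent <- y + rnorm(n)
  a <- plogis(latent + rnorm(n, 0, 0.8))
  b <- plogis(0.4 * latent + rnorm(n, 0, 1.2))
  res <- compare_auc_paired(a, b, y)
  boots <- replicate(1000, {
    i <- c(sample(which(y == 1), 30, TRUE), sample(which(y == 0), 90, TRUE))
    auc_fast <- function(s) {
      r <- rank(s[i]); mean(r[y[i] == 1]) / 90 - (30 + 1) / (2 * 90)
    }
    auc_fast(a) - auc_fast(b)
  })
  z_boot <- res$difference / sd(boots)
  p_boot <- 2 * pnorm(-abs(z_boot))
  expect_lt(abs(res$p - p_boot), 0.05)
})

test_that("clustered logistic slope behaves under signal, noise, separation", {
  # signal: lower reserve -> higher event probability, slope negative,
  # predicted probabilities monotone decreasing in reserve
  mk_obs <- function(value_fn, n_cluster = 30, m = 25, seed = 1) {
    set.seed(seed)
    do.call(rbind, lapply(seq_len(n_cluster), function(c) {
      v <- value_fn(m)
      data.frame(subject_id = sprintf("c%03d", c), time = seq_len(m) * 10,
                 value = v, outcome = c(rep(0L, m - 1), 1L))
    }))
  }
  # noisy enough that events and late non-events overlap (no separation)
  obs <- mk_obs(function(m) seq(1, 0, length.out = m) + rnorm(m, 0, 0.2))
  obs$value <- pmin(1, pmax(0, obs$value))
  fit <- fit_clustered_logistic(obs)
  expect_lt(fit$coef[["value"]], 0)
  expect_false(fit$separation)
  expect_true(all(fit$fitted > 0 & fit$fitted < 1))
  o <- order(obs$value)
  expect_true(all(diff(fit$fitted[o]) <= 1e-12))
  # pure-noise predictor: slope not significant in this single draw
  obs_n <- mk_obs(function(m) runif(m), seed = 9)
  fit_n <- fit_clustered_logistic(obs_n)
  expect_lt(abs(fit_n$z[["value"]]), 2.5)
  # perfect predictor raises the separation flag
  obs_p <- mk_obs(function(m) c(rep(1, m - 1), 0))
  expect_warning(fit_p <- fit_clustered_logistic(obs_p), "separation")
  expect_true(fit_p$separation)
  expect_error(fit_clustered_logistic(obs[obs$subject_id == "c001", ]),
               "clusters")
})

test_that("stage means reproduce the stepwise oracle exactly", {
  co <- tiny_cohort()
  sch <- co$config$schedule
  ser <- do.call(rbind, lapply(co$subjects, oracle_series, schedule = sch))
  class(ser) <- c("reserve_series", "data.frame")
  sm <- stage_means(ser, sch)
  expect_equal(sm$mean[sm$level == 0], 1)          # baseline
  expect_true(all(diff(sm$n) <= 0))                # attrition only
  # per-stage oracle means equal the average stepwise target of subjects
  # still in protocol (direct recomputation)
  for (k in seq_len(nrow(sm))) {
    sel <- ser$time >= sm$t_start[k] & ser$time < sm$t_end[k]
    per <- tapply(ser$value[sel], ser$subject_id[sel], mean)
    expect_equal(sm$mean[k], mean(per, na.rm = TRUE))
    expect_equal(sm$n[k], sum(!is.na(per)))
  }
})

test_that("end-of-stage regression is exact for a single oracle subject", {
  sch <- stage_schedule()
  s <- demo_subject()
  ser <- oracle_series(s, sch)
  eos <- end_of_stage_regression(ser, sch)
  # stepwise oracle is exactly linear in level for one subject
  expect_equal(eos$r2, 1, tolerance = 1e-12)
  expect_lt(eos$slope, 0)
  expect_equal(eos$intercept, 1, tolerance = 1e-9)
  # R^2 invariant to rescaling reserve to percent
  ser_pct <- ser; ser_pct$value <- ser$value * 100
  eos_pct <- end_of_stage_regression(ser_pct, sch)
  expect_equal(eos_pct$r2, eos$r2, tolerance = 1e-12)
  short <- ser[ser$time <= 290, ]
  expect_error(end_of_stage_regression(short, sch), "degenerate")
})

test_that("Steiger Z matches an independently coded oracle", {
  # independent implementation following the published two-step recipe
  steiger_oracle <- function(ra, rb, rab, n) {
    fisher <- function(r) 0.5 * log((1 + r) / (1 - r))  # atanh, by hand
    rbar <- (ra + rb) / 2
    psi <- rab * (1 - rbar^2 - rbar^2) -
      (rbar^2 / 2) * (1 - rbar^2 - rbar^2 - rab^2)
    cov_term <- psi / ((1 - rbar^2) * (1 - rbar^2))
    (fisher(ra) - fisher(rb)) * sqrt((n - 3) / (2 - 2 * cov_term))
  }
  cases <- list(c(.978, .958, .95, 9), c(.9, .5, .3, 20),
                c(-.4, .2, .1, 50), c(.99, .985, .99, 10))
  for (cs in cases) {
    got <- compare_dependent_correlations(cs[1], cs[2], cs[3], cs[4])
    expect_equal(got$z, steiger_oracle(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-6)
  }
  same <- compare_dependent_correlations(.8, .8, .6, 30)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  ab <- compare_dependent_correlations(.9, .6, .5, 30)
  ba <- compare_dependent_correlations(.6, .9, .5, 30)
  expect_equal(ab$z, -ba$z)
  expect_error(compare_dependent_correlations(1, .5, .5, 30), "divergence")
})

test_that("head-to-head evaluation reuses one model across strata", {
  co <- tiny_cohort()
  sch <- co$config$schedule
  ser <- do.call(rbind, lapply(co$subjects, oracle_series, schedule = sch))
  class(ser) <- c("reserve_series", "data.frame")
  ser_b <- ser
  set.seed(1)
  ser_b$value <- pmin(1, pmax(0, ser$value + rnorm(nrow(ser), 0, 0.08)))
  ser_b$source <- "cri_like"
  class(ser_b) <- c("reserve_series", "data.frame")
  rep_ <- suppressWarnings(
    evaluate_head_to_head(ser, ser_b, co$profiles, sch))
  expect_s3_class(rep_, "cr_evaluation")
  # stratified AUCs are computed from subsets of the single model's
  # probabilities: recompute directly
  lab <- do.call(rbind, lapply(split(ser, ser$subject_id), function(s) {
    s <- s[order(s$time), ]
    class(s) <- c("reserve_series", "data.frame")
    label_observations(s)
  }))
  keep_ht <- lab$subject_id %in%
    co$profiles$subject_id[co$profiles$tolerance_class == "HT"]
  if (any(keep_ht) && !is.null(rep_$strata$HT)) {
    direct <- roc_auc(rep_$gee[[1]]$fitted[keep_ht], lab$outcome[keep_ht])
    expect_equal(rep_$strata$HT$auc[[1]]$auc, direct$auc)
  }
  tab <- evaluation_table(rep_)
  expect_true(all(c("estimator", "class", "metric", "value") %in% names(tab)))
  expect_true(all(tab$value[tab$metric == "auc"] >= 0 &
                    tab$value[tab$metric == "auc"] <= 1))
})
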
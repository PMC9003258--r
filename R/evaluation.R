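#' Label reserve estimates for the decompensation regression
#'
#' Every cadence estimate becomes one observation; the final observation of
#' each subject (the one at decompensation) carries outcome 1, all earlier
#' ones 0.
#'
#' @param series A `reserve_series` for one subject.
#' @param subject The matching `subject_profile` (identity check only).
#' @return Data frame with `subject_id`, `time`, `value`, `outcome`.
#' @export
label_observations <- function(series, subject = NULL) {
  stopifnot(inherits(series, "reserve_series"))
  if (nrow(series) == 0) stop("empty series cannot be labeled")
  if (!is.null(subject) &&
      !identical(unique(series$subject_id), subject$subject_id))
    stop("series/subject mismatch")
  data.frame(subject_id = series$subject_id, time = series$time,
             value = series$value,
             outcome = c(rep(0L, nrow(series) - 1), 1L),
             stringsAsFactors = FALSE)
}

#' Clustered logistic regression (GEE, exchangeable working correlation)
#'
#' Marginal logistic model of the decompensation outcome on the reserve
#' value with subjects as clusters and an exchangeable (compound-symmetry)
#' working correlation, fitted by iteratively reweighted GEE updates with a
#' moment estimate of the correlation parameter.  Standard errors are
#' cluster-robust (sandwich).  Complete separation is flagged and resolved
#' by refitting with a small L2 penalty.
#'
#' @param observations Data frame from [label_observations()] (stacked over
#'   subjects): columns `subject_id`, `value`, `outcome`.
#' @param value_col Name of the predictor column (default `"value"`).
#' @param maxit,tol Iteration controls.
#' @return List with `coef` (intercept, slope), `robust_se`, `z`, `p`,
#'   `alpha` (working correlation), `fitted` (probabilities), `separation`,
#'   `converged`.
#' @export
fit_clustered_logistic <- function(observations, value_col = "value",
                                   maxit = 50, tol = 1e-8) {
  y <- observations$outcome
  x <- observations[[value_col]]
  id <- observations$subject_id
  if (length(unique(id)) < 2) stop("need at least 2 clusters")
  if (length(unique(y)) < 2) stop("outcome is constant")
  X <- cbind(`(Intercept)` = 1, value = x)
  fit <- .gee_logit(X, y, id, lambda = 0, maxit = maxit, tol = tol)
  separation <- !fit$converged || max(abs(fit$beta)) > 30 ||
    any(!is.finite(fit$beta))
  if (separation) {
    warning("possible separation: refitting with a small L2 penalty")
    fit <- .gee_logit(X, y, id, lambda = 1e-2 * length(y), maxit = maxit,
                      tol = tol)
  }
  z <- fit$beta / fit$robust_se
  list(coef = fit$beta, robust_se = fit$robust_se, z = z,
       p = 2 * pnorm(-abs(z)), alpha = fit$alpha, fitted = fit$mu,
       separation = separation, converged = fit$converged)
}

.gee_logit <- function(X, y, id, lambda = 0, maxit = 50, tol = 1e-8) {
  p <- ncol(X)
  idx <- split(seq_along(y), id)
  # score and expected information at beta for a fixed working correlation
  score_info <- function(beta, alpha, want_H = TRUE) {
    eta <- pmin(30, pmax(-30, drop(X %*% beta)))
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    U <- rep(0, p); H <- if (want_H) matrix(0, p, p) else NULL
    for (ii in idx) {
      ni <- length(ii)
      Ai <- sqrt(pmax(w[ii], 1e-12))
      Di <- X[ii, , drop = FALSE] * (w[ii])       # dmu/dbeta
      si <- y[ii] - mu[ii]
      # V^{-1} propto A^{-1/2} R^{-1} A^{-1/2}, exchangeable closed form
      g <- alpha / (1 + (ni - 1) * alpha)
      DtA <- t(Di) / rep(Ai, each = p)            # t(D) A^{-1/2}
      sA <- si / Ai
      Rinv_s <- (sA - g * sum(sA)) / (1 - alpha)
      U <- U + drop(DtA %*% Rinv_s)
      if (want_H) {
        Rinv_DA <- (t(DtA) - g * matrix(colSums(t(DtA)), ni, p,
                                        byrow = TRUE)) / (1 - alpha)
        H <- H + DtA %*% Rinv_DA
      }
    }
    if (lambda > 0) {
      U <- U - lambda * beta
      if (want_H) H <- H + diag(lambda, p)
    }
    list(U = U, H = H)
  }
  est_alpha <- function(beta) {
    eta <- pmin(30, pmax(-30, drop(X %*% beta)))
    mu <- plogis(eta)
    r <- (y - mu) / sqrt(pmax(mu * (1 - mu), 1e-12))
    num <- 0; den <- 0
    for (ii in idx) {
      ri <- r[ii]; ni <- length(ri)
      if (ni > 1) {
        num <- num + (sum(ri)^2 - sum(ri^2)) / 2
        den <- den + ni * (ni - 1) / 2
      }
    }
    phi <- sum(r^2) / (length(y) - p)
    # keep the working correlation positive definite: alpha must stay above
    # -1/(n_i - 1) for the largest cluster
    lb <- -0.9 / max(1, max(lengths(idx)) - 1)
    if (den > 0) min(0.99, max(lb, num / (den * phi))) else 0
  }
  beta <- tryCatch(
    suppressWarnings(glm.fit(X, y, family = binomial())$coefficients),
    error = function(e) rep(0, p))
  if (any(!is.finite(beta))) beta <- rep(0, p)
  alpha <- est_alpha(beta)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    si <- score_info(beta, alpha)
    step <- tryCatch(solve(si$H, si$U), error = function(e) rep(NA_real_, p))
    if (any(!is.finite(step))) break
    # step halving on the working-score norm guards against overshoot
    u0 <- sum(si$U^2)
    fac <- 1
    for (h in 1:12) {
      trial <- beta + fac * step
      u1 <- sum(score_info(trial, alpha, want_H = FALSE)$U^2)
      if (u1 < u0 || max(abs(fac * step)) < tol) break
      fac <- fac / 2
    }
    beta_new <- beta + fac * step
    moved <- max(abs(fac * step))
    beta <- beta_new
    alpha <- est_alpha(beta)
    if (moved < tol) { converged <- TRUE; break }
    if (max(abs(beta)) > 50) break
  }
  eta <- pmin(30, pmax(-30, drop(X %*% beta)))
  mu <- plogis(eta)
  w <- mu * (1 - mu)
  # sandwich variance
  B <- matrix(0, p, p); Mmeat <- matrix(0, p, p)
  for (ii in idx) {
    ni <- length(ii)
    Ai <- sqrt(pmax(w[ii], 1e-12))
    Di <- X[ii, , drop = FALSE] * (w[ii])
    si <- y[ii] - mu[ii]
    g <- alpha / (1 + (ni - 1) * alpha)
    DtA <- t(Di) / rep(Ai, each = p)
    sA <- si / Ai
    Rinv_s <- (sA - g * sum(sA)) / (1 - alpha)
    Rinv_DA <- (t(DtA) - g * matrix(colSums(t(DtA)), ni, p,
                                    byrow = TRUE)) / (1 - alpha)
    B <- B + DtA %*% Rinv_DA
    ui <- drop(DtA %*% Rinv_s)
    Mmeat <- Mmeat + tcrossprod(ui)
  }
  if (lambda > 0) B <- B + diag(lambda, p)
  Binv <- tryCatch(solve(B), error = function(e) matrix(NA_real_, p, p))
  V <- Binv %*% Mmeat %*% Binv
  list(beta = setNames(beta, colnames(X)),
       robust_se = sqrt(pmax(diag(V), 0)),
       alpha = alpha, mu = mu, converged = converged)
}

#' ROC AUC with DeLong standard error and confidence interval
#'
#' The AUC equals the Mann-Whitney two-sample statistic (ties count 1/2);
#' the variance follows DeLong's placement decomposition.
#'
#' @param probabilities Scores (higher = more likely event).
#' @param outcomes 0/1 outcomes.
#' @param conf_level Confidence level for the interval.
#' @return List with `auc`, `se`, `ci` (length 2), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(probabilities, outcomes, conf_level = 0.95) {
  stopifnot(length(probabilities) == length(outcomes))
  pos <- probabilities[outcomes == 1]
  neg <- probabilities[outcomes == 0]
  m <- length(pos); n <- length(neg)
  if (m == 0 || n == 0) stop("both outcome classes must be present")
  pl <- .delong_placements(pos, neg)
  auc <- mean(pl$v10)
  se <- sqrt(ifelse(m > 1, var(pl$v10) / m, 0) +
               ifelse(n > 1, var(pl$v01) / n, 0))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * zq * se))
  list(auc = auc, se = se, ci = ci, n_pos = m, n_neg = n)
}

# midrank placements (DeLong, Sun & Xu fast formulation)
.delong_placements <- function(pos, neg) {
  m <- length(pos); n <- length(neg)
  all_ <- c(pos, neg)
  r_all <- rank(all_, ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(v10 = v10, v01 = v01)
}

#' Paired DeLong comparison of two correlated AUCs
#'
#' Both score vectors must refer to the same observations.  The test
#' statistic uses the covariance of the placement components; it is
#' symmetric in the two markers up to sign.
#'
#' @param probs_a,probs_b Scores of the two estimators on identical
#'   observations.
#' @param outcomes 0/1 outcomes.
#' @return List with `auc_a`, `auc_b`, `difference`, `se`, `z`, `p`.
#' @export
compare_auc_paired <- function(probs_a, probs_b, outcomes) {
  stopifnot(length(probs_a) == length(probs_b),
            length(probs_a) == length(outcomes))
  ia <- outcomes == 1
  pa <- .delong_placements(probs_a[ia], probs_a[!ia])
  pb <- .delong_placements(probs_b[ia], probs_b[!ia])
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)
  m <- sum(ia); n <- sum(!ia)
  s10 <- if (m > 1) var(pa$v10 - pb$v10) else 0
  s01 <- if (n > 1) var(pa$v01 - pb$v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  diff <- auc_a - auc_b
  if (se < 1e-12) {
    z <- if (abs(diff) < 1e-12) 0 else sign(diff) * Inf
  } else z <- diff / se
  list(auc_a = auc_a, auc_b = auc_b, difference = diff, se = se, z = z,
       p = if (is.infinite(z)) 0 else 2 * pnorm(-abs(z)))
}

#' Per-stage means of reserve estimates
#'
#' For every protocol stage (baseline = level 0 plus each LBNP level), the
#' estimates of all subjects still in the protocol are averaged: first
#' within subject, then across subjects (on the balanced staged design this
#' equals the least-squares mean).  Standard errors are across subjects.
#'
#' @param series A stacked `reserve_series` (one estimator, many subjects).
#' @param schedule A [stage_schedule()].
#' @return Data frame with `level`, `t_start`, `t_end`, `mean`, `se`, `n`.
#' @export
stage_means <- function(series, schedule) {
  stopifnot(inherits(series, "reserve_series") || is.data.frame(series))
  b <- schedule$baseline_duration
  sd_ <- schedule$stage_duration
  lv <- c(0, schedule$stage_levels)
  t0 <- c(0, b + sd_ * (seq_along(schedule$stage_levels) - 1))
  t1 <- c(b, b + sd_ * seq_along(schedule$stage_levels))
  out <- lapply(seq_along(lv), function(k) {
    sel <- series$time >= t0[k] & series$time < t1[k]
    if (!any(sel)) return(NULL)
    per_subj <- tapply(series$value[sel], series$subject_id[sel], mean)
    per_subj <- per_subj[!is.na(per_subj)]
    data.frame(level = lv[k], t_start = t0[k], t_end = t1[k],
               mean = mean(per_subj),
               se = if (length(per_subj) > 1)
                 sd(per_subj) / sqrt(length(per_subj)) else 0,
               n = length(per_subj))
  })
  do.call(rbind, out)
}

#' End-of-stage ("amalgamated") regression of group means on LBNP level
#'
#' At the last cadence point inside each stage, estimates of the subjects
#' still in protocol are averaged; the group averages are regressed linearly
#' on the stage LBNP magnitude (baseline included as level 0).
#'
#' @param series A stacked `reserve_series`.
#' @param schedule A [stage_schedule()].
#' @param cadence Series cadence, seconds.
#' @return List with `r2`, `slope`, `intercept`, `points` (data frame
#'   `level`, `t_end`, `mean`, `n`), and `r` (signed Pearson correlation).
#' @export
end_of_stage_regression <- function(series, schedule, cadence = 10) {
  b <- schedule$baseline_duration
  sd_ <- schedule$stage_duration
  lv <- c(0, schedule$stage_levels)
  ends <- c(b, b + sd_ * seq_along(schedule$stage_levels))
  t_pt <- floor((ends - 1e-9) / cadence) * cadence  # last grid point in stage
  pts <- lapply(seq_along(lv), function(k) {
    sel <- abs(series$time - t_pt[k]) < 1e-9
    if (!any(sel)) return(NULL)
    data.frame(level = lv[k], t_end = t_pt[k],
               mean = mean(series$value[sel]), n = sum(sel))
  })
  pts <- do.call(rbind, pts)
  if (is.null(pts) || nrow(pts) < 3)
    stop("degenerate regression: fewer than 3 completed stage points")
  fit <- lm(mean ~ level, data = pts)
  r <- suppressWarnings(cor(pts$mean, pts$level))
  list(r2 = suppressWarnings(summary(fit)$r.squared),
       slope = coef(fit)[["level"]],
       intercept = coef(fit)[["(Intercept)"]], points = pts, r = r)
}

#' Steiger's Z test for two dependent correlations sharing a variable
#'
#' Compares `cor(A, X)` with `cor(B, X)` when both are computed on the same
#' n cases (here: the two estimators' stage means against the LBNP level),
#' using Fisher's r-to-z transformation and the Z1* statistic with the
#' mean-correlation plug-in.
#'
#' @param r_a,r_b The two correlations sharing variable X.
#' @param r_ab Correlation between the A and B measurements.
#' @param n Number of cases the correlations are computed on (>= 4).
#' @return List with `z` and two-sided `p`.
#' @export
compare_dependent_correlations <- function(r_a, r_b, r_ab, n) {
  stopifnot(n >= 4)
  if (any(abs(c(r_a, r_b, r_ab)) >= 1))
    stop("transform divergence: correlations must lie strictly inside (-1, 1)")
  z1 <- atanh(r_a); z2 <- atanh(r_b)
  rbar <- (r_a + r_b) / 2
  psi <- r_ab * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_ab^2)
  sbar <- psi / (1 - rbar^2)^2
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * sbar))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Head-to-head evaluation of two reserve estimators
#'
#' Implements the full statistical comparison: clustered logistic regression
#' of decompensation on each estimator (single model over all subjects),
#' ROC AUC with DeLong confidence intervals, paired AUC comparison, per-stage
#' means, end-of-stage regression R-squared, and the dependent-correlation
#' test of the two estimators' stage-mean/LBNP correlations -- each
#' stratified as ALL, HT-only and LT-only.  The stratified AUCs reuse the
#' probabilities of the single overall model; no class-specific refitting
#' occurs.
#'
#' @param series_a,series_b Stacked `reserve_series` of the two estimators
#'   on identical records (e.g. sources `"crm"` and `"cri_like"`).
#' @param profiles Cohort profile data frame (with `tolerance_class`).
#' @param schedule A [stage_schedule()].
#' @return An object of class `cr_evaluation`.
#' @export
evaluate_head_to_head <- function(series_a, series_b, profiles, schedule) {
  stopifnot(all(c("subject_id", "tolerance_class") %in% names(profiles)))
  lab <- function(series) {
    obs <- lapply(split(seq_len(nrow(series)), series$subject_id),
                  function(ii) {
                    s <- series[ii, ]
                    s <- s[order(s$time), ]
                    class(s) <- c("reserve_series", "data.frame")
                    label_observations(s)
                  })
    do.call(rbind, obs)
  }
  obs_a <- lab(series_a); obs_b <- lab(series_b)
  stopifnot(identical(obs_a$subject_id, obs_b$subject_id),
            identical(obs_a$time, obs_b$time))
  gee_a <- fit_clustered_logistic(obs_a)
  gee_b <- fit_clustered_logistic(obs_b)
  cls <- setNames(profiles$tolerance_class, profiles$subject_id)
  strata <- list(ALL = unique(obs_a$subject_id),
                 HT = names(cls)[cls == "HT"],
                 LT = names(cls)[cls == "LT"])
  name_a <- series_a$source[1]; name_b <- series_b$source[1]
  per_class <- lapply(names(strata), function(cl) {
    keep <- obs_a$subject_id %in% strata[[cl]]
    if (!any(keep)) return(NULL)
    y <- obs_a$outcome[keep]
    auc_a <- roc_auc(gee_a$fitted[keep], y)
    auc_b <- roc_auc(gee_b$fitted[keep], y)
    cmp <- compare_auc_paired(gee_a$fitted[keep], gee_b$fitted[keep], y)
    sa <- series_a[series_a$subject_id %in% strata[[cl]], ]
    sb <- series_b[series_b$subject_id %in% strata[[cl]], ]
    sm_a <- stage_means(sa, schedule)
    sm_b <- stage_means(sb, schedule)
    eos_a <- end_of_stage_regression(sa, schedule)
    eos_b <- end_of_stage_regression(sb, schedule)
    common <- merge(eos_a$points[, c("level", "mean")],
                    eos_b$points[, c("level", "mean")], by = "level")
    r_ab <- suppressWarnings(cor(common$mean.x, common$mean.y))
    steiger <- compare_dependent_correlations(eos_a$r, eos_b$r, r_ab,
                                              nrow(common))
    list(class = cl, n_subjects = length(intersect(strata[[cl]],
                                                   unique(obs_a$subject_id))),
         auc = setNames(list(auc_a, auc_b), c(name_a, name_b)),
         auc_comparison = cmp,
         stage_means = setNames(list(sm_a, sm_b), c(name_a, name_b)),
         end_of_stage = setNames(list(eos_a, eos_b), c(name_a, name_b)),
         dependent_correlation = steiger)
  })
  names(per_class) <- names(strata)
  structure(list(estimators = c(name_a, name_b),
                 gee = setNames(list(gee_a, gee_b), c(name_a, name_b)),
                 strata = per_class),
            class = "cr_evaluation")
}

#' @export
print.cr_evaluation <- function(x, ...) {
  cat(sprintf("<cr_evaluation: %s vs %s>\n", x$estimators[1],
              x$estimators[2]))
  for (cl in names(x$strata)) {
    s <- x$strata[[cl]]
    if (is.null(s)) next
    a <- s$auc[[1]]; b <- s$auc[[2]]
    cat(sprintf(
      "  %-3s (n=%d): AUC %s %.4f [%.3f, %.3f] | %s %.4f [%.3f, %.3f] | paired p=%.3g\n",
      cl, s$n_subjects,
      x$estimators[1], a$auc, a$ci[1], a$ci[2],
      x$estimators[2], b$auc, b$ci[1], b$ci[2],
      s$auc_comparison$p))
    cat(sprintf("      end-of-stage R2: %s %.3f | %s %.3f | Steiger p=%.3g\n",
                x$estimators[1], s$end_of_stage[[1]]$r2,
                x$estimators[2], s$end_of_stage[[2]]$r2,
                s$dependent_correlation$p))
  }
  invisible(x)
}

#' Flatten an evaluation report to a tidy metric table
#'
#' @param report A `cr_evaluation`.
#' @return Data frame with `estimator`, `class`, `metric`, `value`, `se`,
#'   `ci_low`, `ci_high`, `p`.
#' @export
evaluation_table <- function(report) {
  stopifnot(inherits(report, "cr_evaluation"))
  rows <- list()
  add <- function(...) rows[[length(rows) + 1]] <<- data.frame(
    ..., stringsAsFactors = FALSE)
  for (cl in names(report$strata)) {
    s <- report$strata[[cl]]
    if (is.null(s)) next
    for (est in names(s$auc)) {
      a <- s$auc[[est]]
      add(estimator = est, class = cl, metric = "auc", value = a$auc,
          se = a$se, ci_low = a$ci[1], ci_high = a$ci[2], p = NA_real_)
      add(estimator = est, class = cl, metric = "end_of_stage_r2",
          value = s$end_of_stage[[est]]$r2, se = NA_real_,
          ci_low = NA_real_, ci_high = NA_real_, p = NA_real_)
    }
    add(estimator = "paired", class = cl, metric = "auc_difference",
        value = s$auc_comparison$difference, se = s$auc_comparison$se,
        ci_low = NA_real_, ci_high = NA_real_, p = s$auc_comparison$p)
    add(estimator = "paired", class = cl, metric = "steiger_z",
        value = s$dependent_correlation$z, se = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_,
        p = s$dependent_correlation$p)
  }
  do.call(rbind, rows)
}
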
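test_that("KM estimator matches closed forms", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))[[1]]
  expect_equal(km$surv, c(2/3, 1/3, 0))
  expect_true(all(diff(km$surv) <= 0))
  cens <- km_estimate(c(1, 2, 3), c(0, 0, 0))[[1]]
  expect_true(all(cens$surv == 1))
  expect_error(km_estimate(1:3, c(1, 1, 1),
                           groups = factor("a", levels = c("a", "b"))[c(1, 1, 1)]),
               "empty group")
})

test_that("KM equals the empirical survivor function without censoring", {
  set.seed(8)
  t <- rexp(200, 0.3)
  km <- km_estimate(t, rep(1, 200))[[1]]
  for (h in c(0.5, 2, 5))
    expect_equal(km_survival_at(km, h), mean(t > h))
})

test_that("log-rank statistic is null on duplicated groups and symmetric", {
  set.seed(2)
  t <- rexp(40, 0.2); e <- rbinom(40, 1, 0.7)
  lr <- logrank_test(c(t, t), c(e, e), rep(c("x", "y"), each = 40))
  expect_lt(lr$chi_square, 1e-10)
  g <- rep(c("a", "b"), 20)
  expect_equal(logrank_test(t, e, g)$chi_square,
               logrank_test(t, e, ifelse(g == "a", "b", "a"))$chi_square)
  expect_error(logrank_test(t, e, rep("a", 40)), "two groups")
})

test_that("log-rank p-values are uniform under label permutation", {
  set.seed(77)
  t <- rexp(60, 0.2); e <- rbinom(60, 1, 0.7)
  ps <- vapply(1:500, function(i) {
    g <- sample(rep(0:1, 30))
    logrank_test(t, e, g)$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("log-rank separates strongly different hazards", {
  ok <- 0
  for (s in 1:20) {
    set.seed(s)
    t <- c(rexp(200, 0.1), rexp(200, 0.3))
    cens <- runif(400, 0, 30)
    lr <- logrank_test(pmin(t, cens), as.integer(t <= cens),
                       rep(c("lo", "hi"), each = 200))
    ok <- ok + (lr$p < 0.001)
  }
  expect_gte(ok, 19)
})

test_that("IPCW AUC without censoring equals the pairwise count exactly", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(10:50, 1)
    t <- rexp(n, 0.3) + 0.01
    sc <- rnorm(n) - 0.5 * t
    h <- stats::median(t)
    if (!any(t <= h) || !any(t > h)) next
    expect_equal(time_dependent_auc(sc, t, rep(1, n), h),
                 auc_nocens_oracle(sc, t, h))
  }
})

test_that("AUC hits its anchors: null scores at 0.5, perfect ranking at 1", {
  set.seed(12)
  t <- rexp(2000, 0.3); sc <- rnorm(2000)
  expect_lt(abs(time_dependent_auc(sc, t, rep(1, 2000), 2) - 0.5), 0.05)
  expect_equal(time_dependent_auc(-t, t, rep(1, 2000), 2), 1)
  expect_error(time_dependent_auc(sc, t, rep(1, 2000), max(t) + 1),
               "follow-up")
})

test_that("C-index matches the exhaustive pairwise oracle on censored data", {
  expect_equal(harrell_cindex(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1)), 1)
  expect_equal(harrell_cindex(c(1, 1, 1), c(1, 2, 3), c(1, 1, 1)), 0.5)
  for (s in 1:30) {
    set.seed(s)
    n <- sample(10:30, 1)
    t <- round(rexp(n, 0.3), 1) # rounding forces some tied times
    e <- rbinom(n, 1, 0.6)
    sc <- sample(rnorm(8), n, replace = TRUE) # and some tied scores
    if (sum(e) == 0) next
    expect_equal(harrell_cindex(sc, t, e), cindex_oracle(sc, t, e))
  }
})

test_that("C-index is rank-invariant and complement-symmetric", {
  set.seed(4)
  t <- rexp(50, 0.2); e <- rbinom(50, 1, 0.7); sc <- rnorm(50)
  ci <- harrell_cindex(sc, t, e)
  expect_equal(harrell_cindex(exp(sc), t, e), ci)
  expect_equal(harrell_cindex(-sc, t, e), 1 - ci)
})

test_that("joint Cox model is gated by the univariate entry rule", {
  set.seed(6)
  n <- 300
  cl <- make_clinical(sprintf("S%03d", 1:n), seed = 6)
  # hazard driven by stage and a synthetic score only
  sc <- rnorm(n)
  lp <- 0.5 * (cl$stage - 1) + 1.0 * sc
  t_ev <- rexp(n, 0.1 * exp(lp))
  cl$os_time <- pmin(t_ev, 15); cl$os_event <- as.integer(t_ev <= 15)
  fit <- multivariate_cox(cl, stats::setNames(sc, cl$sample_id))
  expect_true(all(c("stage", "risk_score") %in% fit$entered))
  multi <- fit$multivariate
  expect_true(all(multi$hr[multi$covariate %in% c("stage", "risk_score")] > 1))
  # single entrant: joint fit must equal the univariate fit
  only <- multivariate_cox(cl, stats::setNames(sc, cl$sample_id),
                           entry_alpha = min(fit$univariate$p))
  expect_identical(nrow(only$multivariate), 1L)
  v <- only$multivariate$covariate[1]
  expect_equal(only$multivariate$coef,
               only$univariate$coef[only$univariate$covariate == v])
  # nothing passes: empty joint table, univariate table intact
  none <- multivariate_cox(cl, stats::setNames(sc, cl$sample_id),
                           entry_alpha = 0)
  expect_identical(nrow(none$multivariate), 0L)
  expect_identical(nrow(none$univariate), 5L)
})

test_that("collinear covariates are named in the singularity error", {
  set.seed(9)
  cl <- make_clinical(sprintf("S%03d", 1:200), seed = 9)
  cl$grade <- cl$stage # perfectly collinear
  lp <- 0.8 * (cl$stage - 1)
  t_ev <- rexp(200, 0.1 * exp(lp))
  cl$os_time <- pmin(t_ev, 15); cl$os_event <- as.integer(t_ev <= 15)
  expect_error(multivariate_cox(cl, rnorm(200) + lp, entry_alpha = 0.05),
               "singular design")
})

test_that("rank-sum score comparison behaves at the null and under shift", {
  set.seed(3)
  sc <- rnorm(50)
  null <- group_score_comparison(c(sc, sc), rep(c("a", "b"), each = 50))
  expect_gt(null$p, 0.9)
  shifted <- group_score_comparison(c(sc, sc + 10),
                                    rep(c("a", "b"), each = 50))
  expect_lt(shifted$p, 0.001)
  expect_error(group_score_comparison(sc, rep("a", 50)), "two")
})

test_that("high-stage samples carry higher pair scores when stage drives risk", {
  ok <- 0
  for (s in 1:10) {
    cfg <- simulation_config(n_samples = 250, n_genes = 30,
                             n_immune_genes = 20, n_true_pairs = 3,
                             true_log_hazard_ratios = rep(0.8, 3),
                             stage_effect_log_hr = 0.5, censoring_rate = 0.3,
                             platform_offsets = 0, platform_scales = 1,
                             seed = 300 + s)
    sim <- simulate_cohorts(cfg)
    cl <- sim$clinical[[1]]
    sc <- sim$truth$linear_predictor[[1]]
    hi <- cl$stage >= 3
    ok <- ok + (stats::median(sc[hi]) > stats::median(sc[!hi]))
  }
  expect_gte(ok, 9)
})
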
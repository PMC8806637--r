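# simulate from a known two-covariate Cox-exponential model
sim_united <- function(n, beta_stage = 0.5, beta_score = 1.0, seed = 1,
                       baseline = 0.12, cens_max = 18) {
  set.seed(seed)
  stage <- sample(1:4, n, replace = TRUE, prob = c(0.5, 0.1, 0.22, 0.18))
  score <- rnorm(n, 0, 0.6)
  lp <- beta_stage * stage + beta_score * score
  t_ev <- rexp(n, baseline * exp(lp - mean(lp)))
  t_c <- runif(n, 0, cens_max)
  list(stage = stage, score = score,
       times = pmin(t_ev, t_c), events = as.integer(t_ev <= t_c))
}

test_that("non-varying covariates are rejected", {
  d <- sim_united(100, seed = 2)
  expect_error(fit_united_model(rep(2, 100), d$score, d$times, d$events),
               "do not vary")
})

test_that("the united Cox fit recovers its generating coefficients", {
  cover_stage <- cover_score <- 0
  for (s in 1:20) {
    d <- sim_united(500, beta_stage = 0.5, beta_score = 1.0, seed = 400 + s)
    m <- fit_united_model(d$stage, d$score, d$times, d$events)
    cf <- summary(m$fit)$coefficients
    ci <- cbind(cf[, "coef"] - 1.96 * cf[, "se(coef)"],
                cf[, "coef"] + 1.96 * cf[, "se(coef)"])
    cover_stage <- cover_stage + (ci[1, 1] <= 0.5 && 0.5 <= ci[1, 2])
    cover_score <- cover_score + (ci[2, 1] <= 1.0 && 1.0 <= ci[2, 2])
  }
  expect_gte(cover_stage, 17)
  expect_gte(cover_score, 17)
})

test_that("points are affine, non-negative, and span [0,100] on the widest
           covariate", {
  d <- sim_united(400, seed = 5)
  m <- fit_united_model(d$stage, d$score, d$times, d$events)
  expect_equal(max(m$points$max_points), 100)
  pts <- nomogram_points(m, d$stage, d$score)
  expect_true(all(pts$stage_points >= -1e-9))
  expect_true(all(pts$score_points >= -1e-9))
  # affine in each covariate: equal steps in stage give equal point steps
  p123 <- nomogram_points(m, 1:3, rep(0, 3))$stage_points
  expect_equal(diff(p123)[1], diff(p123)[2])
})

test_that("nomogram survival lookup equals the direct Cox computation", {
  d <- sim_united(300, seed = 7)
  m <- fit_united_model(d$stage, d$score, d$times, d$events)
  new <- data.frame(stage = c(1, 3), risk_score = c(-0.5, 0.7))
  sf <- survival::survfit(m$fit, newdata = new)
  for (h in c(1, 3, 5)) {
    ours <- predict_united_survival(m, new$stage, new$risk_score, h)[, 1]
    ref <- summary(sf, times = h)$surv
    expect_equal(ours, as.numeric(ref), tolerance = 1e-6)
  }
})

test_that("predicted survival at mean covariates tracks the cohort KM", {
  d <- sim_united(2000, seed = 9)
  m <- fit_united_model(d$stage, d$score, d$times, d$events)
  km <- km_estimate(d$times, d$events)[[1]]
  for (h in c(1, 3, 5)) {
    pred <- predict_united_survival(m, mean(d$stage), mean(d$score), h)[1, 1]
    expect_lt(abs(pred - km_survival_at(km, h)), 0.05)
  }
})

test_that("united stratification is rank-based and separates true effects", {
  d <- sim_united(300, seed = 11)
  m <- fit_united_model(d$stage, d$score, d$times, d$events)
  pr <- united_risk_stratify(m, d$stage, d$score)
  # grouping depends only on score ranks
  lp <- united_linear_predictor(m, d$stage, d$score)
  pr2 <- median_stratify(exp(lp)) # strictly increasing relabelling
  expect_identical(pr$group, pr2$group)
  ok <- 0
  for (s in 1:10) {
    d <- sim_united(400, beta_stage = 0.6, beta_score = 1.2, seed = 500 + s)
    m <- fit_united_model(d$stage, d$score, d$times, d$events)
    pr <- united_risk_stratify(m, d$stage, d$score)
    lr <- logrank_test(d$times, d$events, pr$group)
    ok <- ok + (lr$p < 0.001)
  }
  expect_gte(ok, 9)
})

test_that("united model out-ranks either covariate alone in concordance", {
  wins_stage <- wins_score <- 0
  for (s in 1:10) {
    d <- sim_united(500, beta_stage = 0.5, beta_score = 1.0, seed = 600 + s)
    m <- fit_united_model(d$stage, d$score, d$times, d$events)
    lp <- united_linear_predictor(m, d$stage, d$score)
    c_united <- harrell_cindex(lp, d$times, d$events)
    wins_stage <- wins_stage +
      (c_united > harrell_cindex(d$stage, d$times, d$events))
    wins_score <- wins_score +
      (c_united > harrell_cindex(d$score, d$times, d$events))
  }
  expect_gte(wins_stage, 6)
  expect_gte(wins_score, 6)
})

test_that("calibration bins agree with the KM in a well-specified model", {
  d <- sim_united(1500, seed = 13)
  m <- fit_united_model(d$stage, d$score, d$times, d$events)
  tab <- calibration_table(m, d$stage, d$score, d$times, d$events,
                           horizon = 3)
  expect_identical(nrow(tab), 3L)
  expect_equal(sum(tab$n), 1500L)
  expect_true(all(abs(tab$predicted - tab$observed) < 0.06))
  # single bin reduces to the overall KM
  one <- calibration_table(m, d$stage, d$score, d$times, d$events,
                           horizon = 3, n_bins = 1)
  km <- km_estimate(d$times, d$events)[[1]]
  expect_equal(one$observed, km_survival_at(km, 3))
})

test_that("an exaggerated model shows directional miscalibration", {
  d <- sim_united(800, seed = 15)
  m <- fit_united_model(d$stage, d$score, d$times, d$events)
  m$coefficients <- m$coefficients * 2 # deliberately over-confident
  tab <- calibration_table(m, d$stage, d$score, d$times, d$events,
                           horizon = 3)
  low <- tab[which.min(tab$predicted), ]
  expect_lt(low$predicted, low$observed)
})
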
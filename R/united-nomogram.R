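#' Fit the united clinical-stage + risk-score Cox model
#'
#' Two-covariate Cox proportional-hazards fit (Efron ties) of overall
#' survival on ordinal clinical stage (1-4) and the continuous gene-pair
#' risk score, with the Breslow baseline cumulative hazard. The model is
#' re-expressed as a nomogram: each covariate's contribution
#' beta_i * (x - ref_i) is mapped to points on a 0-100 scale anchored so
#' the widest-range covariate spans exactly [0, 100]; predicted survival is
#' S0(t)^exp(linear predictor).
#'
#' @param stage integer stage 1-4 per subject.
#' @param scores numeric risk scores per subject.
#' @param times,events survival outcome per subject.
#' @return A list of class `nomogram_model`: `coefficients`, `basehaz`
#'   (time grid + cumulative hazard, covariates at zero), `points`
#'   (per-covariate reference value and points-per-unit), and the training
#'   covariate ranges.
#' @export
fit_united_model <- function(stage, scores, times, events) {
  check_surv(times, events)
  stopifnot(length(stage) == length(times), length(scores) == length(times))
  df <- data.frame(stage = as.numeric(stage), risk_score = as.numeric(scores))
  nonvar <- names(df)[vapply(df, function(x) length(unique(x)) < 2L,
                             logical(1))]
  if (length(nonvar))
    stop("covariate(s) do not vary: ", paste(nonvar, collapse = ", "))
  fit <- survival::coxph(
    survival::Surv(times, events) ~ stage + risk_score,
    data = df, ties = "efron")
  beta <- stats::coef(fit)
  bh <- survival::basehaz(fit, centered = FALSE)
  # points: contribution beta*x shifted to start at 0 over the training
  # range; one point-unit = widest covariate range / 100
  contrib <- vapply(names(beta),
                    function(v) range(beta[[v]] * df[[v]]), numeric(2))
  widest <- max(contrib[2L, ] - contrib[1L, ])
  if (widest <= 0) stop("degenerate covariate contributions")
  points <- data.frame(
    covariate = names(beta),
    beta = as.numeric(beta),
    ref = contrib[1L, ] / as.numeric(beta),   # value where points = 0
    points_per_unit = 100 * as.numeric(beta) / widest,
    max_points = 100 * (contrib[2L, ] - contrib[1L, ]) / widest,
    stringsAsFactors = FALSE)
  rownames(points) <- NULL
  structure(list(coefficients = beta,
                 basehaz = data.frame(time = bh$time, hazard = bh$hazard),
                 points = points,
                 fit = fit,
                 ranges = lapply(df, range)),
            class = "nomogram_model")
}

#' @export
print.nomogram_model <- function(x, ...) {
  cat("nomogram_model (Cox: stage + risk_score)\n")
  print(x$points, ...)
  invisible(x)
}

#' Linear predictor of the united model
#'
#' @param model a `nomogram_model`.
#' @param stage,scores covariate values.
#' @return Numeric vector beta_stage * stage + beta_score * score
#'   (uncentred, matching the stored baseline hazard).
#' @export
united_linear_predictor <- function(model, stage, scores) {
  stopifnot(inherits(model, "nomogram_model"))
  as.numeric(model$coefficients["stage"] * as.numeric(stage) +
               model$coefficients["risk_score"] * as.numeric(scores))
}

#' Nomogram points for covariate values
#'
#' @param model a `nomogram_model`.
#' @param stage,scores covariate values.
#' @return data.frame with per-covariate points and their total. Points are
#'   affine in each covariate and non-negative over the training range;
#'   validation samples outside that range may exceed the nominal maximum.
#' @export
nomogram_points <- function(model, stage, scores) {
  stopifnot(inherits(model, "nomogram_model"))
  p <- model$points
  pt <- function(v, x) {
    row <- p[p$covariate == v, ]
    row$points_per_unit * (as.numeric(x) - row$ref)
  }
  stage_pts <- pt("stage", stage)
  score_pts <- pt("risk_score", scores)
  data.frame(stage_points = stage_pts, score_points = score_pts,
             total_points = stage_pts + score_pts)
}

#' Predicted survival from the united model
#'
#' S(t | x) = S0(t)^exp(beta' x) with the Breslow baseline.
#'
#' @param model a `nomogram_model`.
#' @param stage,scores covariate values.
#' @param horizon evaluation time(s).
#' @return Matrix of survival probabilities, subjects x horizons.
#' @export
predict_united_survival <- function(model, stage, scores, horizon) {
  stopifnot(inherits(model, "nomogram_model"))
  lp <- united_linear_predictor(model, stage, scores)
  H0 <- step_lookup0(model$basehaz$time, model$basehaz$hazard, horizon)
  out <- outer(exp(lp), H0, function(r, h) exp(-h * r))
  colnames(out) <- as.character(horizon)
  out
}

#' Median stratification on the united linear predictor
#'
#' Scores each sample with the united model's linear predictor and splits
#' at the cohort's own median (high iff strictly above), mirroring the
#' per-cohort median rule used for the gene-pair score alone.
#'
#' @param model a `nomogram_model`.
#' @param stage,scores covariate values.
#' @param sample_ids optional sample identifiers.
#' @param cutoff stratification cutoff; defaults to the cohort median.
#' @return A `risk_profile` (see [median_stratify()]).
#' @export
united_risk_stratify <- function(model, stage, scores, sample_ids = NULL,
                                 cutoff = NULL) {
  lp <- united_linear_predictor(model, stage, scores)
  if (!is.null(sample_ids)) names(lp) <- sample_ids
  if (is.null(cutoff)) cutoff <- stats::median(lp)
  median_stratify(lp, cutoff = cutoff)
}

#' Calibration of predicted vs observed survival
#'
#' Bins subjects by predicted survival at the horizon (quantile bins,
#' tertiles by default), and compares each bin's mean predicted survival
#' with its Kaplan-Meier observed survival at the horizon. Bins whose KM
#' curve cannot reach the horizon (no at-risk subjects and no event by
#' then) are flagged rather than silently dropped.
#'
#' @param model a `nomogram_model`.
#' @param stage,scores,times,events cohort data.
#' @param horizon evaluation time.
#' @param n_bins number of quantile bins (default 3).
#' @return data.frame of class `calibration_table`: bin, n, predicted
#'   (mean), observed (KM), flagged.
#' @export
calibration_table <- function(model, stage, scores, times, events,
                              horizon, n_bins = 3) {
  check_surv(times, events)
  if (horizon >= max(times))
    stop("horizon ", horizon, " is beyond the observed follow-up")
  pred <- predict_united_survival(model, stage, scores, horizon)[, 1L]
  qs <- stats::quantile(pred, probs = seq(0, 1, length.out = n_bins + 1L))
  qs[1L] <- -Inf; qs[length(qs)] <- Inf
  bin <- cut(pred, breaks = unique(qs), labels = FALSE,
             include.lowest = TRUE)
  rows <- lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    km <- km_estimate(times[sel], events[sel])[[1L]]
    at_risk_past <- any(times[sel] >= horizon)
    obs <- km_survival_at(km, horizon)
    data.frame(bin = b, n = sum(sel),
               predicted = mean(pred[sel]),
               observed = obs,
               flagged = !at_risk_past)
  })
  out <- do.call(rbind, rows)
  attr(out, "horizon") <- horizon
  class(out) <- c("calibration_table", "data.frame")
  out
}

# step lookup with value 0 before the first time point (cumulative hazard)
step_lookup0 <- function(time, value, at) {
  idx <- findInterval(at, time)
  ifelse(idx == 0, 0, value[pmax(idx, 1L)])
}
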
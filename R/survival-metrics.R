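#' Kaplan-Meier estimate per group
#'
#' Product-limit estimator of overall survival, one curve per group.
#'
#' @param times non-negative follow-up times.
#' @param events 0/1 event indicators (1 = death).
#' @param groups group labels, one per subject; `NULL` for a single curve.
#' @return A list of `km_estimate` objects, one per group, each with
#'   `time`, `surv`, `n_risk`, `n_event` and `group`.
#' @export
km_estimate <- function(times, events, groups = NULL) {
  check_surv(times, events)
  if (is.null(groups)) groups <- rep("all", length(times))
  if (length(groups) != length(times))
    stop("groups must match times in length")
  tab <- table(groups)
  if (any(tab == 0L)) stop("empty group in Kaplan-Meier input")
  out <- lapply(names(tab), function(g) {
    sel <- groups == g
    fit <- survival::survfit(
      survival::Surv(times[sel], events[sel]) ~ 1)
    structure(list(time = fit$time, surv = fit$surv,
                   n_risk = fit$n.risk, n_event = fit$n.event,
                   group = g),
              class = "km_estimate")
  })
  names(out) <- names(tab)
  out
}

#' Evaluate a KM curve at arbitrary times
#'
#' Right-continuous step-function lookup; S(t) = 1 before the first event.
#'
#' @param km a `km_estimate`.
#' @param at numeric vector of times.
#' @return Survival probabilities at `at`.
#' @export
km_survival_at <- function(km, at) {
  stopifnot(inherits(km, "km_estimate"))
  step_lookup(km$time, km$surv, at)
}

#' Two-group (or k-group) log-rank test
#'
#' @param times,events as in [km_estimate()].
#' @param groups group labels; at least two distinct groups required.
#' @return List with `chi_square`, `df` and `p`.
#' @export
logrank_test <- function(times, events, groups) {
  check_surv(times, events)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L)
    stop("log-rank test needs at least two groups")
  fit <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(fit$n) - 1L
  list(chi_square = unname(fit$chisq), df = df,
       p = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Time-dependent cumulative/dynamic AUC
#'
#' AUC of the risk score at a survival horizon: cases are subjects with an
#' observed event by the horizon, controls are subjects still event-free
#' beyond it. Censoring is handled by inverse-probability-of-censoring
#' weighting (IPCW): cases are weighted by 1/G(T-), controls by
#' 1/G(horizon), with G the Kaplan-Meier estimate of the censoring
#' distribution. Score ties between a case and a control count 1/2.
#' Without censoring the estimator reduces exactly to the empirical
#' probability that a random case out-scores a random control.
#'
#' @param scores numeric risk scores (higher = higher risk).
#' @param times,events as in [km_estimate()].
#' @param horizon evaluation time, within observed follow-up.
#' @return The AUC (scalar in \[0,1\]).
#' @export
time_dependent_auc <- function(scores, times, events, horizon) {
  check_surv(times, events)
  stopifnot(length(scores) == length(times), horizon > 0)
  if (horizon >= max(times))
    stop("horizon ", horizon, " is beyond the observed follow-up")
  is_case <- times <= horizon & events == 1
  is_ctrl <- times > horizon
  if (!any(is_case)) stop("no cases (events by the horizon)")
  if (!any(is_ctrl)) stop("no controls (subjects past the horizon)")
  # KM of the censoring distribution, left-continuous at case times
  gfit <- survival::survfit(survival::Surv(times, 1 - events) ~ 1)
  g_at <- function(t) step_lookup(gfit$time, gfit$surv, t)
  eps <- min(diff(sort(unique(c(0, times))))) / 2
  w_case <- 1 / g_at(times[is_case] - eps)
  w_ctrl <- rep(1 / g_at(horizon), sum(is_ctrl))
  sc <- scores[is_case]
  st <- scores[is_ctrl]
  cmp <- outer(sc, st, ">") + 0.5 * outer(sc, st, "==")
  num <- as.numeric(w_case %*% cmp %*% w_ctrl)
  num / (sum(w_case) * sum(w_ctrl))
}

#' Harrell's concordance index
#'
#' Fraction of comparable subject pairs in which the higher-scoring subject
#' fails first. Pairs are comparable when censoring lets their failure order
#' be determined; score ties count 1/2. Computed from the concordance pair
#' counts of the survival package.
#'
#' @param scores numeric risk scores (higher = higher risk).
#' @param times,events as in [km_estimate()].
#' @return The C-index (scalar in \[0,1\]).
#' @export
harrell_cindex <- function(scores, times, events) {
  check_surv(times, events)
  stopifnot(length(scores) == length(times))
  fit <- survival::concordance(
    survival::Surv(times, events) ~ scores, reverse = TRUE)
  cnt <- fit$count
  comparable <- cnt["concordant"] + cnt["discordant"] + cnt["tied.x"]
  if (comparable == 0) stop("no comparable pairs under censoring")
  unname((cnt["concordant"] + 0.5 * cnt["tied.x"]) / comparable)
}

#' Uni- and multivariable Cox models over clinical factors and risk score
#'
#' Fits a univariate Cox model for each of age, gender, grade, stage and
#' risk score, then a joint model over the covariates passing the entry
#' rule (default: univariate Wald p <= 0.001). Stage and grade enter as
#' ordinal numerics 1-4; gender as male vs female.
#'
#' @param clinical clinical table (one row per subject).
#' @param scores risk scores named by `sample_id` (or aligned by position).
#' @param entry_alpha univariate p-value bound for entry to the joint model.
#' @return List with `univariate` and `multivariate` coefficient tables
#'   (covariate, coef, hr, se, z, p, lower95, upper95) and `entered`, the
#'   covariates that passed the entry rule. The multivariate table is empty
#'   when nothing passes.
#' @export
multivariate_cox <- function(clinical, scores, entry_alpha = 0.001) {
  clinical <- as_clinical_table(clinical)
  if (!is.null(names(scores))) {
    idx <- match(clinical$sample_id, names(scores))
    if (anyNA(idx)) stop("scores missing for some samples")
    scores <- scores[idx]
  }
  stopifnot(length(scores) == nrow(clinical))
  df <- data.frame(
    age = clinical$age,
    gender = as.integer(clinical$gender == "male"),
    grade = clinical$grade,
    stage = clinical$stage,
    risk_score = as.numeric(scores))
  if (sum(clinical$os_event) < ncol(df))
    stop("fewer events than covariates")
  y <- survival::Surv(clinical$os_time, clinical$os_event)
  uni <- do.call(rbind, lapply(names(df), function(v) {
    fit <- survival::coxph(y ~ x, data = data.frame(x = df[[v]]))
    cox_row(fit, v)
  }))
  rownames(uni) <- NULL
  entered <- uni$covariate[uni$p <= entry_alpha]
  multi <- uni[0, ]
  if (length(entered)) {
    xm <- as.matrix(df[, entered, drop = FALSE])
    qr_rank <- qr(cbind(1, xm))$rank
    if (qr_rank < ncol(xm) + 1L)
      stop("singular design among covariates: ",
           paste(entered, collapse = ", "))
    fit <- survival::coxph(y ~ xm)
    multi <- do.call(rbind, lapply(seq_along(entered), function(i)
      cox_row(fit, entered[i], i)))
    rownames(multi) <- NULL
  }
  list(univariate = uni, multivariate = multi, entered = entered)
}

#' Rank-sum comparison of scores between two clinical groups
#'
#' Wilcoxon rank-sum test of risk scores between two groups (e.g. stage 1-2
#' vs stage 3-4, or grade 1-2 vs 3-4).
#'
#' @param scores numeric risk scores.
#' @param group logical or two-level vector splitting the subjects.
#' @return List with `statistic` (rank-sum W) and `p`.
#' @export
group_score_comparison <- function(scores, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L)
    stop("group must have exactly two non-empty levels")
  wt <- stats::wilcox.test(scores ~ group, exact = FALSE)
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Full evaluation report for a risk profile
#'
#' Bundles the standard validation battery: high-vs-low log-rank test,
#' time-dependent AUC at the requested horizons, Harrell's C-index, and
#' uni/multivariable Cox tables over clinical factors plus the score.
#'
#' @param profile a `risk_profile` from [median_stratify()].
#' @param clinical clinical table covering the profiled samples.
#' @param horizons evaluation horizons in the cohort's time unit
#'   (default `c(1, 3, 5)` years).
#' @param entry_alpha passed to [multivariate_cox()].
#' @return List of class `evaluation_report`.
#' @export
evaluate_risk_model <- function(profile, clinical, horizons = c(1, 3, 5),
                                entry_alpha = 0.001) {
  stopifnot(inherits(profile, "risk_profile"))
  clinical <- align_clinical(clinical, profile$sample_id)
  t <- clinical$os_time; e <- clinical$os_event
  lr <- logrank_test(t, e, profile$group)
  auc <- vapply(horizons, function(h)
    time_dependent_auc(profile$risk_score, t, e, h), numeric(1))
  names(auc) <- paste0("auc_", horizons)
  structure(list(
    logrank = lr,
    auc = auc,
    cindex = harrell_cindex(profile$risk_score, t, e),
    cox = multivariate_cox(clinical, stats::setNames(profile$risk_score,
                                                     profile$sample_id),
                           entry_alpha = entry_alpha),
    horizons = horizons),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report\n")
  cat(sprintf("  log-rank: chi2 = %.3f, p = %.3g\n",
              x$logrank$chi_square, x$logrank$p))
  cat("  AUC:", paste(sprintf("%s = %.3f", names(x$auc), x$auc),
                      collapse = ", "), "\n")
  cat(sprintf("  C-index: %.4f\n", x$cindex))
  invisible(x)
}

# ---- internals ----

check_surv <- function(times, events) {
  if (length(times) != length(events))
    stop("times and events differ in length")
  if (any(times < 0)) stop("negative survival times")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  invisible(TRUE)
}

# Right-continuous step lookup of (time, value) pairs; value 1 before the
# first time point.
step_lookup <- function(time, value, at) {
  idx <- findInterval(at, time)
  out <- ifelse(idx == 0, 1, value[pmax(idx, 1L)])
  as.numeric(out)
}

cox_row <- function(fit, name, i = 1L) {
  s <- summary(fit)
  data.frame(covariate = name,
             coef = unname(s$coefficients[i, "coef"]),
             hr = unname(s$coefficients[i, "exp(coef)"]),
             se = unname(s$coefficients[i, "se(coef)"]),
             z = unname(s$coefficients[i, "z"]),
             p = unname(s$coefficients[i, "Pr(>|z|)"]),
             lower95 = unname(s$conf.int[i, "lower .95"]),
             upper95 = unname(s$conf.int[i, "upper .95"]),
             stringsAsFactors = FALSE)
}
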
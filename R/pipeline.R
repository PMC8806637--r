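#' End-to-end pipeline configuration
#'
#' Collects every threshold of the gene-pair workflow in one place, with
#' the study defaults: MAD > 0.5 gene filter, 80% pair-prevalence bound,
#' univariate screen at p < 0.001, multivariate entry at p <= 0.001,
#' nomogram entry at p < 0.05, LASSO iteration cap 10,000 with 10-fold CV,
#' 7:3 training split, and 1/3/5-year evaluation horizons.
#'
#' @param simulation a [simulation_config()] describing the synthetic
#'   input cohorts.
#' @param mad_threshold,prevalence_bound see [filter_config()].
#' @param screen_alpha univariate pair-screen p-value threshold.
#' @param multivariate_entry_alpha entry rule for the joint clinical model.
#' @param nomogram_entry_alpha significance bound recorded for nomogram
#'   covariates.
#' @param lasso_max_iter,cv_folds LASSO-Cox optimiser cap and CV folds.
#' @param split_threshold training-assignment cutoff (7:3 default).
#' @param horizons AUC evaluation horizons, years, ascending.
#' @param split_seed,cv_seed seeds for the cohort split and CV folds.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            mad_threshold = 0.5,
                            prevalence_bound = 0.8,
                            screen_alpha = 0.001,
                            multivariate_entry_alpha = 0.001,
                            nomogram_entry_alpha = 0.05,
                            lasso_max_iter = 10000,
                            cv_folds = 10,
                            split_threshold = 0.7,
                            horizons = c(1, 3, 5),
                            split_seed = 101L,
                            cv_seed = 202L) {
  stopifnot(inherits(simulation, "simulation_config"),
            screen_alpha > 0, screen_alpha < 1,
            split_threshold >= 0, split_threshold <= 1,
            all(diff(horizons) > 0), all(horizons > 0))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full gene-pair prognostic workflow
#'
#' Simulate -> harmonise scales -> drop incomplete records -> MAD filter
#' per platform -> pair indicators -> prevalence filter -> cross-platform
#' intersection -> 7:3 split of platform 1 -> univariate Cox screen ->
#' LASSO-Cox signature -> risk scores and per-cohort median stratification
#' -> KM/log-rank, 1/3/5-year AUC, C-index, uni/multivariable Cox -> united
#' stage+score nomogram with calibration. Returns a manifest recording the
#' resolved configuration, seeds, and the funnel of record counts at every
#' stage, so a re-run with the same seeds is bit-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, the signature, risk
#'   profiles and manifest funnel are written there and their md5 digests
#'   recorded in the manifest.
#' @return A list of class `run_manifest`: `config`, `funnel` (named
#'   counts), `signature`, `profiles`, `evaluations`, `nomogram`,
#'   `calibration`, and `digests` (when `out_dir` is given).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  fc <- filter_config(mad_threshold = config$mad_threshold,
                      prevalence_bound = config$prevalence_bound)
  log_stage <- function(...) message(sprintf(...))

  log_stage("stage simulate: %d platform(s)",
            length(config$simulation$n_samples))
  sim <- simulate_cohorts(config$simulation)
  immune <- grep("^IMM", gene_ids(sim$cohorts[[1L]]), value = TRUE)

  cohorts <- lapply(sim$cohorts, function(co)
    if (co$log_scale) co else log2_transform(co))
  clean <- Map(drop_incomplete, sim$clinical, cohorts)
  cohorts <- lapply(clean, `[[`, "cohort")
  clinical <- lapply(clean, `[[`, "clinical")

  genes_per_platform <- lapply(cohorts, mad_filter, immune_genes = immune,
                               config = fc)
  genes <- sort(Reduce(intersect, genes_per_platform))
  if (length(genes) < 2L) stop("stage mad_filter: fewer than 2 genes shared")
  log_stage("stage mad_filter: %d immune genes retained on all platforms",
            length(genes))

  raw_pairs <- lapply(cohorts, build_pairs, genes = genes)
  n_pairs_built <- nrow(raw_pairs[[1L]]$values)
  filtered <- lapply(raw_pairs, prevalence_filter, config = fc)
  candidates <- intersect_pairs(filtered)
  cand_ids <- paste(candidates$gene_a, candidates$gene_b, sep = "|")
  log_stage("stage pairs: %d built, %d candidates after prevalence+intersection",
            n_pairs_built, length(cand_ids))

  split <- split_cohort(sample_ids(cohorts[[1L]]), seed = config$split_seed,
                        threshold = config$split_threshold)
  pm <- lapply(raw_pairs, subset_pairs, pair_ids = cand_ids)
  cohort_pm <- list(
    training = subset_samples(pm[[1L]], split$training),
    validation1 = subset_samples(pm[[1L]], split$validation))
  cohort_cl <- list(
    training = clinical[[1L]][clinical[[1L]]$sample_id %in% split$training, ],
    validation1 = clinical[[1L]][clinical[[1L]]$sample_id %in% split$validation, ])
  if (length(pm) > 1L) {
    for (p in 2:length(pm)) {
      nm <- sprintf("validation%d", p)
      cohort_pm[[nm]] <- pm[[p]]
      cohort_cl[[nm]] <- clinical[[p]]
    }
  }

  screen <- univariate_cox_screen(cohort_pm$training, cohort_cl$training,
                                  alpha = config$screen_alpha)
  if (!length(screen$retained))
    stop("stage screen: no pairs pass p < ", config$screen_alpha)
  log_stage("stage screen: %d of %d pairs at p < %g",
            length(screen$retained), nrow(screen$table), config$screen_alpha)

  sig <- lasso_cox_select(subset_pairs(cohort_pm$training, screen$retained),
                          cohort_cl$training,
                          max_iter = config$lasso_max_iter,
                          nfolds = config$cv_folds, seed = config$cv_seed)
  log_stage("stage lasso: signature of %d pairs", nrow(sig))

  profiles <- Map(function(m, cl) {
    median_stratify(risk_score(m, sig))
  }, cohort_pm, cohort_cl)

  max_h <- function(cl) config$horizons[config$horizons < max(cl$os_time)]
  evaluations <- Map(function(pr, cl) {
    evaluate_risk_model(pr, cl, horizons = max_h(cl),
                        entry_alpha = config$multivariate_entry_alpha)
  }, profiles, cohort_cl)

  tr_cl <- align_clinical(cohort_cl$training, profiles$training$sample_id)
  nomo <- fit_united_model(tr_cl$stage, profiles$training$risk_score,
                           tr_cl$os_time, tr_cl$os_event)
  united <- Map(function(pr, cl) {
    cl <- align_clinical(cl, pr$sample_id)
    united_risk_stratify(nomo, cl$stage, pr$risk_score, pr$sample_id)
  }, profiles, cohort_cl)
  calib <- lapply(max_h(tr_cl), function(h)
    calibration_table(nomo, tr_cl$stage, profiles$training$risk_score,
                      tr_cl$os_time, tr_cl$os_event, horizon = h))
  united_cindex <- Map(function(up, cl) {
    cl <- align_clinical(cl, up$sample_id)
    harrell_cindex(up$risk_score, cl$os_time, cl$os_event)
  }, united, cohort_cl)

  funnel <- c(immune_genes = length(immune),
              genes_retained = length(genes),
              pairs_built = n_pairs_built,
              pairs_candidate = length(cand_ids),
              pairs_screened = length(screen$retained),
              signature_size = nrow(sig))
  manifest <- structure(list(
    config = config,
    seeds = c(simulation = config$simulation$seed,
              split = config$split_seed, cv = config$cv_seed),
    funnel = funnel,
    signature = sig,
    profiles = profiles,
    evaluations = evaluations,
    nomogram = nomo,
    united_profiles = united,
    united_cindex = united_cindex,
    calibration = calib),
    class = "run_manifest")

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    sig_path <- file.path(out_dir, "signature.tsv")
    write_signature(sig, sig_path)
    prof_path <- file.path(out_dir, "risk_profiles.tsv")
    prof <- do.call(rbind, Map(function(nm, pr)
      data.frame(cohort = nm, pr, stringsAsFactors = FALSE),
      names(profiles), profiles))
    utils::write.table(prof, prof_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    funnel_path <- file.path(out_dir, "funnel.tsv")
    utils::write.table(data.frame(stage = names(funnel), count = funnel),
                       funnel_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$digests <- tools::md5sum(c(sig_path, prof_path, funnel_path))
  }
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("run_manifest\n  funnel:\n")
  for (nm in names(x$funnel))
    cat(sprintf("    %-16s %d\n", nm, x$funnel[[nm]]))
  invisible(x)
}

#' Restrict a pair matrix to a set of samples
#'
#' @param m a `pair_matrix`.
#' @param ids sample identifiers to keep, in matrix order.
#' @return The restricted `pair_matrix`.
#' @export
subset_samples <- function(m, ids) {
  stopifnot(inherits(m, "pair_matrix"))
  missing <- setdiff(ids, m$sample_ids)
  if (length(missing))
    stop("sample(s) absent from pair matrix: ",
         paste(missing, collapse = ", "))
  keep <- m$sample_ids %in% ids
  pair_matrix(m$values[, keep, drop = FALSE], m$pairs)
}
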
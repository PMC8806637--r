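#' Configuration for the synthetic multi-platform cohort generator
#'
#' Defines the ground-truth regime the simulator emulates: a shared gene
#' universe measured on several platforms with different scales and
#' offsets, an immune-gene subset, a set of "true" prognostic gene pairs
#' whose indicators drive an exponential survival hazard, an ordinal tumour
#' stage with its own hazard effect, and independent uniform censoring
#' tuned to a target rate.
#'
#' Defaults mirror a two-platform renal-cancer regime: ~540 RNA-seq-like
#' samples split 7:3 downstream plus ~100 array-like samples, ~67%
#' censoring (about one third of patients die during follow-up), stage
#' marginals 0.50/0.10/0.22/0.18, and a handful of true pairs with log
#' hazard ratio 0.7 each.
#'
#' @param n_samples integer vector, samples per platform.
#' @param n_genes total genes in the universe.
#' @param n_immune_genes immune-gene subset size (<= n_genes).
#' @param n_true_pairs number of prognostic pairs (needs 2 x this many
#'   distinct immune genes).
#' @param true_log_hazard_ratios per-pair log hazard ratios.
#' @param baseline_hazard events per time unit (years) at indicator zero.
#' @param censoring_rate target fraction censored, in \[0, 1).
#' @param platform_offsets additive shift per platform, log2 scale.
#' @param platform_scales multiplicative factor per platform, log2 scale
#'   (must be positive so the map stays strictly increasing).
#' @param noise_sd per-gene, per-sample Gaussian noise SD on log2 scale.
#' @param stage_effect_log_hr log hazard ratio per stage step above 1.
#' @param stage_probs marginal stage probabilities (length 4).
#' @param seed integer seed; everything downstream is reproducible from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = c(540, 100),
                              n_genes = 200,
                              n_immune_genes = 60,
                              n_true_pairs = 5,
                              true_log_hazard_ratios = rep(0.7, n_true_pairs),
                              baseline_hazard = 0.06,
                              censoring_rate = 0.67,
                              platform_offsets = c(0, 2),
                              platform_scales = c(1, 1.3),
                              noise_sd = 1,
                              stage_effect_log_hr = 0.35,
                              stage_probs = c(0.50, 0.10, 0.22, 0.18),
                              seed = 1L) {
  stopifnot(all(n_samples > 0), n_genes > 0,
            n_immune_genes > 0, n_immune_genes <= n_genes,
            n_true_pairs >= 0,
            length(true_log_hazard_ratios) == n_true_pairs,
            baseline_hazard > 0,
            censoring_rate >= 0, censoring_rate < 1,
            length(platform_offsets) == length(n_samples),
            length(platform_scales) == length(n_samples),
            all(platform_scales > 0),
            noise_sd > 0,
            length(stage_probs) == 4L, all(stage_probs >= 0),
            abs(sum(stage_probs) - 1) < 1e-8)
  if (2L * n_true_pairs > n_immune_genes)
    stop("n_true_pairs = ", n_true_pairs, " needs ", 2L * n_true_pairs,
         " distinct immune genes but only ", n_immune_genes,
         " are available")
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate multi-platform cohorts with known prognostic truth
#'
#' Per platform, draws a genes x samples log2 expression matrix
#' (per-gene lognormal base signal plus Gaussian noise), applies the
#' platform's affine distortion (scale then offset, both on log2 scale — a
#' strictly increasing map, so within-sample gene rankings and hence pair
#' indicators are untouched), and emits platform 1 on log2 scale and all
#' later platforms on linear scale (2^x, exercising the log2 ingestion
#' step). True pairs are formed from disjoint immune genes whose base means
#' are equalised so each indicator is informative (~50% prevalence).
#' Survival times are exponential with rate
#' `baseline_hazard * exp(sum coef_k * indicator_k +
#' stage_effect_log_hr * (stage - 1))`; censoring is independent uniform on
#' \[0, c\] with c solved so the expected censored fraction matches the
#' target.
#'
#' @param config a [simulation_config()].
#' @return List with `cohorts` (list of [expression_cohort()]), `clinical`
#'   (list of clinical data.frames) and `truth` (true pairs, coefficients,
#'   per-platform linear predictors and censoring bound).
#' @export
simulate_cohorts <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(as.integer(config$seed))
  n_plat <- length(config$n_samples)
  genes <- c(sprintf("IMM%04d", seq_len(config$n_immune_genes)),
             sprintf("GENE%04d", seq_len(config$n_genes - config$n_immune_genes)))
  genes <- genes[seq_len(config$n_genes)]
  mu <- stats::rnorm(config$n_genes, mean = 4, sd = 1.5)
  names(mu) <- genes
  # true pairs use disjoint immune genes with equal base means, so the
  # indicator is close to Bernoulli(1/2) and survives the prevalence filter
  true_pairs <- data.frame(gene_a = character(0), gene_b = character(0))
  if (config$n_true_pairs > 0) {
    ga <- genes[seq(1L, by = 2L, length.out = config$n_true_pairs)]
    gb <- genes[seq(2L, by = 2L, length.out = config$n_true_pairs)]
    pair_mu <- stats::rnorm(config$n_true_pairs, mean = 4, sd = 1.5)
    mu[ga] <- pair_mu
    mu[gb] <- pair_mu
    true_pairs <- data.frame(gene_a = ga, gene_b = gb,
                             stringsAsFactors = FALSE)
  }
  cohorts <- vector("list", n_plat)
  clinical <- vector("list", n_plat)
  lps <- vector("list", n_plat)
  cens_bounds <- numeric(n_plat)
  for (p in seq_len(n_plat)) {
    n <- config$n_samples[p]
    sid <- sprintf("P%d_S%04d", p, seq_len(n))
    log_expr <- matrix(mu, config$n_genes, n) +
      matrix(stats::rnorm(config$n_genes * n, sd = config$noise_sd),
             config$n_genes, n)
    dimnames(log_expr) <- list(genes, sid)
    ind <- if (config$n_true_pairs > 0)
      (log_expr[true_pairs$gene_a, , drop = FALSE] >
         log_expr[true_pairs$gene_b, , drop = FALSE]) * 1L
    else matrix(0L, 0L, n)
    stage <- sample(1:4, n, replace = TRUE, prob = config$stage_probs)
    lp <- as.numeric(crossprod(ind, config$true_log_hazard_ratios)) +
      config$stage_effect_log_hr * (stage - 1)
    rate <- config$baseline_hazard * exp(lp)
    t_event <- stats::rexp(n, rate = rate)
    if (config$censoring_rate > 0) {
      cmax <- solve_censoring_bound(rate, config$censoring_rate)
      t_cens <- stats::runif(n, 0, cmax)
    } else {
      cmax <- Inf
      t_cens <- rep(Inf, n)
    }
    cens_bounds[p] <- cmax
    clinical[[p]] <- data.frame(
      sample_id = sid,
      age = round(stats::rnorm(n, 60, 10)),
      gender = sample(c("male", "female"), n, replace = TRUE,
                      prob = c(0.65, 0.35)),
      grade = sample(1:4, n, replace = TRUE,
                     prob = c(0.03, 0.44, 0.39, 0.14)),
      stage = stage,
      os_time = pmin(t_event, t_cens),
      os_event = as.integer(t_event <= t_cens),
      stringsAsFactors = FALSE)
    distorted <- config$platform_scales[p] * log_expr +
      config$platform_offsets[p]
    if (p == 1L) {
      cohorts[[p]] <- expression_cohort(distorted, sprintf("platform%d", p),
                                        log_scale = TRUE)
    } else {
      cohorts[[p]] <- expression_cohort(2^distorted, sprintf("platform%d", p),
                                        log_scale = FALSE)
    }
    lps[[p]] <- stats::setNames(lp, sid)
  }
  truth <- structure(list(
    true_pairs = true_pairs,
    true_coefficients = config$true_log_hazard_ratios,
    linear_predictor = lps,
    censoring_bounds = cens_bounds,
    seed = config$seed),
    class = "simulation_truth")
  list(cohorts = cohorts, clinical = clinical, truth = truth)
}

# Uniform censoring C ~ U(0, c) against exponential T with per-subject
# rates: P(censored) averaged over subjects is mean((1 - exp(-r c))/(r c)).
# Monotone decreasing in c; solve for the target by bisection.
solve_censoring_bound <- function(rates, target) {
  f <- function(cc) mean((1 - exp(-rates * cc)) / (rates * cc)) - target
  lo <- 1e-8; hi <- 1
  while (f(hi) > 0 && hi < 1e12) hi <- hi * 2
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Write simulated cohorts as a round-trippable TSV fixture
#'
#' Writes one expression TSV and one clinical TSV per platform, plus a
#' truth TSV of the true pairs and coefficients. Values are printed with
#' 17 significant digits so that reading them back reproduces the doubles
#' bit-for-bit.
#'
#' @param sim result of [simulate_cohorts()].
#' @param dir_path writable output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_fixture <- function(sim, dir_path) {
  if (!dir.exists(dir_path))
    dir.create(dir_path, recursive = TRUE)
  if (!dir.exists(dir_path)) stop("cannot create directory: ", dir_path)
  paths <- character(0)
  for (p in seq_along(sim$cohorts)) {
    co <- sim$cohorts[[p]]
    ep <- file.path(dir_path, sprintf("expression_platform%d.tsv", p))
    mat <- co$matrix
    df <- data.frame(gene = rownames(mat),
                     matrix(sprintf("%.17g", mat), nrow(mat),
                            dimnames = list(NULL, colnames(mat))),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, ep, sep = "\t", quote = FALSE, row.names = FALSE)
    cp <- file.path(dir_path, sprintf("clinical_platform%d.tsv", p))
    cl <- sim$clinical[[p]]
    cl$os_time <- sprintf("%.17g", cl$os_time)
    utils::write.table(cl, cp, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, stats::setNames(c(ep, cp),
                                      sprintf(c("expression%d", "clinical%d"), p)))
  }
  tp <- file.path(dir_path, "truth_pairs.tsv")
  tr <- sim$truth$true_pairs
  tr$coefficient <- if (nrow(tr)) sprintf("%.17g", sim$truth$true_coefficients)
                    else character(0)
  utils::write.table(tr, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, truth = tp)
  invisible(paths)
}
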
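# Independent oracles and small data builders shared across the suite.

# Harrell's C by exhaustive double loop, written directly from the pairwise
# definition: a pair is comparable when censoring determines who fails
# first; score ties count 1/2. Kept independent of the package's
# implementation path.
cindex_oracle <- function(scores, times, events) {
  n <- length(times)
  conc <- comp <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      first <- 0L # subject known to fail first
      if (times[i] < times[j] && events[i] == 1) first <- i
      else if (times[j] < times[i] && events[j] == 1) first <- j
      else if (times[i] == times[j] && events[i] != events[j])
        first <- if (events[i] == 1) i else j
      if (first == 0L) next
      other <- if (first == i) j else i
      comp <- comp + 1
      if (scores[first] > scores[other]) conc <- conc + 1
      else if (scores[first] == scores[other]) conc <- conc + 0.5
    }
  }
  conc / comp
}

# Cumulative/dynamic AUC without censoring: empirical probability that a
# random case (event by horizon) out-scores a random control (past it).
auc_nocens_oracle <- function(scores, times, horizon) {
  case <- which(times <= horizon)
  ctrl <- which(times > horizon)
  tot <- 0
  for (i in case) for (j in ctrl)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(case) * length(ctrl))
}

# Small random expression cohort on log2 scale.
make_cohort <- function(n_genes = 10, n_samples = 30, seed = 1,
                        platform = "test", prefix = "G") {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, mean = 5, sd = 2),
              n_genes, n_samples,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(n_genes)),
                              sprintf("S%03d", seq_len(n_samples))))
  expression_cohort(m, platform = platform, log_scale = TRUE)
}

# Clinical table with exponential survival driven by a given linear
# predictor (zero by default) and uniform censoring.
make_clinical <- function(sample_ids, seed = 1, lp = 0, baseline = 0.1,
                          cens_max = Inf) {
  set.seed(seed)
  n <- length(sample_ids)
  t_event <- rexp(n, rate = baseline * exp(rep_len(lp, n)))
  t_cens <- if (is.finite(cens_max)) runif(n, 0, cens_max) else rep(Inf, n)
  data.frame(sample_id = sample_ids,
             age = round(rnorm(n, 60, 10)),
             gender = sample(c("male", "female"), n, replace = TRUE),
             grade = sample(1:4, n, replace = TRUE),
             stage = sample(1:4, n, replace = TRUE),
             os_time = pmin(t_event, t_cens),
             os_event = as.integer(t_event <= t_cens),
             stringsAsFactors = FALSE)
}

# A random strictly increasing per-sample transform (affine with positive
# slope, exp, or rank), applied to one sample's expression column.
random_monotone_transform <- function(seed) {
  set.seed(seed)
  kind <- sample(c("affine", "exp", "rank"), 1L)
  a <- runif(1, 0.2, 5); b <- runif(1, -10, 10)
  switch(kind,
         affine = function(x) a * x + b,
         exp = function(x) exp(x / 10),
         rank = function(x) rank(x, ties.method = "average"))
}

apply_monotone <- function(cohort, seed) {
  m <- cohort$matrix
  for (s in seq_len(ncol(m))) {
    f <- random_monotone_transform(seed * 1000L + s)
    m[, s] <- f(m[, s])
  }
  expression_cohort(m, cohort$platform, cohort$log_scale)
}

# Pair matrix of k "true" informative pairs plus nulls, with survival whose
# hazard is driven by the true-pair indicators (optionally plus an ordinal
# stage effect); used for screen/LASSO recovery checks.
make_pair_survival <- function(n = 400, n_true = 5, n_null = 95,
                               log_hr = 0.7, seed = 1, baseline = 0.1,
                               cens_max = 12, stage_effect = 0) {
  set.seed(seed)
  total <- n_true + n_null
  vals <- matrix(rbinom(total * n, 1L, 0.5), total, n)
  storage.mode(vals) <- "integer"
  ga <- sprintf("A%03d", seq_len(total))
  gb <- sprintf("B%03d", seq_len(total))
  rownames(vals) <- paste(ga, gb, sep = "|")
  colnames(vals) <- sprintf("S%04d", seq_len(n))
  m <- pair_matrix(vals, data.frame(gene_a = ga, gene_b = gb,
                                    stringsAsFactors = FALSE))
  stage <- sample(1:4, n, replace = TRUE, prob = c(0.5, 0.1, 0.22, 0.18))
  lp <- if (n_true > 0)
    as.numeric(crossprod(vals[seq_len(n_true), , drop = FALSE],
                         rep(log_hr, n_true))) else rep(0, n)
  lp <- lp + stage_effect * (stage - 1)
  t_event <- rexp(n, rate = baseline * exp(lp))
  t_cens <- if (is.finite(cens_max)) runif(n, 0, cens_max) else rep(Inf, n)
  cl <- data.frame(sample_id = colnames(vals),
                   age = round(rnorm(n, 60, 10)),
                   gender = sample(c("male", "female"), n, replace = TRUE),
                   grade = sample(1:4, n, replace = TRUE),
                   stage = stage,
                   os_time = pmin(t_event, t_cens),
                   os_event = as.integer(t_event <= t_cens),
                   stringsAsFactors = FALSE)
  list(pairs = m, clinical = cl,
       true_ids = rownames(vals)[seq_len(n_true)], lp = lp)
}
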
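#' Construct a gene-pair signature
#'
#' A signature is an ordered set of oriented gene pairs with coefficients:
#' the risk score of a sample is the sum over pairs of
#' coefficient x indicator(gene_a > gene_b). Orientation is stored as given
#' (it is part of the published signature), not re-canonicalised.
#'
#' @param gene_a,gene_b character vectors of gene symbols, first and second
#'   member of each pair.
#' @param coefficient numeric vector of pair weights; finite and non-zero.
#' @param provenance character label recording where the signature came from.
#' @return A data.frame of class `irgp_signature`.
#' @export
irgp_signature <- function(gene_a, gene_b, coefficient,
                           provenance = "unspecified") {
  stopifnot(length(gene_a) == length(gene_b),
            length(gene_a) == length(coefficient))
  if (any(gene_a == gene_b)) stop("a signature pair cannot repeat a gene")
  if (!all(is.finite(coefficient)) || any(coefficient == 0))
    stop("signature coefficients must be finite and non-zero")
  id <- paste(gene_a, gene_b, sep = "|")
  if (anyDuplicated(id)) stop("duplicated signature pair(s)")
  out <- data.frame(gene_a = gene_a, gene_b = gene_b,
                    coefficient = coefficient, stringsAsFactors = FALSE)
  attr(out, "provenance") <- provenance
  class(out) <- c("irgp_signature", "data.frame")
  out
}

#' @export
print.irgp_signature <- function(x, ...) {
  cat(sprintf("irgp_signature: %d pairs (provenance: %s)\n",
              nrow(x), attr(x, "provenance")))
  print.data.frame(x, ...)
  invisible(x)
}

#' The published 11-pair renal-cancer signature
#'
#' Loads the packaged 11 immune-related gene pairs and their LASSO-Cox
#' coefficients, fitted on TCGA clear-cell renal-cell carcinoma training
#' data and validated on an independent microarray cohort. Orientation is
#' as published: the indicator is 1 when the first gene out-ranks the
#' second within a sample.
#'
#' @return An [irgp_signature()] with 11 entries.
#' @export
kirc_signature <- function() {
  path <- system.file("extdata", "kirc_irgp_signature.tsv",
                      package = "irgpsurv", mustWork = TRUE)
  read_signature(path, provenance = "published ccRCC 11-pair signature")
}

#' Read / write a signature TSV
#'
#' Columns: gene_a, gene_b, optional immune_process_a/immune_process_b
#' annotations, coefficient.
#'
#' @param path TSV path.
#' @param provenance label attached to the loaded signature.
#' @return `read_signature` returns an [irgp_signature()];
#'   `write_signature` returns `path` invisibly.
#' @export
read_signature <- function(path, provenance = path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE, comment.char = "")
  irgp_signature(tab$gene_a, tab$gene_b, as.numeric(tab$coefficient),
                 provenance = provenance)
}

#' @rdname read_signature
#' @param sig an [irgp_signature()].
#' @export
write_signature <- function(sig, path) {
  out <- data.frame(gene_a = sig$gene_a, gene_b = sig$gene_b,
                    coefficient = sprintf("%.17g", sig$coefficient),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Univariate Cox screen over pair indicators
#'
#' Fits a single-covariate Cox proportional-hazards model (Efron ties) per
#' pair indicator against overall survival and retains pairs with Wald
#' p < alpha. Pairs constant within the cohort cannot be fitted and are
#' skipped with a warning.
#'
#' @param m a `pair_matrix`.
#' @param clinical clinical table aligned with `m` by `sample_id`.
#' @param alpha retention threshold on the Wald p-value (default 0.001).
#' @return A list of class `cox_screen`: `table` (per-pair data.frame with
#'   coef, hr, se, z, p, lower/upper 95% CI), `retained` (pair ids with
#'   p < alpha) and `alpha`.
#' @export
univariate_cox_screen <- function(m, clinical, alpha = 0.001) {
  stopifnot(inherits(m, "pair_matrix"))
  clinical <- align_clinical(clinical, m$sample_ids)
  if (sum(clinical$os_event) < 2L)
    stop("need at least 2 events for a Cox screen")
  y <- survival::Surv(clinical$os_time, clinical$os_event)
  ids <- rownames(m$values)
  res <- vector("list", length(ids))
  skipped <- character(0)
  for (i in seq_along(ids)) {
    x <- m$values[i, ]
    if (length(unique(x)) < 2L) {
      skipped <- c(skipped, ids[i])
      next
    }
    fit <- survival::coxph(y ~ x, ties = "efron")
    s <- summary(fit)
    res[[i]] <- data.frame(
      pair = ids[i],
      coef = unname(s$coefficients[1L, "coef"]),
      hr = unname(s$coefficients[1L, "exp(coef)"]),
      se = unname(s$coefficients[1L, "se(coef)"]),
      z = unname(s$coefficients[1L, "z"]),
      p = unname(s$coefficients[1L, "Pr(>|z|)"]),
      lower95 = unname(s$conf.int[1L, "lower .95"]),
      upper95 = unname(s$conf.int[1L, "upper .95"]),
      stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("skipped constant pair(s): ", paste(skipped, collapse = ", "))
  table <- do.call(rbind, res)
  if (is.null(table))
    stop("no pair could be fitted")
  rownames(table) <- NULL
  structure(list(table = table,
                 retained = table$pair[table$p < alpha],
                 alpha = alpha),
            class = "cox_screen")
}

#' @export
print.cox_screen <- function(x, ...) {
  cat(sprintf("cox_screen: %d pairs fitted, %d retained at p < %g\n",
              nrow(x$table), length(x$retained), x$alpha))
  invisible(x)
}

#' LASSO-Cox signature selection
#'
#' Fits an L1-penalised Cox model over the screened pair indicators, with
#' the penalty chosen by k-fold cross-validated partial-likelihood deviance
#' (seeded fold assignment). Pairs with a non-zero coefficient at the
#' selected penalty form the signature. With a single candidate pair the
#' penalised fit degenerates and the unpenalised Cox coefficient is used.
#'
#' @param m a `pair_matrix` restricted to the screened pairs.
#' @param clinical clinical table aligned by `sample_id`.
#' @param max_iter optimiser iteration cap (default 10000).
#' @param nfolds cross-validation folds (default 10).
#' @param seed integer seed for fold assignment.
#' @param lambda `"min"` (CV-minimum deviance, default) or `"1se"`.
#' @return An [irgp_signature()].
#' @export
lasso_cox_select <- function(m, clinical, max_iter = 10000, nfolds = 10,
                             seed = 1L, lambda = c("min", "1se")) {
  stopifnot(inherits(m, "pair_matrix"))
  lambda <- match.arg(lambda)
  clinical <- align_clinical(clinical, m$sample_ids)
  if (!nrow(m$values)) stop("no screened pairs to select from")
  y <- survival::Surv(clinical$os_time, clinical$os_event)
  if (nrow(m$values) == 1L) {
    fit <- survival::coxph(y ~ x, data = data.frame(x = m$values[1L, ]))
    beta <- unname(stats::coef(fit))
    if (!is.finite(beta) || beta == 0)
      stop("single-pair fit produced no usable coefficient")
    return(irgp_signature(m$pairs$gene_a, m$pairs$gene_b, beta,
                          provenance = "unpenalised single-pair fit"))
  }
  x <- t(m$values)
  set.seed(as.integer(seed))
  foldid <- sample(rep(seq_len(nfolds), length.out = nrow(x)))
  cv <- glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid,
                          maxit = max_iter)
  lam <- if (lambda == "min") cv$lambda.min else cv$lambda.1se
  beta <- as.numeric(stats::coef(cv, s = lam))
  nz <- which(beta != 0)
  if (!length(nz))
    stop("LASSO shrank every coefficient to zero; consider lambda = 'min' ",
         "or a weaker penalty rule")
  irgp_signature(m$pairs$gene_a[nz], m$pairs$gene_b[nz], beta[nz],
                 provenance = sprintf("lasso-cox (lambda.%s, %d-fold CV, seed %d)",
                                      lambda, nfolds, as.integer(seed)))
}

#' Risk score from a pair matrix and a signature
#'
#' Computes the weighted sum of 0/1 pair-indicator values with the signature
#' coefficients: score = sum_k Exp_pair_k x Coef_pair_k. The signature's
#' stored orientation is respected: if a signature pair is present in the
#' matrix in reversed orientation its indicator is complemented (valid for
#' tie-free expression, the generic case for continuous data).
#'
#' @param m a `pair_matrix` covering the signature's gene pairs.
#' @param sig an [irgp_signature()].
#' @return Named numeric vector of per-sample risk scores.
#' @export
risk_score <- function(m, sig) {
  stopifnot(inherits(m, "pair_matrix"), inherits(sig, "irgp_signature"))
  ids <- rownames(m$values)
  vals <- matrix(0L, nrow(sig), ncol(m$values))
  for (k in seq_len(nrow(sig))) {
    fwd <- paste(sig$gene_a[k], sig$gene_b[k], sep = "|")
    rev <- paste(sig$gene_b[k], sig$gene_a[k], sep = "|")
    if (fwd %in% ids) {
      vals[k, ] <- m$values[fwd, ]
    } else if (rev %in% ids) {
      vals[k, ] <- 1L - m$values[rev, ]
    } else {
      stop("signature pair ", fwd, " not computable from the pair matrix")
    }
  }
  scores <- as.numeric(crossprod(vals, sig$coefficient))
  names(scores) <- m$sample_ids
  scores
}

#' Indicator matrix for a signature's own pairs
#'
#' Evaluates the signature pairs directly on an expression cohort, in the
#' signature's stored orientation (exact also under ties).
#'
#' @param cohort an [expression_cohort()] containing all signature genes.
#' @param sig an [irgp_signature()].
#' @return A `pair_matrix` with one row per signature pair.
#' @export
signature_pairs <- function(cohort, sig) {
  stopifnot(inherits(cohort, "expression_cohort"),
            inherits(sig, "irgp_signature"))
  need <- unique(c(sig$gene_a, sig$gene_b))
  missing <- setdiff(need, gene_ids(cohort))
  if (length(missing))
    stop("signature gene(s) absent from cohort: ",
         paste(missing, collapse = ", "))
  vals <- (cohort$matrix[sig$gene_a, , drop = FALSE] >
             cohort$matrix[sig$gene_b, , drop = FALSE]) * 1L
  storage.mode(vals) <- "integer"
  rownames(vals) <- paste(sig$gene_a, sig$gene_b, sep = "|")
  pair_matrix(vals, data.frame(gene_a = sig$gene_a, gene_b = sig$gene_b,
                               stringsAsFactors = FALSE))
}

#' Median-cutoff risk stratification
#'
#' Dichotomises continuous risk scores at a cutoff (default: the median of
#' the scores being stratified, i.e. each cohort is split at its own
#' median). A sample is high-risk iff its score strictly exceeds the
#' cutoff; scores equal to the cutoff go to the low-risk group.
#'
#' @param scores named numeric vector of risk scores.
#' @param cutoff stratification cutoff; defaults to `median(scores)`. Pass
#'   the training-cohort median to stratify a validation cohort against the
#'   training reference instead.
#' @return A data.frame of class `risk_profile` with columns `sample_id`,
#'   `risk_score`, `group` ("high"/"low"); the cutoff is kept as an
#'   attribute.
#' @export
median_stratify <- function(scores, cutoff = stats::median(scores)) {
  if (!length(scores)) stop("no scores to stratify")
  out <- data.frame(
    sample_id = if (is.null(names(scores))) as.character(seq_along(scores))
                else names(scores),
    risk_score = as.numeric(scores),
    group = ifelse(scores > cutoff, "high", "low"),
    stringsAsFactors = FALSE)
  attr(out, "cutoff") <- cutoff
  class(out) <- c("risk_profile", "data.frame")
  out
}

# Align a clinical table to a sample-id vector, erroring on absentees.
align_clinical <- function(clinical, sample_ids) {
  clinical <- as_clinical_table(clinical)
  idx <- match(sample_ids, clinical$sample_id)
  if (anyNA(idx))
    stop("sample(s) missing from clinical table: ",
         paste(sample_ids[is.na(idx)], collapse = ", "))
  clinical[idx, , drop = FALSE]
}
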
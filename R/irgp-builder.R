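#' Filter configuration for gene-pair construction
#'
#' @param mad_threshold genes are kept when their median absolute deviation
#'   across samples strictly exceeds this value (default 0.5).
#' @param prevalence_bound pairs are kept when the majority indicator class
#'   (all-0 or all-1) occupies strictly less than this fraction of samples
#'   (default 0.8, i.e. neither class may reach 80%).
#' @param mad_constant multiplier applied to the raw MAD; 1 gives the bare
#'   median of absolute deviations, 1.4826 the normal-consistent estimator.
#' @param mad_scale scale on which the MAD is computed: `"log2"` transforms
#'   linear-scale cohorts with log2(x+1) first (the default), `"native"`
#'   uses values as stored. Pair indicators are unaffected either way.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(mad_threshold = 0.5, prevalence_bound = 0.8,
                          mad_constant = 1, mad_scale = c("log2", "native")) {
  stopifnot(mad_threshold >= 0, prevalence_bound > 0.5, prevalence_bound <= 1,
            mad_constant > 0)
  structure(list(mad_threshold = mad_threshold,
                 prevalence_bound = prevalence_bound,
                 mad_constant = mad_constant,
                 mad_scale = match.arg(mad_scale)),
            class = "filter_config")
}

#' Variability filter on immune genes
#'
#' Restricts an immune-gene list to genes present in the cohort whose MAD
#' (median of absolute deviations from the per-gene median across samples)
#' strictly exceeds `config$mad_threshold`. Low-MAD genes carry little
#' ranking information and are dropped before pairing.
#'
#' @param cohort an [expression_cohort()].
#' @param immune_genes character vector of immune-related gene symbols.
#' @param config a [filter_config()].
#' @return Character vector of retained gene symbols, in cohort row order.
#' @export
mad_filter <- function(cohort, immune_genes, config = filter_config()) {
  stopifnot(inherits(cohort, "expression_cohort"))
  if (!length(immune_genes)) stop("immune gene list is empty")
  present <- intersect(gene_ids(cohort), immune_genes)
  if (!length(present))
    stop("none of the immune genes are present in cohort '",
         cohort$platform, "'")
  m <- cohort$matrix[present, , drop = FALSE]
  if (config$mad_scale == "log2" && !cohort$log_scale) {
    if (any(m < 0)) stop("negative values; cannot move to log2 scale for MAD")
    m <- log2(m + 1)
  }
  mads <- apply(m, 1L, stats::mad, constant = config$mad_constant)
  kept <- present[mads > config$mad_threshold]
  if (!length(kept))
    stop("no genes exceed MAD threshold ", config$mad_threshold,
         " in cohort '", cohort$platform, "'; review the threshold")
  kept
}

#' Binary gene-pair indicator
#'
#' The indicator is 1 when the first gene's expression strictly exceeds the
#' second's within the same sample, and 0 otherwise (ties score 0). Being a
#' within-sample rank comparison, it is invariant to any strictly increasing
#' rescaling of that sample's values — the property that makes gene-pair
#' features platform-robust.
#'
#' @param expr_a,expr_b finite numeric expression values (vectorised).
#' @return Integer 0/1 vector.
#' @export
pair_indicator <- function(expr_a, expr_b) {
  if (!all(is.finite(expr_a)) || !all(is.finite(expr_b)))
    stop("pair_indicator requires finite inputs")
  as.integer(expr_a > expr_b)
}

#' Build the pair-indicator matrix for a gene set
#'
#' Forms every unordered pair of the given genes once, oriented
#' lexicographically by symbol (gene_a < gene_b), and evaluates
#' [pair_indicator()] per sample, giving a pairs x samples 0/1 matrix.
#'
#' @param cohort an [expression_cohort()].
#' @param genes character vector (>= 2) of gene symbols present in the cohort.
#' @return A `pair_matrix`: list with `values` (0/1 integer matrix, rows
#'   named "GENEA|GENEB"), `pairs` (data.frame gene_a/gene_b) and
#'   `sample_ids`.
#' @export
build_pairs <- function(cohort, genes) {
  stopifnot(inherits(cohort, "expression_cohort"))
  genes <- sort(unique(genes))
  if (length(genes) < 2L) stop("need at least 2 genes to form pairs")
  missing <- setdiff(genes, gene_ids(cohort))
  if (length(missing))
    stop("gene(s) absent from cohort: ", paste(missing, collapse = ", "))
  idx <- utils::combn(length(genes), 2L)
  a <- genes[idx[1L, ]]
  b <- genes[idx[2L, ]]
  vals <- (cohort$matrix[a, , drop = FALSE] >
             cohort$matrix[b, , drop = FALSE]) * 1L
  storage.mode(vals) <- "integer"
  rownames(vals) <- paste(a, b, sep = "|")
  pair_matrix(vals, data.frame(gene_a = a, gene_b = b,
                               stringsAsFactors = FALSE))
}

#' @rdname build_pairs
#' @param values 0/1 integer matrix, pairs x samples, with row and column
#'   names.
#' @param pairs data.frame with columns gene_a, gene_b, one row per row of
#'   `values`.
#' @export
pair_matrix <- function(values, pairs) {
  stopifnot(is.matrix(values), nrow(values) == nrow(pairs),
            all(values %in% c(0L, 1L)),
            all(c("gene_a", "gene_b") %in% names(pairs)))
  if (any(pairs$gene_a == pairs$gene_b))
    stop("a pair cannot compare a gene with itself")
  if (anyDuplicated(rownames(values)))
    stop("duplicated pair rows")
  storage.mode(values) <- "integer"
  structure(list(values = values, pairs = pairs,
                 sample_ids = colnames(values)),
            class = "pair_matrix")
}

#' @export
print.pair_matrix <- function(x, ...) {
  cat(sprintf("pair_matrix: %d pairs x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Prevalence filter on pair indicators
#'
#' Keeps pairs whose indicator is informative in the cohort: the fraction of
#' 1s must lie strictly inside (1 - prevalence_bound, prevalence_bound), so
#' that neither the 0-class nor the 1-class reaches the bound (default 80%)
#' of samples. Near-constant pairs carry no discriminative signal.
#'
#' @param m a `pair_matrix`.
#' @param config a [filter_config()].
#' @return The filtered `pair_matrix`.
#' @export
prevalence_filter <- function(m, config = filter_config()) {
  stopifnot(inherits(m, "pair_matrix"))
  if (!nrow(m$values)) stop("empty pair matrix")
  frac1 <- rowMeans(m$values)
  keep <- frac1 < config$prevalence_bound &
    frac1 > 1 - config$prevalence_bound
  if (!any(keep))
    stop("no pairs survive the prevalence filter (bound ",
         config$prevalence_bound, ")")
  subset_pairs(m, rownames(m$values)[keep])
}

#' Intersect candidate pairs across platforms
#'
#' Returns the pairs retained (post-filter) on every platform, preserving
#' the canonical order of the first matrix. Restricting the candidate set to
#' this intersection is what lets one signature transfer across measurement
#' platforms.
#'
#' @param matrices list of `pair_matrix` objects (>= 1).
#' @return data.frame of shared pairs (gene_a, gene_b).
#' @export
intersect_pairs <- function(matrices) {
  stopifnot(length(matrices) >= 1L,
            all(vapply(matrices, inherits, logical(1), "pair_matrix")))
  ids <- Reduce(intersect, lapply(matrices, function(m) rownames(m$values)))
  if (!length(ids)) stop("no pairs shared across all platforms")
  first <- matrices[[1L]]
  keep <- rownames(first$values) %in% ids
  first$pairs[keep, , drop = FALSE]
}

#' Restrict a pair matrix to named pairs
#'
#' @param m a `pair_matrix`.
#' @param pair_ids character vector of "GENEA|GENEB" row ids.
#' @return The restricted `pair_matrix`, in `pair_ids` order.
#' @export
subset_pairs <- function(m, pair_ids) {
  stopifnot(inherits(m, "pair_matrix"))
  missing <- setdiff(pair_ids, rownames(m$values))
  if (length(missing))
    stop("pair(s) absent from matrix: ", paste(missing, collapse = ", "))
  sel <- match(pair_ids, rownames(m$values))
  pair_matrix(m$values[sel, , drop = FALSE],
              m$pairs[sel, , drop = FALSE])
}
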
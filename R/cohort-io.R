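#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file with gene symbols in the first column, one
#' column per sample, and a header row of sample identifiers. Duplicate gene
#' symbols, duplicate sample ids, ragged rows and non-numeric cells are
#' rejected with a descriptive error.
#'
#' @param path path to the TSV file.
#' @param platform platform label to attach to the cohort.
#' @param log_scale logical; whether the stored values are log2-scale.
#' @return An [expression_cohort()].
#' @export
read_expression <- function(path, platform, log_scale) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character",
                           comment.char = "")
  if (ncol(raw) < 2L) stop("expression file needs >=1 sample column: ", path)
  genes <- raw[[1L]]
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop("duplicated gene row(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(apply(vals, 2L, as.numeric))
  num <- matrix(num, nrow = nrow(raw),
                dimnames = list(genes, colnames(raw)[-1L]))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("non-numeric cell in ", path, " at gene '", genes[bad[1L]],
         "', sample '", colnames(num)[bad[2L]], "'")
  }
  expression_cohort(num, platform = platform, log_scale = log_scale)
}

#' Read a clinical table from TSV
#'
#' @param path TSV with columns sample_id, age, gender, grade, stage,
#'   os_time, os_event. Stage and grade may be Arabic or Roman numerals;
#'   empty cells and "NA" are treated as missing.
#' @return A validated clinical data.frame.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  cl <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"), comment.char = "")
  as_clinical_table(cl)
}

#' Read a gene list file
#'
#' One symbol per line; lines starting with `#` and blank lines are ignored.
#'
#' @param path path to the list file.
#' @return Character vector of unique gene symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(lines)
}

#' Log2-transform a linear-scale cohort
#'
#' Replaces each value x by log2(x + 1), bringing FPKM-like linear data onto
#' the same order of magnitude as log-scale microarray data. The pseudocount
#' keeps zero expression finite. Pair indicators are unaffected because the
#' map is strictly increasing.
#'
#' @param cohort an [expression_cohort()] with `log_scale = FALSE`.
#' @return The cohort with transformed values and `log_scale = TRUE`.
#' @export
log2_transform <- function(cohort) {
  stopifnot(inherits(cohort, "expression_cohort"))
  if (cohort$log_scale)
    stop("cohort '", cohort$platform, "' is already log-scale")
  if (any(cohort$matrix < 0))
    stop("negative values cannot be log2-transformed")
  expression_cohort(log2(cohort$matrix + 1), cohort$platform, TRUE)
}

#' Drop samples with incomplete records
#'
#' Keeps only samples that appear in both the clinical table and the
#' expression cohort and have no missing value in any required clinical
#' field (age, gender, grade, stage, os_time, os_event) — the blanket
#' complete-case rule.
#'
#' @param clinical a clinical data.frame.
#' @param cohort an [expression_cohort()].
#' @return A list with elements `clinical` and `cohort`, restricted to
#'   complete samples (clinical rows in cohort column order).
#' @export
drop_incomplete <- function(clinical, cohort) {
  clinical <- as_clinical_table(clinical)
  required <- c("age", "gender", "grade", "stage", "os_time", "os_event")
  complete <- stats::complete.cases(clinical[, required])
  keep_ids <- intersect(sample_ids(cohort), clinical$sample_id[complete])
  if (!length(keep_ids))
    stop("no samples with complete clinical records remain")
  cl <- clinical[match(keep_ids, clinical$sample_id), , drop = FALSE]
  rownames(cl) <- NULL
  co <- expression_cohort(cohort$matrix[, keep_ids, drop = FALSE],
                          cohort$platform, cohort$log_scale)
  list(clinical = cl, cohort = co)
}

#' Random 7:3 training/validation split
#'
#' Each sample draws an independent Uniform(0,1) number; samples with a draw
#' less than or equal to the threshold go to the training cohort, the rest
#' to the validation cohort. The default threshold 0.7 gives the 7:3 split.
#'
#' @param sample_ids character vector of sample identifiers.
#' @param seed integer seed making the split reproducible.
#' @param threshold training-assignment cutoff in \[0,1\].
#' @return A list of class `cohort_split` with `training`, `validation`,
#'   `seed` and `threshold`.
#' @export
split_cohort <- function(sample_ids, seed, threshold = 0.7) {
  if (!length(sample_ids)) stop("empty sample id list")
  stopifnot(threshold >= 0, threshold <= 1)
  set.seed(as.integer(seed))
  u <- stats::runif(length(sample_ids))
  structure(list(training = sample_ids[u <= threshold],
                 validation = sample_ids[u > threshold],
                 seed = as.integer(seed), threshold = threshold),
            class = "cohort_split")
}

#' @export
print.cohort_split <- function(x, ...) {
  cat(sprintf("cohort_split: %d training / %d validation (threshold %.2f, seed %d)\n",
              length(x$training), length(x$validation), x$threshold, x$seed))
  invisible(x)
}
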
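#' Construct an expression cohort
#'
#' An expression cohort is a genes x samples numeric matrix tagged with the
#' measurement platform it came from and whether values are on a log scale.
#' Gene symbols are row names, sample identifiers are column names; both must
#' be unique and every value finite.
#'
#' @param matrix numeric matrix, genes in rows, samples in columns, with
#'   row and column names set.
#' @param platform character label for the measurement platform.
#' @param log_scale logical; `TRUE` when values are log2-scale (microarray
#'   style), `FALSE` for linear FPKM-like values.
#' @return An object of class `expression_cohort`.
#' @export
expression_cohort <- function(matrix, platform, log_scale) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("expression data must be a numeric matrix")
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop("expression matrix needs gene row names and sample column names")
  dup_g <- rownames(matrix)[duplicated(rownames(matrix))]
  if (length(dup_g))
    stop("duplicated gene symbol(s): ", paste(unique(dup_g), collapse = ", "))
  dup_s <- colnames(matrix)[duplicated(colnames(matrix))]
  if (length(dup_s))
    stop("duplicated sample id(s): ", paste(unique(dup_s), collapse = ", "))
  if (!all(is.finite(matrix)))
    stop("expression matrix contains non-finite values")
  stopifnot(is.character(platform), length(platform) == 1L,
            is.logical(log_scale), length(log_scale) == 1L)
  structure(list(matrix = matrix, platform = platform,
                 log_scale = log_scale),
            class = "expression_cohort")
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat(sprintf("expression_cohort: %d genes x %d samples, platform '%s' (%s scale)\n",
              nrow(x$matrix), ncol(x$matrix), x$platform,
              if (x$log_scale) "log2" else "linear"))
  invisible(x)
}

#' @rdname expression_cohort
#' @param x an `expression_cohort`.
#' @export
gene_ids <- function(x) rownames(x$matrix)

#' @rdname expression_cohort
#' @export
sample_ids <- function(x) colnames(x$matrix)

#' Validate a clinical table
#'
#' A clinical table has one row per sample with columns `sample_id`, `age`,
#' `gender` ("male"/"female"), `grade` and `stage` (ordinal 1-4), `os_time`
#' (non-negative follow-up) and `os_event` (0 = censored, 1 = death).
#' Missing values are permitted on entry; [drop_incomplete()] removes them.
#'
#' @param clinical a data.frame with the columns above.
#' @return The validated data.frame (invisibly usable downstream).
#' @export
as_clinical_table <- function(clinical) {
  required <- c("sample_id", "age", "gender", "grade", "stage",
                "os_time", "os_event")
  missing_cols <- setdiff(required, names(clinical))
  if (length(missing_cols))
    stop("clinical table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(clinical$sample_id))
    stop("clinical table has duplicated sample ids")
  clinical$grade <- parse_ordinal(clinical$grade)
  clinical$stage <- parse_ordinal(clinical$stage)
  bad_t <- !is.na(clinical$os_time) & clinical$os_time < 0
  if (any(bad_t)) stop("negative os_time for sample(s): ",
                       paste(clinical$sample_id[bad_t], collapse = ", "))
  bad_e <- !is.na(clinical$os_event) & !clinical$os_event %in% c(0, 1)
  if (any(bad_e)) stop("os_event must be 0 or 1")
  clinical
}

# Stage/grade come as Arabic (1-4) or Roman (I-IV, optionally prefixed like
# "Stage III"); normalise to integer 1-4, NA preserved.
parse_ordinal <- function(x) {
  if (is.numeric(x)) {
    out <- as.integer(x)
  } else {
    s <- toupper(trimws(gsub("(?i)^(stage|grade)\\s*", "", as.character(x),
                             perl = TRUE)))
    roman <- c(I = 1L, II = 2L, III = 3L, IV = 4L)
    out <- ifelse(s %in% names(roman), roman[s], suppressWarnings(as.integer(s)))
    out[is.na(x) | s == "" | s == "NA"] <- NA_integer_
  }
  bad <- !is.na(out) & (out < 1L | out > 4L)
  if (any(bad)) stop("ordinal stage/grade outside 1-4: ",
                     paste(unique(x[bad]), collapse = ", "))
  as.integer(out)
}
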
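.check_counts <- function(counts, lengths = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("'counts' must be a numeric matrix (genes x samples)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have gene row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids in 'counts'")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids in 'counts'")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("'counts' must be finite and non-negative")
  if (!is.null(lengths)) {
    if (is.matrix(lengths)) {
      if (!identical(dim(lengths), dim(counts)))
        stop("per-sample 'lengths' must have the same dimensions as 'counts'")
      lv <- lengths
    } else {
      if (length(lengths) != nrow(counts))
        stop("'lengths' must have one value per gene")
      if (!is.null(names(lengths)) &&
          !identical(names(lengths), rownames(counts)))
        stop("names of 'lengths' do not match gene ids of 'counts'")
      lv <- as.numeric(lengths)
    }
    if (any(!is.finite(lv)) || any(lv <= 0))
      stop("gene lengths must be finite and strictly positive")
  }
  invisible(TRUE)
}

#' Remove genes with very low total counts
#'
#' Drops genes whose total raw count across all samples is at or below
#' `max_total` (default 10), the usual robustness filter applied before
#' differential expression on bulk RNA-seq. A gene summing to exactly
#' `max_total` is removed; a gene summing to `max_total + 1` is kept.
#'
#' @param counts Numeric genes x samples matrix with dimnames.
#' @param max_total Total-count threshold; genes with `rowSums <= max_total`
#'   are excluded.
#' @return The filtered count matrix, with attribute `"removed"` listing the
#'   ids of excluded genes. Errors if no gene survives.
#' @export
filter_low_counts <- function(counts, max_total = 10) {
  .check_counts(counts)
  keep <- rowSums(counts) > max_total
  if (!any(keep))
    stop("no genes remain after the low-count filter (total counts <= ",
         max_total, " for every gene)")
  out <- counts[keep, , drop = FALSE]
  attr(out, "removed") <- rownames(counts)[!keep]
  out
}

#' Scale counts by geometric-mean-normalized gene lengths
#'
#' Each gene's length is divided by its geometric mean across samples, and
#' counts are divided by the resulting normalized length. With a single
#' per-gene length (or a single sample) the normalized length is 1 everywhere
#' and the counts pass through unchanged; the correction only acts when
#' effective gene length varies between samples.
#'
#' @param counts Numeric genes x samples count matrix.
#' @param lengths Per-gene vector, or genes x samples matrix of per-sample
#'   effective lengths (bases); strictly positive.
#' @return Real-valued matrix of length-scaled counts.
#' @export
length_scale <- function(counts, lengths) {
  .check_counts(counts, lengths)
  if (!is.matrix(lengths))
    return(counts * 1.0)  # constant length per gene: normalized length is 1
  geo <- exp(rowMeans(log(lengths)))
  lnorm <- lengths / geo
  counts / lnorm
}

#' Trimmed mean of M-values scaling factors
#'
#' Between-sample scaling factors from doubly trimmed, precision-weighted
#' log-ratios against a reference library (the library whose 75th-percentile
#' count fraction is closest to the mean of those), rescaled to geometric
#' mean 1. Computed with [edgeR::calcNormFactors()], the standard
#' implementation of the method.
#'
#' @param x Numeric genes x samples matrix of (possibly length-scaled) counts;
#'   at least two samples, no all-zero sample.
#' @param trim_m Two-sided trim fraction on M-values (log-ratios).
#' @param trim_a Two-sided trim fraction on A-values (mean abundances).
#' @return Named per-sample vector of positive factors with geometric mean 1.
#' @export
tmm_factors <- function(x, trim_m = 0.30, trim_a = 0.05) {
  if (!is.matrix(x) || ncol(x) < 2)
    stop("TMM factors require a matrix with at least 2 samples")
  if (any(x < 0) || any(!is.finite(x)))
    stop("counts must be finite and non-negative")
  lib <- colSums(x)
  if (any(lib == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(x)[lib == 0], collapse = ", "))
  f <- edgeR::calcNormFactors(x, method = "TMM",
                              logratioTrim = trim_m, sumTrim = trim_a)
  f <- f / exp(mean(log(f)))  # enforce geometric mean 1 exactly
  names(f) <- colnames(x)
  f
}

#' Normalize raw counts to log2 TMM-TPM expression
#'
#' The full preprocessing chain for a raw count matrix: low-count gene filter,
#' gene-length geometric-mean scaling, TMM scaling factors, TPM on the
#' TMM-effective library sizes, and a log2 transform with pseudocount.
#' Per-sample TPM columns sum to 1e6 / TMM factor, and every log2-TPM column
#' is invariant to uniform rescaling of that sample's counts.
#'
#' @param counts Raw genes x samples count matrix.
#' @param lengths Per-gene vector or per-gene-per-sample matrix of lengths.
#' @param max_total Low-count filter threshold (see [filter_low_counts()]);
#'   set to `NULL` to skip filtering.
#' @param pseudocount Added to TPM before log2; default 1.
#' @param trim_m,trim_a TMM trim fractions, passed to [tmm_factors()].
#' @return Object of class `"tmm_tpm_norm"`: a list with `expression`
#'   (log2-TPM matrix), `tmm_factors`, `effective_library_sizes`, and
#'   `filtered_gene_ids`.
#' @export
normalize_expression <- function(counts, lengths, max_total = 10,
                                 pseudocount = 1, trim_m = 0.30,
                                 trim_a = 0.05) {
  .check_counts(counts, lengths)
  removed <- character(0)
  if (!is.null(max_total)) {
    keep_counts <- filter_low_counts(counts, max_total)
    removed <- attr(keep_counts, "removed")
    attr(keep_counts, "removed") <- NULL
    if (is.matrix(lengths)) lengths <- lengths[rownames(keep_counts), , drop = FALSE]
    else if (!is.null(names(lengths))) lengths <- lengths[rownames(keep_counts)]
    else lengths <- lengths[rownames(counts) %in% rownames(keep_counts)]
    counts <- keep_counts
  }
  scaled <- length_scale(counts, lengths)
  f <- if (ncol(scaled) >= 2) tmm_factors(scaled, trim_m, trim_a)
       else structure(1, names = colnames(scaled))
  eff <- colSums(scaled) * f
  tpm <- sweep(scaled, 2, eff, "/") * 1e6
  expr <- log2(tpm + pseudocount)
  structure(list(expression = expr,
                 tmm_factors = f,
                 effective_library_sizes = eff,
                 filtered_gene_ids = removed,
                 pseudocount = pseudocount),
            class = "tmm_tpm_norm")
}

#' @export
print.tmm_tpm_norm <- function(x, ...) {
  cat("log2 TMM-TPM normalization\n")
  cat("  genes:  ", nrow(x$expression),
      " (", length(x$filtered_gene_ids), " removed by low-count filter)\n",
      sep = "")
  cat("  samples:", ncol(x$expression), "\n")
  cat("  TMM factor range: ",
      paste(signif(range(x$tmm_factors), 4), collapse = " - "), "\n", sep = "")
  invisible(x)
}

#' Flag outlier samples by median inter-sample distance
#'
#' Computes all pairwise Euclidean distances between samples over the full
#' gene set of a log2 expression matrix, summarizes each sample by its median
#' distance to all other samples, and flags samples whose median distance
#' strictly exceeds the 75th percentile plus three times the interquartile
#' range of the median distances. Quantiles use linear interpolation between
#' order statistics.
#'
#' @param expr Log2 expression matrix (genes x samples), at least 4 samples.
#' @return Object of class `"outlier_report"`: `median_distances`,
#'   `threshold`, `flagged_sample_ids`.
#' @export
detect_outliers <- function(expr) {
  if (!is.matrix(expr) || ncol(expr) < 4)
    stop("outlier detection needs an expression matrix with >= 4 samples")
  d <- as.matrix(stats::dist(t(expr)))
  med <- vapply(seq_len(ncol(d)),
                function(i) stats::median(d[i, -i]), numeric(1))
  names(med) <- colnames(expr)
  thr <- unname(stats::quantile(med, 0.75, type = 7) +
                  3 * stats::IQR(med, type = 7))
  structure(list(median_distances = med,
                 threshold = thr,
                 flagged_sample_ids = names(med)[med > thr]),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("Sample outlier report: threshold", signif(x$threshold, 5), "\n")
  if (length(x$flagged_sample_ids))
    cat("  flagged:", paste(x$flagged_sample_ids, collapse = ", "), "\n")
  else cat("  no samples flagged\n")
  invisible(x)
}

# --- tab-separated matrix io (genes x samples, first column = gene id) ------

#' Read / write expression or count matrices as TSV
#'
#' Plain tab-separated matrices with a header row of sample ids and the gene
#' id in the first column; columns are written in their current order so
#' output is deterministic.
#'
#' @param path File path.
#' @rdname matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @param x Matrix with dimnames.
#' @param id_name Header used for the gene-id column.
#' @rdname matrix_tsv
#' @export
write_matrix_tsv <- function(x, path, id_name = "gene_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an outlier report as JSON
#' @param x An `"outlier_report"`.
#' @param path Output path.
#' @export
write_outlier_report <- function(x, path) {
  stopifnot(inherits(x, "outlier_report"))
  jsonlite::write_json(
    list(median_distances = as.list(x$median_distances),
         threshold = x$threshold,
         flagged_sample_ids = x$flagged_sample_ids),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
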
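# Two-group differential ranking with a signed-significance metric, BH
# adjustment, and pre-ranked gene set enrichment with a gene-label
# permutation null.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (wraps [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Rank genes between two groups by signed significance
#'
#' For each gene the log2 fold change is the difference of group mean log2
#' expression (second factor level minus first) and the p-value comes from a
#' two-sided Welch (unequal-variance) t-test. The ranking metric combines
#' direction and significance as `-log10(p) * sign(log2FC)`; zero p-values
#' are floored at the smallest positive double before taking logs. Adjusted
#' p-values are Benjamini-Hochberg over all tested genes.
#'
#' @param expr Log2 expression matrix (genes x samples).
#' @param groups Per-sample two-level factor (or coercible); each level needs
#'   at least 2 samples.
#' @return Data frame with columns `gene`, `log2_fold_change`, `p_value`,
#'   `adjusted_p`, `rank_score`.
#' @export
differential_ranking <- function(expr, groups) {
  stopifnot(is.matrix(expr))
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("'groups' must have exactly two levels")
  if (length(groups) != ncol(expr))
    stop("'groups' must have one value per sample")
  if (any(table(groups) < 2)) stop("each group needs at least 2 samples")
  i1 <- groups == levels(groups)[1]
  i2 <- groups == levels(groups)[2]
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- rowMeans(expr[, i1, drop = FALSE])
  m2 <- rowMeans(expr[, i2, drop = FALSE])
  v1 <- apply(expr[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(expr[, i2, drop = FALSE], 1, stats::var)
  lfc <- m2 - m1
  se2 <- v1 / n1 + v2 / n2
  tstat <- ifelse(se2 > 0, lfc / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1))),
               n1 + n2 - 2)
  p <- 2 * stats::pt(-abs(tstat), df)
  p[!is.finite(p)] <- 1
  padj <- bh_adjust(p)
  pf <- pmax(p, .Machine$double.xmin)
  data.frame(gene = rownames(expr),
             log2_fold_change = unname(lfc),
             p_value = unname(p),
             adjusted_p = unname(padj),
             rank_score = unname(-log10(pf) * sign(lfc)),
             stringsAsFactors = FALSE)
}

#' Select differentially expressed genes
#'
#' Genes passing `adjusted_p < padj_cut` and `|log2FC| > lfc_cut` (both
#' strict).
#'
#' @param ranked Output of [differential_ranking()].
#' @param padj_cut Adjusted p-value cutoff (default 0.05).
#' @param lfc_cut Absolute log2 fold-change cutoff (default 0.5).
#' @return Character vector of gene ids.
#' @export
select_deg <- function(ranked, padj_cut = 0.05, lfc_cut = 0.5) {
  stopifnot(all(c("gene", "adjusted_p", "log2_fold_change") %in%
                  names(ranked)))
  ranked$gene[ranked$adjusted_p < padj_cut &
                abs(ranked$log2_fold_change) > lfc_cut]
}

# Enrichment-score statistic of the weighted running sum for one set of hit
# positions within a ranking of length N; w = |rank score| per position.
# Candidates for the extremum are the values immediately after each hit
# (running maximum) and immediately before each hit (running minimum).
.es_stat <- function(hit_idx, w, N) {
  k <- length(hit_idx)
  hw <- w[hit_idx]
  nr <- sum(hw)
  if (nr == 0) return(0)
  cum_hit <- cumsum(hw) / nr
  miss_before <- (hit_idx - seq_len(k)) / (N - k)
  up <- cum_hit - miss_before
  down <- c(0, cum_hit[-k]) - miss_before
  hi <- max(up)
  lo <- min(down, 0)
  if (hi >= -lo) hi else lo
}

#' Pre-ranked gene set enrichment with a permutation null
#'
#' Classical weighted Kolmogorov-Smirnov enrichment on a ranked gene list:
#' genes are ordered by decreasing rank score, the running sum increments at
#' set members in proportion to `|rank score|` (weight exponent 1) and
#' decrements uniformly elsewhere, and the enrichment score (ES) is the
#' signed maximum deviation. The null distribution per set comes from random
#' gene-label permutations (random hit positions of the same set size); the
#' normalized score is `NES = ES / mean(|null ES| of the same sign)` and the
#' permutation p-value is two-tailed by sign with the usual +1 correction.
#' Sets are intersected with the ranking first and only those whose
#' intersected size lies in `[min_size, max_size]` are scored; a set with no
#' genes in the ranking at all is an error. BH adjustment is applied across
#' scored sets. Results are reproducible bit-for-bit for a fixed `seed`.
#'
#' @param ranked Output of [differential_ranking()], or any data frame with
#'   `gene` and `rank_score` columns (no duplicate genes).
#' @param sets Named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param min_size,max_size Set-size bounds after intersection (defaults 10
#'   and 500).
#' @param n_perm Number of permutations (at least 100; default 1000).
#' @param seed Integer seed for the permutation stream.
#' @return Data frame (one row per scored set): `set`, `size`, `es`, `nes`,
#'   `p_value`, `adjusted_p`; attributes `n_perm` and `seed`.
#' @export
preranked_gsea <- function(ranked, sets, min_size = 10, max_size = 500,
                           n_perm = 1000, seed = 1) {
  stopifnot(all(c("gene", "rank_score") %in% names(ranked)))
  if (anyDuplicated(ranked$gene)) stop("duplicate genes in ranking")
  if (n_perm < 100) stop("n_perm must be at least 100")
  if (!is.list(sets) || is.null(names(sets))) stop("'sets' must be a named list")
  ord <- order(ranked$rank_score, decreasing = TRUE)
  genes <- ranked$gene[ord]
  w <- abs(ranked$rank_score[ord])
  N <- length(genes)
  pos <- seq_len(N)
  names(pos) <- genes
  inter <- lapply(sets, function(s) unname(pos[unique(s)[unique(s) %in% genes]]))
  vanished <- lengths(inter) == 0
  if (any(vanished))
    stop("gene set(s) with no genes in the ranking: ",
         paste(names(sets)[vanished], collapse = ", "))
  sizes <- lengths(inter)
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep))
    stop("no gene set within size bounds [", min_size, ", ", max_size, "]")
  inter <- inter[keep]
  sizes <- sizes[keep]

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  # one shared null per distinct set size
  null_by_size <- new.env(parent = emptyenv())
  null_for <- function(k) {
    key <- as.character(k)
    if (!is.null(null_by_size[[key]])) return(null_by_size[[key]])
    es <- vapply(seq_len(n_perm), function(i)
      .es_stat(sort.int(sample.int(N, k)), w, N), numeric(1))
    null_by_size[[key]] <- es
    es
  }
  res <- lapply(seq_along(inter), function(i) {
    idx <- sort.int(inter[[i]])
    es <- .es_stat(idx, w, N)
    null <- null_for(sizes[i])
    same <- if (es >= 0) null[null >= 0] else null[null < 0]
    nes <- if (length(same) && mean(abs(same)) > 0)
      es / mean(abs(same)) else 0
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    data.frame(set = names(inter)[i], size = sizes[i], es = es, nes = nes,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adjusted_p <- bh_adjust(out$p_value)
  rownames(out) <- NULL
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("gsea_result", "data.frame")
  out
}

#' @export
print.gsea_result <- function(x, ...) {
  cat("Pre-ranked GSEA:", nrow(x), "sets,",
      attr(x, "n_perm"), "permutations (seed", attr(x, "seed"), ")\n")
  y <- as.data.frame(x)
  y <- y[order(y$p_value), ]
  print(utils::head(y, 10), row.names = FALSE, digits = 4)
  if (nrow(y) > 10) cat("... and", nrow(y) - 10, "more sets\n")
  invisible(x)
}

#' Write ranking or enrichment tables as TSV
#'
#' Enrichment output records the permutation count and seed in `#`-prefixed
#' header lines.
#'
#' @param x Data frame ([differential_ranking()] or [preranked_gsea()]
#'   output).
#' @param path Output path.
#' @export
write_enrichment_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(attr(x, "n_perm")))
    writeLines(c(paste0("# n_perm=", attr(x, "n_perm")),
                 paste0("# seed=", attr(x, "seed"))), con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
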
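# Independent oracles and fixture builders shared across tests.

# Direct evaluation of the published TMM algorithm: reference library by
# 75th-percentile count fraction closest to the mean, per-pair M/A values on
# genes nonzero in both libraries, double rank trimming (30% on M, 5% on A),
# inverse-binomial-variance weighted mean, factors rescaled to geometric
# mean 1. Written from the method's definition, independent of edgeR.
tmm_direct <- function(x, trim_m = 0.3, trim_a = 0.05) {
  lib <- colSums(x)
  f75 <- apply(x, 2, function(col) stats::quantile(col, 0.75, type = 7)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  one <- function(obs, refc, nO, nR) {
    logR <- log2((obs / nO) / (refc / nR))
    absE <- (log2(obs / nO) + log2(refc / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - refc) / nR / refc
    fin <- is.finite(logR) & is.finite(absE)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * trim_m) + 1; hiL <- n + 1 - loL
    loS <- floor(n * trim_a) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    2^(sum(logR[keep] / v[keep]) / sum(1 / v[keep]))
  }
  f <- vapply(seq_len(ncol(x)),
              function(j) one(x[, j], x[, ref], lib[j], lib[ref]), numeric(1))
  f / exp(mean(log(f)))
}

# Random count matrix with gene-level dispersion.
random_counts <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  m <- matrix(stats::rpois(n_genes * n_samples,
                           stats::rgamma(n_genes * n_samples, 2, scale = 50)),
              n_genes, n_samples,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  m
}

# Gaussian log2 expression matrix.
random_expr <- function(n_genes, n_samples, seed, mean = 6, sd = 1) {
  set.seed(seed)
  matrix(stats::rnorm(n_genes * n_samples, mean, sd), n_genes, n_samples,
         dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                         sprintf("s%03d", seq_len(n_samples))))
}

# Three disjoint Pr/Er/Im modules over the first genes of a matrix.
toy_modules <- function(genes, sizes = c(16, 4, 11)) {
  stopifnot(length(genes) >= sum(sizes))
  list(Pr = genes[seq_len(sizes[1])],
       Er = genes[sizes[1] + seq_len(sizes[2])],
       Im = genes[sizes[1] + sizes[2] + seq_len(sizes[3])])
}

# Reconstructed arm x biomarker subject-level data from the published
# response rates (palbociclib arm = "B", paclitaxel = "A").
trial_interaction_data <- function() {
  pos <- reconstruct_counts(c(47.8, 31.6), total = 42)
  neg <- reconstruct_counts(c(43.3, 65.6), total = 121)
  d <- rbind(expand_counts(pos$events, pos$n, arm = c("B", "A"),
                           biomarker = "positive"),
             expand_counts(neg$events, neg$n, arm = c("B", "A"),
                           biomarker = "negative"))
  names(d)[names(d) == "y"] <- "orr12"
  d
}
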
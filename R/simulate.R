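# Synthetic two-arm neoadjuvant cohort generator. Emulates the statistical
# structure the downstream analysis assumes: a count matrix whose latent log2
# expression carries three block-correlated gene modules (proliferation, ER
# signalling, immune), a randomized treatment arm, and a binary response
# whose log-odds depend on arm, the true module-derived biomarker label, and
# their interaction.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  force(expr)
}

#' Configuration for a synthetic trial cohort
#'
#' Defaults describe a two-arm neoadjuvant cohort of the size and structure
#' of a randomized phase-II trial analysis population: 163 patients, 1:1
#' allocation between paclitaxel-first (arm A) and palbociclib-first
#' (arm B), a 31-gene three-module biomarker, and response coefficients that
#' reproduce arm-by-biomarker objective response rates of 47.8% / 31.6%
#' (biomarker-positive, arms B / A) and 43.3% / 65.6% (biomarker-negative) —
#' i.e. within-stratum arm odds ratios 1.99 and 0.40 with a qualitative
#' interaction.
#'
#' @param n_samples Number of patients.
#' @param n_genes Gene universe size.
#' @param module_sizes Named integer vector `(pr, er, im)` of module gene
#'   counts; the default (16, 4, 11) sums to 31.
#' @param within_module_correlation Target gene-gene noise correlation
#'   within a module, in `[0, 1)`.
#' @param module_mean_shift Log2-units separation between latent high and
#'   low module states.
#' @param noise_sd Per-gene log2 noise standard deviation.
#' @param arm_probability Probability of palbociclib-first assignment
#'   (arm B).
#' @param module_state_rates Marginal probabilities that a sample's latent
#'   Pr / Er / Im state is high; defaults (0.75, 0.5, 0.5) mirror the
#'   classifier's Q1 / median / median call rates.
#' @param response_coefficients Length-4 vector `(intercept, arm, biomarker,
#'   interaction)` on the log-odds scale for the binary response; `arm` is 1
#'   for arm B.
#' @param outlier_count,outlier_shift Number of aberrant samples injected at
#'   generation time and their latent log2 shift (see [inject_outliers()]).
#' @param seed Integer seed; the single source of randomness.
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(n_samples = 163,
                       n_genes = 2000,
                       module_sizes = c(pr = 16, er = 4, im = 11),
                       within_module_correlation = 0.5,
                       module_mean_shift = 2,
                       noise_sd = 1,
                       arm_probability = 0.5,
                       module_state_rates = c(pr = 0.75, er = 0.5, im = 0.5),
                       response_coefficients = c(
                         intercept = stats::qlogis(0.656),
                         arm = log(0.40),
                         biomarker = stats::qlogis(0.316) - stats::qlogis(0.656),
                         interaction = log(1.99 / 0.40)),
                       outlier_count = 0,
                       outlier_shift = 0,
                       seed = 1) {
  stopifnot(n_samples >= 2, n_genes >= 1, length(module_sizes) == 3,
            all(module_sizes >= 1), length(module_state_rates) == 3,
            length(response_coefficients) == 4)
  if (sum(module_sizes) > n_genes)
    stop("module_sizes sum (", sum(module_sizes),
         ") exceeds n_genes (", n_genes, ")")
  if (within_module_correlation < 0 || within_module_correlation >= 1)
    stop("within_module_correlation must be in [0, 1)")
  if (arm_probability < 0 || arm_probability > 1)
    stop("arm_probability must be a probability")
  if (any(module_state_rates < 0 | module_state_rates > 1))
    stop("module_state_rates must be probabilities")
  if (any(!is.finite(response_coefficients)))
    stop("response_coefficients must be finite")
  if (outlier_count >= n_samples)
    stop("outlier_count must be smaller than n_samples")
  names(module_sizes) <- names(module_state_rates) <- c("pr", "er", "im")
  names(response_coefficients) <-
    c("intercept", "arm", "biomarker", "interaction")
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 module_sizes = as.integer(module_sizes) |>
                   stats::setNames(c("pr", "er", "im")),
                 within_module_correlation = within_module_correlation,
                 module_mean_shift = module_mean_shift,
                 noise_sd = noise_sd,
                 arm_probability = arm_probability,
                 module_state_rates = module_state_rates,
                 response_coefficients = response_coefficients,
                 outlier_count = as.integer(outlier_count),
                 outlier_shift = outlier_shift,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat("  samples:", x$n_samples, " genes:", x$n_genes,
      " modules (Pr/Er/Im):", paste(x$module_sizes, collapse = "/"), "\n")
  cat("  response log-odds: ",
      paste(sprintf("%s=%.3f", names(x$response_coefficients),
                    x$response_coefficients), collapse = ", "), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# Latent log2 expression for all samples. states: n x 3 0/1 matrix.
.latent_matrix <- function(cfg, baseline, states) {
  n <- cfg$n_samples
  g <- cfg$n_genes
  rho <- cfg$within_module_correlation
  sd <- cfg$noise_sd
  y <- matrix(baseline, g, n) +
    matrix(stats::rnorm(g * n, 0, sd * sqrt(1 - rho)), g, n)
  mod_idx <- .module_indices(cfg)
  for (m in 1:3) {
    idx <- mod_idx[[m]]
    shared <- stats::rnorm(n, 0, sd * sqrt(rho))
    y[idx, ] <- y[idx, ] +
      rep(shared + cfg$module_mean_shift * states[, m], each = length(idx))
    # non-module genes keep independent noise at full sd
  }
  other <- setdiff(seq_len(g), unlist(mod_idx))
  if (length(other) && rho > 0)
    y[other, ] <- y[other, ] +
      matrix(stats::rnorm(length(other) * n, 0, sd * sqrt(rho)),
             length(other), n)
  y
}

.module_indices <- function(cfg) {
  ms <- cfg$module_sizes
  list(pr = seq_len(ms[1]),
       er = ms[1] + seq_len(ms[2]),
       im = ms[1] + ms[2] + seq_len(ms[3]))
}

.counts_from_latent <- function(latent, lengths, depth) {
  mu <- (2^latent) * (lengths / 1000) * rep(depth, each = nrow(latent))
  cnt <- matrix(stats::rpois(length(mu), mu), nrow(latent), ncol(latent))
  dimnames(cnt) <- dimnames(latent)
  cnt
}

#' Simulate a synthetic two-arm cohort with known ground truth
#'
#' Per sample, latent high/low states are drawn independently for the three
#' modules at `module_state_rates`; the true biomarker label applies the
#' classifier rule (Pr high, Er high, Im low) to these noise-free states, so
#' truth does not depend on cohort composition. Latent log2 expression adds
#' the module mean shift and block-correlated noise, and counts are Poisson
#' draws around `2^latent * length/1000 * depth`. Treatment arm is
#' Bernoulli(`arm_probability`) and the binary response is Bernoulli with
#' log-odds `c0 + c1 arm + c2 label + c3 arm:label`. Everything is
#' reproducible from the config seed.
#'
#' @param config A [sim_config()].
#' @return Object of class `"synthetic_cohort"`: `counts`, `lengths`,
#'   `gene_sets` (Pr/Er/Im lists), `clinical` (data frame with sample_id,
#'   arm, orr12, orr24, pcr, rcb_class, ki67_baseline, ki67_week12,
#'   suv_baseline, suv_week12), and `truth` (latent states, labels,
#'   coefficients, outlier ids, latent matrix, depths).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    n <- config$n_samples
    g <- config$n_genes
    gene_ids <- sprintf("G%05d", seq_len(g))
    sample_ids <- sprintf("S%04d", seq_len(n))
    baseline <- stats::runif(g, 2, 8)
    lengths <- stats::setNames(round(stats::runif(g, 300, 5000)), gene_ids)
    depth <- exp(stats::rnorm(n, log(30), 0.2))
    states <- cbind(pr = stats::rbinom(n, 1, config$module_state_rates["pr"]),
                    er = stats::rbinom(n, 1, config$module_state_rates["er"]),
                    im = stats::rbinom(n, 1, config$module_state_rates["im"]))
    label <- states[, "pr"] == 1 & states[, "er"] == 1 & states[, "im"] == 0
    latent <- .latent_matrix(config, baseline, states)
    dimnames(latent) <- list(gene_ids, sample_ids)

    outlier_ids <- character(0)
    outlier_genes <- character(0)
    if (config$outlier_count > 0) {
      which_out <- sample.int(n, config$outlier_count)
      shift_genes <- sample.int(g, floor(g / 2))
      latent[shift_genes, which_out] <-
        latent[shift_genes, which_out] + config$outlier_shift
      outlier_ids <- sample_ids[which_out]
      outlier_genes <- gene_ids[shift_genes]
    }

    counts <- .counts_from_latent(latent, lengths, depth)

    cf <- config$response_coefficients
    arm_b <- stats::rbinom(n, 1, config$arm_probability)
    eta <- cf["intercept"] + cf["arm"] * arm_b + cf["biomarker"] * label +
      cf["interaction"] * arm_b * label
    orr12 <- stats::rbinom(n, 1, stats::plogis(eta))
    flip <- stats::rbinom(n, 1, 0.15) == 1   # late responses / progressions
    orr24 <- ifelse(flip, 1 - orr12, orr12)
    pcr <- stats::rbinom(n, 1, stats::plogis(-2.6 + 1.2 * orr12))
    rcb_class <- ifelse(pcr == 1, "0",
                        sample(c("I", "II", "III"), n, replace = TRUE,
                               prob = c(0.25, 0.5, 0.25)))
    ki67_baseline <- stats::runif(n, 8, 45)
    ki67_week12 <- pmin(100, ki67_baseline *
                          exp(stats::rnorm(n, log(0.2), 0.8)))
    suv_baseline <- exp(stats::rnorm(n, log(5.7), 0.4))
    # metabolic suppression stronger under chemotherapy (ratio 0.40 vs 0.53)
    ratio_mu <- ifelse(arm_b == 1, log(0.53), log(0.40))
    suv_week12 <- suv_baseline * exp(stats::rnorm(n, ratio_mu, 0.3))

    mod_idx <- .module_indices(config)
    gene_sets <- list(Pr = gene_ids[mod_idx$pr],
                      Er = gene_ids[mod_idx$er],
                      Im = gene_ids[mod_idx$im])
    clinical <- data.frame(sample_id = sample_ids,
                           arm = ifelse(arm_b == 1, "B", "A"),
                           orr12 = orr12, orr24 = orr24, pcr = pcr,
                           rcb_class = rcb_class,
                           ki67_baseline = ki67_baseline,
                           ki67_week12 = ki67_week12,
                           suv_baseline = suv_baseline,
                           suv_week12 = suv_week12,
                           stringsAsFactors = FALSE)
    structure(list(counts = counts,
                   lengths = lengths,
                   gene_sets = gene_sets,
                   clinical = clinical,
                   truth = list(states = states,
                                label = stats::setNames(label, sample_ids),
                                response_coefficients = cf,
                                outlier_ids = outlier_ids,
                                outlier_genes = outlier_genes,
                                latent = latent,
                                depth = stats::setNames(depth, sample_ids),
                                baseline = stats::setNames(baseline, gene_ids)),
                   config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic two-arm cohort: ", ncol(x$counts), " samples x ",
      nrow(x$counts), " genes (seed ", x$config$seed, ")\n", sep = "")
  cat("  arm A/B: ", sum(x$clinical$arm == "A"), "/",
      sum(x$clinical$arm == "B"),
      "; true biomarker-positive: ", sum(x$truth$label),
      sprintf(" (%.1f%%)\n", 100 * mean(x$truth$label)), sep = "")
  if (length(x$truth$outlier_ids))
    cat("  injected outliers:",
        paste(x$truth$outlier_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Inject aberrant-expression samples into a simulated cohort
#'
#' Adds `shift` log2 units to a random fraction of genes (default half) of
#' `k` randomly chosen samples on the latent scale and regenerates their
#' counts, recording the affected sample ids in the cohort truth. Shifting a
#' strict subset of genes makes the sample a compositional outlier that
#' survives depth normalization; `gene_fraction = 1` instead produces a pure
#' library-size shift, which normalization removes by design. Reproducible:
#' the injection stream is derived from the cohort seed.
#'
#' @param cohort A `"synthetic_cohort"`.
#' @param k Number of samples to perturb; must be `< n_samples`. `k = 0`
#'   returns the cohort unchanged.
#' @param shift Latent log2 shift added to the selected genes.
#' @param gene_fraction Fraction of genes shifted, in `(0, 1]`.
#' @return The modified cohort.
#' @export
inject_outliers <- function(cohort, k, shift, gene_fraction = 0.5) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  n <- ncol(cohort$counts)
  if (k >= n) stop("k must be smaller than the number of samples")
  if (k < 0) stop("k must be non-negative")
  if (gene_fraction <= 0 || gene_fraction > 1)
    stop("gene_fraction must be in (0, 1]")
  if (k == 0) return(cohort)
  .with_seed(cohort$config$seed + 104729L + k, {
    g <- nrow(cohort$counts)
    which_out <- sample.int(n, k)
    shift_genes <- sample.int(g, max(1, floor(g * gene_fraction)))
    latent <- cohort$truth$latent
    latent[shift_genes, which_out] <- latent[shift_genes, which_out] + shift
    new_counts <- .counts_from_latent(
      latent[, which_out, drop = FALSE],
      cohort$lengths,
      cohort$truth$depth[which_out])
    cohort$counts[, which_out] <- new_counts
    cohort$truth$latent <- latent
    cohort$truth$outlier_ids <-
      union(cohort$truth$outlier_ids, colnames(cohort$counts)[which_out])
    cohort$truth$outlier_genes <-
      union(cohort$truth$outlier_genes, rownames(cohort$counts)[shift_genes])
    cohort
  })
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes `counts.tsv`, `lengths.tsv`, `modules.gmt`, `clinical.csv` and
#' `truth.json` into a directory, in the formats the pipeline reads back.
#'
#' @param cohort A `"synthetic_cohort"`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(cohort$counts, file.path(dir, "counts.tsv"))
  utils::write.table(
    data.frame(gene_id = names(cohort$lengths), length = cohort$lengths),
    file.path(dir, "lengths.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_gmt(cohort$gene_sets, file.path(dir, "modules.gmt"))
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(label = as.list(stats::setNames(as.integer(cohort$truth$label),
                                         names(cohort$truth$label))),
         response_coefficients = as.list(cohort$truth$response_coefficients),
         outlier_ids = cohort$truth$outlier_ids,
         seed = cohort$config$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
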
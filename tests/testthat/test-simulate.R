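test_that("cohorts are reproducible from the seed and differ across seeds", {
  cfg <- sim_config(n_samples = 40, n_genes = 100, seed = 3)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  c2 <- simulate_cohort(sim_config(n_samples = 40, n_genes = 100, seed = 4))
  expect_false(identical(a$counts, c2$counts))
})

test_that("cohort structure satisfies its invariants", {
  cfg <- sim_config(n_samples = 50, n_genes = 120, seed = 9)
  co <- simulate_cohort(cfg)
  expect_true(all(co$counts >= 0))
  expect_true(all(co$counts == round(co$counts)))
  expect_identical(co$clinical$sample_id, colnames(co$counts))
  # module gene lists are disjoint subsets of the gene universe
  all_mod <- unlist(co$gene_sets)
  expect_identical(anyDuplicated(all_mod), 0L)
  expect_true(all(all_mod %in% rownames(co$counts)))
  # truth labels follow the generative rule exactly
  st <- co$truth$states
  expect_identical(unname(co$truth$label),
                   st[, "pr"] == 1 & st[, "er"] == 1 & st[, "im"] == 0)
  expect_true(all(co$clinical$arm %in% c("A", "B")))
  expect_true(all(co$clinical$orr12 %in% 0:1))
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(n_genes = 20, module_sizes = c(16, 4, 11)),
               "exceeds n_genes")
  expect_error(sim_config(within_module_correlation = 1), "\\[0, 1\\)")
  expect_error(sim_config(arm_probability = 1.2), "probability")
  expect_error(sim_config(response_coefficients = c(0, 0, 0, Inf)), "finite")
  expect_error(sim_config(n_samples = 50, outlier_count = 50),
               "smaller than n_samples")
})

test_that("null coefficients give ~50% response in both arms", {
  cfg <- sim_config(n_samples = 2000, n_genes = 40, module_mean_shift = 0,
                    response_coefficients = c(0, 0, 0, 0), seed = 15)
  co <- simulate_cohort(cfg)
  for (arm in c("A", "B")) {
    rate <- mean(co$clinical$orr12[co$clinical$arm == arm])
    expect_lt(abs(rate - 0.5), 0.045)  # ~3 binomial SEs at n ~ 1000
  }
})

test_that("true-label prevalence matches the analytic product of state rates", {
  cfg <- sim_config(n_samples = 4000, n_genes = 40, seed = 21)
  co <- simulate_cohort(cfg)
  # independent states at (0.75, 0.5, 0.5): P(+) = 0.1875
  se <- sqrt(0.1875 * 0.8125 / 4000)
  expect_lt(abs(mean(co$truth$label) - 0.1875), 3 * se)
})

test_that("within-module latent correlation approaches the configured value", {
  rho <- 0.5
  cfg <- sim_config(n_samples = 2000, n_genes = 60, module_mean_shift = 0,
                    within_module_correlation = rho, seed = 27)
  co <- simulate_cohort(cfg)
  lat <- co$truth$latent
  for (m in names(co$gene_sets)) {
    cm <- stats::cor(t(lat[co$gene_sets[[m]], ]))
    mean_cor <- mean(cm[upper.tri(cm)])
    expect_lt(abs(mean_cor - rho), 0.05)
  }
  # genes outside the modules stay uncorrelated
  other <- setdiff(rownames(lat), unlist(co$gene_sets))[1:10]
  co2 <- stats::cor(t(lat[other, ]))
  expect_lt(max(abs(co2[upper.tri(co2)])), 0.1)
})

test_that("logistic refit on truth recovers the response coefficients", {
  cfg <- sim_config(n_samples = 2000, n_genes = 40, seed = 33)
  co <- simulate_cohort(cfg)
  d <- data.frame(y = co$clinical$orr12,
                  arm = as.integer(co$clinical$arm == "B"),
                  lab = as.integer(co$truth$label))
  fit <- stats::glm(y ~ arm * lab, family = stats::binomial(), data = d)
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  truth <- co$truth$response_coefficients
  expect_true(all(abs(est - truth) < 2 * se))
})

test_that("outlier injection is null-safe and detectable by the QC stage", {
  cfg <- sim_config(n_samples = 100, n_genes = 300, seed = 41)
  co <- simulate_cohort(cfg)
  expect_identical(inject_outliers(co, 0, 5), co)
  expect_error(inject_outliers(co, 100, 5), "smaller than")

  # a large compositional shift on one sample is flagged exactly
  out <- inject_outliers(co, 1, 6)
  expect_length(out$truth$outlier_ids, 1)
  nr <- normalize_expression(out$counts, out$lengths)
  rep <- detect_outliers(nr$expression)
  expect_identical(rep$flagged_sample_ids, out$truth$outlier_ids)

  # zero shift leaves the QC verdict at its baseline
  base_rep <- detect_outliers(normalize_expression(co$counts,
                                                   co$lengths)$expression)
  null_inj <- inject_outliers(co, 1, 0)
  null_rep <- detect_outliers(normalize_expression(null_inj$counts,
                                                   null_inj$lengths)$expression)
  expect_identical(null_rep$flagged_sample_ids, base_rep$flagged_sample_ids)
})

test_that("cohorts round-trip through the plain-text writers", {
  co <- simulate_cohort(sim_config(n_samples = 12, n_genes = 60, seed = 2))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  cnt <- read_matrix_tsv(file.path(dir, "counts.tsv"))
  expect_equal(cnt, co$counts * 1.0)
  sets <- read_gmt(file.path(dir, "modules.gmt"))
  expect_identical(sets$Pr, co$gene_sets$Pr)
  cl <- utils::read.csv(file.path(dir, "clinical.csv"),
                        stringsAsFactors = FALSE)
  expect_identical(cl$sample_id, co$clinical$sample_id)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$seed, 2)
})
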
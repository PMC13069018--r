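test_that("low-count filter removes genes at the threshold and is idempotent", {
  m <- matrix(c(5, 5, 0,   # sum 10 -> removed
                6, 5, 0,   # sum 11 -> kept
                1, 1, 1),  # sum 3  -> removed
              nrow = 3, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"), c("s1", "s2", "s3")))
  f <- filter_low_counts(m, 10)
  expect_identical(rownames(f), "gB")
  expect_setequal(attr(f, "removed"), c("gA", "gC"))

  expect_error(filter_low_counts(m * 0, 10), "no genes remain")

  all_pos <- m + 10
  expect_equal(unclass(filter_low_counts(all_pos, 0))[, ],
               all_pos[, ], ignore_attr = TRUE)

  once <- filter_low_counts(m, 10)
  twice <- filter_low_counts(once, 10)
  expect_equal(unclass(twice)[, ], unclass(once)[, ], ignore_attr = TRUE)
})

test_that("length scaling divides by geometric-mean-normalized lengths", {
  cnt <- matrix(c(10, 10), 1, 2,
                dimnames = list("g1", c("s1", "s2")))
  # per-gene constant length: pass-through
  expect_equal(length_scale(cnt, c(g1 = 1000)), cnt * 1.0)
  # per-sample lengths (100, 400): geomean 200, normalized (0.5, 2)
  L <- matrix(c(100, 400), 1, 2, dimnames = dimnames(cnt))
  expect_equal(unname(length_scale(cnt, L)[1, ]), c(20, 5))
  # single sample: geomean of one value is itself
  one <- cnt[, 1, drop = FALSE]
  expect_equal(length_scale(one, L[, 1, drop = FALSE]), one * 1.0)
  expect_error(length_scale(cnt, c(g1 = 0)), "positive")
})

test_that("TMM factors match a direct evaluation of the published algorithm", {
  for (seed in c(11, 23, 31)) {
    m <- random_counts(200, 6, seed)
    f <- tmm_factors(m)
    expect_equal(unname(f), tmm_direct(m), tolerance = 1e-6)
    expect_equal(exp(mean(log(f))), 1, tolerance = 1e-9)
  }
})

test_that("TMM factors are 1 for identical or uniformly scaled libraries", {
  m <- random_counts(150, 2, 5)
  same <- cbind(s1 = m[, 1], s2 = m[, 1])
  expect_equal(unname(tmm_factors(same)), c(1, 1))
  doubled <- cbind(s1 = m[, 1] + 1, s2 = 2 * (m[, 1] + 1))
  expect_equal(unname(tmm_factors(doubled)), c(1, 1), tolerance = 1e-12)
  bad <- cbind(s1 = m[, 1], s2 = 0 * m[, 1])
  expect_error(tmm_factors(bad), "all-zero")
  expect_error(tmm_factors(m[, 1, drop = FALSE]), "2 samples")
})

test_that("log2 TMM-TPM columns behave like TPM", {
  # one sample, two genes, equal counts and lengths -> 500000 each
  cnt <- matrix(c(50, 50), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  nr <- normalize_expression(cnt, c(g1 = 1000, g2 = 1000), max_total = NULL)
  expect_equal(unname(2^nr$expression[, 1] - 1), c(5e5, 5e5))

  m <- random_counts(300, 5, 7)
  len <- stats::setNames(round(runif(300, 200, 3000)), rownames(m))
  nr <- normalize_expression(m, len, max_total = NULL)
  # TPM column sums equal 1e6 / TMM factor
  tpm <- 2^nr$expression - 1
  expect_equal(colSums(tpm), 1e6 / nr$tmm_factors, tolerance = 1e-8)
  # uniform scaling of one sample's counts: the depth change cancels exactly
  # gene-wise (constant TPM ratio); only the precision weights of the TMM
  # factor re-estimate move, by a small amount
  m2 <- m
  m2[, 3] <- m2[, 3] * 7
  nr2 <- normalize_expression(m2, len, max_total = NULL)
  ratio <- (2^nr2$expression[, 3] - 1) / (2^nr$expression[, 3] - 1)
  expect_lt(stats::sd(ratio) / mean(ratio), 1e-9)
  expect_lt(abs(log2(mean(ratio))), 0.1)
})

test_that("preprocessing is invariant to gene and sample order", {
  m <- random_counts(120, 6, 13) + 1
  len <- stats::setNames(round(runif(120, 200, 3000)), rownames(m))
  nr <- normalize_expression(m, len)
  gp <- sample(nrow(m)); sp <- sample(ncol(m))
  nr_perm <- normalize_expression(m[gp, sp], len[gp])
  expect_equal(nr_perm$expression[rownames(nr$expression),
                                  colnames(nr$expression)],
               nr$expression, tolerance = 1e-12)
  expect_equal(nr_perm$tmm_factors[names(nr$tmm_factors)], nr$tmm_factors,
               tolerance = 1e-12)
})

test_that("median-distance outlier rule flags shifted samples, strictly", {
  # all samples identical: distances 0, IQR 0, nothing flagged (strict >)
  m <- matrix(5, 50, 6,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  rep0 <- detect_outliers(m)
  expect_identical(rep0$flagged_sample_ids, character(0))
  expect_equal(rep0$threshold, 0)

  # 20 i.i.d. samples plus one shifted by 10 log2-units on all genes
  e <- random_expr(100, 21, 17)
  e[, 21] <- e[, 21] + 10
  rep1 <- detect_outliers(e)
  expect_identical(rep1$flagged_sample_ids, colnames(e)[21])

  expect_error(detect_outliers(e[, 1:3]), ">= 4 samples")
})

test_that("matrix TSV round-trips and outlier report serializes", {
  m <- random_counts(20, 4, 3)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(m, tf)
  expect_equal(read_matrix_tsv(tf), m * 1.0)

  e <- random_expr(30, 6, 4)
  rep <- detect_outliers(e)
  jf <- withr::local_tempfile(fileext = ".json")
  write_outlier_report(rep, jf)
  parsed <- jsonlite::read_json(jf)
  expect_equal(parsed$threshold, rep$threshold)
})
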
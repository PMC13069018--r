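test_that("count reconstruction inverts one-decimal rounding", {
  expect_equal(reconstruct_counts(43.3, n = 60),
               data.frame(events = 26L, n = 60L))
  # two rates constrained to a common total: unique split
  expect_equal(reconstruct_counts(c(47.8, 31.6), total = 42),
               data.frame(events = c(11L, 6L), n = c(23L, 19L)))
  # no integer count of 3 rounds to 50.0%
  expect_error(reconstruct_counts(50.0, n = 3), "no integer")
  # wide denominators make several counts round identically
  expect_error(reconstruct_counts(10.0, n = 2500), "ambiguous")
  expect_error(reconstruct_counts(150, n = 10), "\\[0, 100\\]")
})

test_that("Wald odds ratios reproduce closed-form values and symmetry", {
  r <- odds_ratio_wald(c(11, 12, 6, 13))
  expect_equal(round(r$odds_ratio, 2), 1.99)
  r2 <- odds_ratio_wald(c(26, 34, 40, 21))
  expect_equal(round(r2$odds_ratio, 2), 0.40)
  expect_equal(round(r2$ci_low, 2), 0.19)
  expect_true(r2$ci_low <= r2$odds_ratio && r2$odds_ratio <= r2$ci_high)

  sym <- odds_ratio_wald(c(5, 5, 5, 5))
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p_value, 1)

  # OR(a,b,c,d) * OR(b,a,d,c) = 1
  set.seed(8)
  for (i in 1:20) {
    cells <- sample(1:40, 4, replace = TRUE)
    o1 <- odds_ratio_wald(cells)$odds_ratio
    o2 <- odds_ratio_wald(cells[c(2, 1, 4, 3)])$odds_ratio
    expect_equal(o1 * o2, 1, tolerance = 1e-12)
  }

  # CI width shrinks as all cells scale up
  small <- odds_ratio_wald(c(6, 9, 8, 7))
  big <- odds_ratio_wald(10 * c(6, 9, 8, 7))
  expect_lt(log(big$ci_high / big$ci_low), log(small$ci_high / small$ci_low))

  expect_error(odds_ratio_wald(c(3, 0, 2, 5)), "haldane")
  hald <- odds_ratio_wald(c(3, 0, 2, 5), continuity = "haldane")
  expect_true(is.finite(hald$odds_ratio) && hald$odds_ratio > 0)
})

test_that("Fisher's exact test matches the hypergeometric tail", {
  expect_equal(fisher_exact(c(5, 5, 5, 5))$p_value, 1)

  # direct summation oracle for the (10,0,0,10) table: margins 10/10, n = 20
  probs <- dhyper(0:10, 10, 10, 10)
  p_direct <- sum(probs[probs <= dhyper(10, 10, 10, 10) * (1 + 1e-7)])
  r <- fisher_exact(c(10, 0, 0, 10))
  expect_lt(r$p_value, 1e-4)
  expect_equal(r$p_value, p_direct, tolerance = 1e-10)

  set.seed(12)
  for (i in 1:10) {
    cells <- matrix(sample(0:15, 4, replace = TRUE), 2)
    if (sum(cells) == 0) next
    expect_equal(fisher_exact(cells)$p_value,
                 fisher_exact(t(cells))$p_value, tolerance = 1e-12)
  }
})

test_that("interaction model reproduces stratum table odds ratios exactly", {
  d <- trial_interaction_data()
  fit <- logistic_interaction(d, "orr12", "arm", "biomarker")
  # saturated 2x2 strata: model ORs equal closed-form table ORs
  pos <- fit$strata[fit$strata$stratum == "positive", ]
  neg <- fit$strata[fit$strata$stratum == "negative", ]
  expect_equal(pos$odds_ratio, odds_ratio_wald(c(11, 12, 6, 13))$odds_ratio,
               tolerance = 1e-6)
  expect_equal(neg$odds_ratio, odds_ratio_wald(c(26, 34, 40, 21))$odds_ratio,
               tolerance = 1e-6)
  expect_equal(pos$ci_low, odds_ratio_wald(c(11, 12, 6, 13))$ci_low,
               tolerance = 1e-6)
  expect_true(fit$p_interaction > 0 && fit$p_interaction < 1)
})

test_that("interaction test is null when all four cells respond alike", {
  d <- rbind(expand_counts(c(5, 5), c(10, 10), arm = c("A", "B"),
                           biomarker = "neg"),
             expand_counts(c(5, 5), c(10, 10), arm = c("A", "B"),
                           biomarker = "pos"))
  fit <- logistic_interaction(d, "y", "arm", "biomarker")
  expect_equal(fit$p_interaction, 1, tolerance = 1e-8)
  expect_equal(fit$strata$odds_ratio, c(1, 1), tolerance = 1e-8)
})

test_that("degenerate cells are named instead of fitted", {
  d <- rbind(expand_counts(c(5, 0), c(10, 10), arm = c("A", "B"),
                           biomarker = "neg"),
             expand_counts(c(4, 6), c(10, 10), arm = c("A", "B"),
                           biomarker = "pos"))
  expect_error(logistic_interaction(d, "y", "arm", "biomarker"),
               "degenerate.*B x neg")
  expect_error(logistic_interaction(data.frame(arm = 1, y = 1), "y",
                                    "arm", "missing_col"), "missing column")
})

test_that("clinical metrics follow their defining formulas", {
  # CCCA boundary at Ki67 = 2.7%
  expect_true(ccca_call(2.7))
  expect_false(ccca_call(2.71))
  expect_true(ccca_call(0))
  expect_error(ccca_call(120), "\\[0, 100\\]")

  expect_equal(eastils_percent(20, 80), 25)
  expect_equal(eastils_percent(0, 50), 0)
  expect_equal(eastils_percent(20000, 80000), eastils_percent(20, 80))
  expect_error(eastils_percent(5, 0), "> 0")

  r <- suv_ratio(1, 0.53)
  expect_equal(r$relative_decrease_percent, 47)
  expect_equal(suv_ratio(4.2, 4.2)$relative_decrease_percent, 0)
  expect_equal(suv_ratio(3, 0)$ratio, 0)
  expect_equal(suv_ratio(3, 0)$relative_decrease_percent, 100)
  expect_error(suv_ratio(0, 1), "> 0")
})

test_that("association results export as a tidy stratified table", {
  d <- trial_interaction_data()
  fit <- logistic_interaction(d, "orr12", "arm", "biomarker")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_association_tsv(fit, tf)
  tab <- utils::read.delim(tf, stringsAsFactors = FALSE)
  expect_setequal(tab$stratum, c("positive", "negative", "interaction"))
  expect_equal(tab$p[tab$stratum == "interaction"], fit$p_interaction)
})
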
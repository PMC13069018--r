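# Contingency-table and logistic-regression statistics for two-arm trial
# endpoints, plus the simple clinical metrics (CCCA, easTILs%, SUVmax ratio)
# and integer reconstruction of counts from printed one-decimal rates.

.as_2x2 <- function(x) {
  if (is.matrix(x)) {
    if (!identical(dim(x), c(2L, 2L))) stop("expected a 2x2 table")
    m <- x
  } else {
    if (length(x) != 4) stop("expected 4 cell counts (a, b, c, d)")
    m <- matrix(as.numeric(x), 2, 2, byrow = TRUE)
  }
  if (any(m < 0) || any(!is.finite(m))) stop("cell counts must be non-negative")
  if (sum(m) == 0) stop("empty table")
  dimnames(m) <- list(group = c("g1", "g2"),
                      outcome = c("event", "no_event"))
  m
}

#' Reconstruct integer event counts from printed percentages
#'
#' Published tables often give response rates to one decimal without the
#' underlying counts. Given a rate and a known denominator, this finds the
#' integer event count consistent with one-decimal rounding
#' (`|100 r/n - rate| < 0.05`). Given two rates and only their combined
#' denominator, it searches all splits for the unique consistent
#' `(r1, n1, r2, n2)`. Multiple consistent solutions raise an ambiguity
#' error listing them; no solution is an error too.
#'
#' @param rates One rate, or two rates for the constrained-sum search
#'   (percent, one decimal).
#' @param n Known denominator (single-rate form).
#' @param total Combined denominator `n1 + n2` (two-rate form).
#' @return A data.frame with columns `events` and `n` (one row per rate).
#' @examples
#' reconstruct_counts(43.3, n = 60)              # 26 of 60
#' reconstruct_counts(c(47.8, 31.6), total = 42) # 11/23 and 6/19
#' @export
reconstruct_counts <- function(rates, n = NULL, total = NULL) {
  if (any(rates < 0 | rates > 100)) stop("rates must be in [0, 100]")
  consistent <- function(r, nn, rate) abs(100 * r / nn - rate) < 0.05
  if (length(rates) == 1 && !is.null(n)) {
    if (n <= 0) stop("n must be positive")
    r <- which(consistent(0:n, n, rates)) - 1L
    if (length(r) == 0)
      stop("no integer count in 0..", n, " rounds to ", rates, "%")
    if (length(r) > 1)
      stop("ambiguous: counts ", paste(r, collapse = ", "),
           " of ", n, " all round to ", rates, "%")
    return(data.frame(events = r, n = as.integer(n)))
  }
  if (length(rates) == 2 && !is.null(total)) {
    if (total < 2) stop("total must allow two non-empty groups")
    hits <- list()
    for (n1 in seq_len(total - 1)) {
      n2 <- total - n1
      r1 <- which(consistent(0:n1, n1, rates[1])) - 1L
      r2 <- which(consistent(0:n2, n2, rates[2])) - 1L
      if (length(r1) == 1 && length(r2) == 1)
        hits[[length(hits) + 1]] <- c(r1, n1, r2, n2)
      else if (length(r1) > 1 || length(r2) > 1)
        stop("ambiguous within-group counts at split ", n1, "+", n2)
    }
    if (length(hits) == 0)
      stop("no split of ", total, " is consistent with rates ",
           paste(rates, collapse = "% and "), "%")
    if (length(hits) > 1)
      stop("ambiguous: ", length(hits), " consistent splits of ", total, ": ",
           paste(vapply(hits, function(h)
             sprintf("%d/%d & %d/%d", h[1], h[2], h[3], h[4]),
             character(1)), collapse = "; "))
    h <- hits[[1]]
    return(data.frame(events = c(h[1], h[3]), n = c(h[2], h[4])))
  }
  stop("supply either one rate with 'n', or two rates with 'total'")
}

#' Odds ratio with Wald confidence interval from a 2x2 table
#'
#' Cells are `(a, b, c, d)` read row-wise: rows are the two treatment groups,
#' columns responder / non-responder, so `OR = (a d) / (b c)` compares the
#' odds of response in group 1 against group 2. The CI is
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` with
#' `z = qnorm(1 - alpha/2)`, and the p-value is the two-sided Wald test of
#' `log OR = 0`. With a zero cell the estimate is undefined; pass
#' `continuity = "haldane"` to add 0.5 to every cell.
#'
#' @param x 2x2 matrix or length-4 vector `(a, b, c, d)`.
#' @param alpha Two-sided level; default 0.05.
#' @param continuity `"none"` (error on zero cells) or `"haldane"`.
#' @return Object of class `"association"` with `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `method = "wald"`, `n`.
#' @export
odds_ratio_wald <- function(x, alpha = 0.05,
                            continuity = c("none", "haldane")) {
  continuity <- match.arg(continuity)
  m <- .as_2x2(x)
  if (any(m == 0)) {
    if (continuity == "none")
      stop("zero cell in 2x2 table; use continuity = \"haldane\" ",
           "to add 0.5 to all cells")
    m <- m + 0.5
  }
  a <- m[1, 1]; b <- m[1, 2]; cc <- m[2, 1]; d <- m[2, 2]
  lor <- log(a * d / (b * cc))
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  z <- stats::qnorm(1 - alpha / 2)
  structure(list(odds_ratio = exp(lor),
                 ci_low = exp(lor - z * se),
                 ci_high = exp(lor + z * se),
                 p_value = 2 * stats::pnorm(-abs(lor) / se),
                 method = "wald",
                 n = sum(.as_2x2(x)),
                 table = m),
            class = "association")
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value from [stats::fisher.test()] (summation of
#' hypergeometric probabilities no larger than the observed table's), with
#' the conditional maximum-likelihood odds ratio. Handles zero cells.
#'
#' @inheritParams odds_ratio_wald
#' @return An `"association"` object with `method = "fisher"`.
#' @export
fisher_exact <- function(x) {
  m <- .as_2x2(x)
  ft <- stats::fisher.test(m)
  structure(list(odds_ratio = unname(ft$estimate),
                 ci_low = ft$conf.int[1],
                 ci_high = ft$conf.int[2],
                 p_value = ft$p.value,
                 method = "fisher",
                 n = sum(m),
                 table = m),
            class = "association")
}

#' @export
print.association <- function(x, digits = 3, ...) {
  cat(sprintf("OR = %.*g (95%% CI %.*g-%.*g), p = %.3g [%s, n = %d]\n",
              digits, x$odds_ratio, digits, x$ci_low, digits, x$ci_high,
              x$p_value, x$method, as.integer(x$n)))
  invisible(x)
}

#' Treatment-by-biomarker interaction in a logistic model
#'
#' Fits `endpoint ~ arm + biomarker + arm:biomarker` by maximum likelihood on
#' complete cases and tests the interaction term with a two-sided likelihood
#' ratio test (a Wald test of the interaction coefficient is reported
#' alongside). Within each biomarker stratum the arm odds ratio and its Wald
#' CI are estimated by a stratum-specific logistic regression, so on a fully
#' cross-classified 2x2x2 table they coincide with the closed-form table
#' odds ratios.
#'
#' Cells of the arm-by-biomarker cross-classification in which every subject
#' has the same outcome make the stratum MLE diverge; these degenerate cells
#' are named in an error rather than silently returning an unbounded fit.
#'
#' @param data Data frame with the model variables.
#' @param endpoint Name of the binary endpoint column (0/1; NA dropped).
#' @param arm Name of the treatment column (two levels; the second level is
#'   the comparator in the reported odds ratios).
#' @param biomarker Name of the binary biomarker column (two levels; e.g. a
#'   CDKPredX label).
#' @param alpha Two-sided level for stratum CIs.
#' @return Object of class `"interaction_fit"`: per-stratum odds ratios with
#'   CIs and Wald p-values, `p_interaction` (LRT), `p_interaction_wald`, and
#'   the underlying [stats::glm] fit.
#' @export
logistic_interaction <- function(data, endpoint, arm = "arm",
                                 biomarker, alpha = 0.05) {
  need <- c(endpoint, arm, biomarker)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[need]), need]
  names(d) <- c("y", "arm", "bio")
  d$y <- as.numeric(d$y)
  if (!all(d$y %in% c(0, 1))) stop("endpoint must be binary 0/1")
  d$arm <- factor(d$arm)
  d$bio <- factor(d$bio)
  if (nlevels(d$arm) != 2 || nlevels(d$bio) != 2)
    stop("'arm' and 'biomarker' must each have exactly two observed levels")
  if (sum(d$y) == 0 || sum(d$y) == nrow(d))
    stop("endpoint has no events or no non-events")
  cells <- split(d$y, list(d$arm, d$bio), sep = " x ")
  degenerate <- names(cells)[vapply(cells, function(v)
    length(v) == 0 || all(v == v[1]), logical(1))]
  if (length(degenerate))
    stop("degenerate arm x biomarker cell(s) (all same outcome): ",
         paste(degenerate, collapse = "; "),
         " -- the interaction MLE does not exist")
  full <- stats::glm(y ~ arm * bio, family = stats::binomial(), data = d)
  reduced <- stats::glm(y ~ arm + bio, family = stats::binomial(), data = d)
  lrt_stat <- reduced$deviance - full$deviance
  p_lrt <- stats::pchisq(lrt_stat, df = 1, lower.tail = FALSE)
  cf <- summary(full)$coefficients
  p_wald <- cf[nrow(cf), 4]
  z <- stats::qnorm(1 - alpha / 2)
  strata <- do.call(rbind, lapply(levels(d$bio), function(lv) {
    ds <- d[d$bio == lv, ]
    fs <- stats::glm(y ~ arm, family = stats::binomial(), data = ds)
    cs <- summary(fs)$coefficients
    # arm coefficient: log-odds of response, first level = reference
    est <- cs[2, 1]; se <- cs[2, 2]
    data.frame(stratum = lv,
               odds_ratio = exp(est),
               ci_low = exp(est - z * se),
               ci_high = exp(est + z * se),
               p_value = cs[2, 4],
               n = nrow(ds),
               stringsAsFactors = FALSE)
  }))
  structure(list(strata = strata,
                 p_interaction = p_lrt,
                 lrt_statistic = lrt_stat,
                 p_interaction_wald = p_wald,
                 method = "lrt",
                 fit = full,
                 n = nrow(d),
                 arm_levels = levels(d$arm),
                 biomarker = biomarker,
                 endpoint = endpoint),
            class = "interaction_fit")
}

#' @export
print.interaction_fit <- function(x, digits = 3, ...) {
  cat("Treatment x biomarker interaction (", x$endpoint, " ~ ",
      x$arm_levels[2], " vs ", x$arm_levels[1], " x ", x$biomarker,
      ", n = ", x$n, ")\n", sep = "")
  s <- x$strata
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %s: OR = %.*g (95%% CI %.*g-%.*g), p = %.3g, n = %d\n",
                s$stratum[i], digits, s$odds_ratio[i], digits, s$ci_low[i],
                digits, s$ci_high[i], s$p_value[i], s$n[i]))
  cat(sprintf("  interaction: p = %.3g (LRT; Wald p = %.3g)\n",
              x$p_interaction, x$p_interaction_wald))
  invisible(x)
}

#' @export
coef.interaction_fit <- function(object, ...) stats::coef(object$fit)

#' @export
summary.interaction_fit <- function(object, ...) {
  out <- list(strata = object$strata,
              p_interaction = object$p_interaction,
              p_interaction_wald = object$p_interaction_wald,
              glm_summary = summary(object$fit))
  class(out) <- "summary.interaction_fit"
  out
}

#' @export
print.summary.interaction_fit <- function(x, ...) {
  print(x$strata, row.names = FALSE)
  cat(sprintf("interaction LRT p = %.4g (Wald %.4g)\n",
              x$p_interaction, x$p_interaction_wald))
  cat("\nFull model:\n")
  print(x$glm_summary$coefficients)
  invisible(x)
}

#' Write association results as a tidy TSV (one row per stratum)
#'
#' @param x An `"interaction_fit"` or `"association"` object, or a list of
#'   them.
#' @param path Output TSV path.
#' @export
write_association_tsv <- function(x, path) {
  rows <- function(obj, label) {
    if (inherits(obj, "association"))
      data.frame(stratum = label, estimate = obj$odds_ratio,
                 ci_low = obj$ci_low, ci_high = obj$ci_high,
                 p = obj$p_value, method = obj$method, n = obj$n)
    else if (inherits(obj, "interaction_fit"))
      rbind(data.frame(stratum = obj$strata$stratum,
                       estimate = obj$strata$odds_ratio,
                       ci_low = obj$strata$ci_low,
                       ci_high = obj$strata$ci_high,
                       p = obj$strata$p_value, method = "wald",
                       n = obj$strata$n),
            data.frame(stratum = "interaction", estimate = NA,
                       ci_low = NA, ci_high = NA, p = obj$p_interaction,
                       method = "lrt", n = obj$n))
    else stop("unsupported object of class ", class(obj)[1])
  }
  if (inherits(x, c("association", "interaction_fit"))) x <- list(result = x)
  if (is.null(names(x))) names(x) <- paste0("result", seq_along(x))
  tab <- do.call(rbind, Map(rows, x, names(x)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Complete cell cycle arrest call from Ki67
#'
#' On-treatment Ki67 of at most 2.7% defines complete cell cycle arrest
#' (CCCA); the boundary value 2.7 itself is arrested.
#'
#' @param ki67_percent Ki67-positive cell percentage(s) in `[0, 100]`.
#' @return Logical vector.
#' @export
ccca_call <- function(ki67_percent) {
  if (any(!is.na(ki67_percent) &
          (ki67_percent < 0 | ki67_percent > 100)))
    stop("Ki67 must be a percentage in [0, 100]")
  ki67_percent <= 2.7
}

#' Digital TIL surrogate: easTILs%
#'
#' `easTILs% = 100 * TIL cell area / stroma area`, both areas in the same
#' units (any unit cancels).
#'
#' @param til_cell_area,stroma_area Non-negative areas, identical units;
#'   `stroma_area` strictly positive.
#' @return Percentage value(s).
#' @export
eastils_percent <- function(til_cell_area, stroma_area) {
  if (any(stroma_area <= 0, na.rm = TRUE)) stop("stroma area must be > 0")
  if (any(til_cell_area < 0, na.rm = TRUE)) stop("TIL area must be >= 0")
  100 * til_cell_area / stroma_area
}

#' SUVmax metabolic response ratio
#'
#' Week-12 over baseline SUVmax ratio, with the corresponding relative
#' decrease `100 * (1 - ratio)` in percent (a ratio of 0.53 is a 47%
#' relative decrease).
#'
#' @param baseline Baseline SUVmax, strictly positive.
#' @param week12 Week-12 SUVmax, non-negative.
#' @return Data frame with columns `ratio` and `relative_decrease_percent`.
#' @export
suv_ratio <- function(baseline, week12) {
  if (any(baseline <= 0, na.rm = TRUE)) stop("baseline SUVmax must be > 0")
  if (any(week12 < 0, na.rm = TRUE)) stop("week-12 SUVmax must be >= 0")
  r <- week12 / baseline
  data.frame(ratio = r, relative_decrease_percent = 100 * (1 - r))
}

#' Expand arm-by-stratum event counts into subject-level rows
#'
#' Convenience for building an analysis data set from a 2x2(x2) count table,
#' e.g. counts reconstructed from printed rates via [reconstruct_counts()].
#'
#' @param events,n Vectors of event counts and group sizes (same length).
#' @param arm,biomarker Group labels (recycled to `length(events)`).
#' @return Data frame with columns `arm`, `biomarker`, `y` (0/1), one row
#'   per subject.
#' @export
expand_counts <- function(events, n, arm, biomarker = NA) {
  stopifnot(length(events) == length(n), all(events <= n), all(events >= 0))
  arm <- rep_len(arm, length(n))
  biomarker <- rep_len(biomarker, length(n))
  do.call(rbind, lapply(seq_along(n), function(i) {
    data.frame(arm = arm[i], biomarker = biomarker[i],
               y = rep(c(1, 0), c(events[i], n[i] - events[i])),
               stringsAsFactors = FALSE)
  }))
}
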
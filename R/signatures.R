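# Metagene scoring, cohort-quantile dichotomization, and the CDKPredX
# three-module classifier. All quantiles use linear interpolation between
# order statistics (stats::quantile type 7), fixed once for the package.

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated, fields name,
#' description, then gene ids. Parsing is delegated to
#' [fgsea::gmtPathways()]; this wrapper rejects duplicate set names and empty
#' sets and de-duplicates genes within a set.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (one per set), with attribute
#'   `"source"` recording the file path.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  sets <- fgsea::gmtPathways(path)
  if (length(sets) == 0) stop("no gene sets in ", path)
  if (anyDuplicated(names(sets)))
    stop("duplicate gene set name(s): ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, unique)
  empty <- lengths(sets) == 0
  if (any(empty))
    stop("empty gene set(s): ", paste(names(sets)[empty], collapse = ", "))
  attr(sets, "source") <- path
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Per-set description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  if (anyDuplicated(names(sets))) stop("duplicate gene set names")
  if (any(lengths(sets) == 0)) stop("cannot write empty gene sets")
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Per-sample metagene score for one gene set
#'
#' The unweighted arithmetic mean of log2 expression over the set's genes
#' present in the matrix. The score is only computed when at least
#' `min_fraction_present` of the set is present, the usual tolerance for
#' cross-platform application of published signatures; otherwise an error
#' names the missing genes.
#'
#' @param expr Log2 expression matrix (genes x samples).
#' @param genes Character vector of gene ids (one gene set).
#' @param min_fraction_present Minimum fraction of `genes` that must be rows
#'   of `expr`.
#' @return Named per-sample numeric vector with attribute `"missing"` listing
#'   set genes absent from the matrix.
#' @export
metagene_score <- function(expr, genes, min_fraction_present = 0.5) {
  stopifnot(is.matrix(expr), length(genes) > 0)
  genes <- unique(genes)
  present <- intersect(genes, rownames(expr))
  missing <- setdiff(genes, present)
  if (length(present) == 0 ||
      length(present) / length(genes) < min_fraction_present)
    stop(length(missing), " of ", length(genes),
         " gene-set genes missing from the expression matrix ",
         "(below min_fraction_present = ", min_fraction_present, "): ",
         paste(utils::head(missing, 20), collapse = ", "),
         if (length(missing) > 20) ", ..." else "")
  score <- colMeans(expr[present, , drop = FALSE])
  attr(score, "missing") <- missing
  score
}

#' Dichotomize scores at a cohort quantile
#'
#' Splits per-sample scores into `"high"`/`"low"` at the cohort median or
#' lower quartile (linear-interpolation quantile). Ties go high: a score
#' exactly at the threshold is called `"high"`, so a median split yields at
#' least 50% high deterministically. All-identical scores degenerate to
#' everything high, with a warning.
#'
#' @param scores Finite per-sample numeric vector, length >= 2.
#' @param rule `"median"` (0.5) or `"lower_quartile"` (0.25).
#' @return List with `call` (character vector of `"high"`/`"low"`) and
#'   `threshold`.
#' @export
dichotomize <- function(scores, rule = c("median", "lower_quartile")) {
  rule <- match.arg(rule)
  if (length(scores) < 2) stop("need at least 2 samples to dichotomize")
  if (any(!is.finite(scores))) stop("scores must be finite")
  q <- if (rule == "median") 0.5 else 0.25
  thr <- unname(stats::quantile(scores, q, type = 7))
  call <- ifelse(scores >= thr, "high", "low")
  names(call) <- names(scores)
  if (all(scores == scores[1]))
    warning("all scores identical; every sample called 'high'")
  list(call = call, threshold = thr)
}

#' Fit the CDKPredX three-module classifier to a cohort
#'
#' CDKPredX summarizes each tumor by three metagene scores — proliferation
#' (Pr), ER signalling (Er), and immune activity (Im) — each the mean log2
#' expression of its module genes, then dichotomizes each score at a
#' module-specific cohort quantile: the lower quartile for Pr and the median
#' for Er and Im (ties high). A sample is CDKPredX-positive when Pr is high,
#' Er is high and Im is low; all other samples are negative. Because the
#' permissive Q1 gate calls about 75% of samples Pr-high, independent modules
#' give an expected positive prevalence of 0.75 x 0.5 x 0.5 = 18.75%.
#'
#' "Fitting" here means deriving the three quantile thresholds from the
#' cohort at hand; [predict.cdkpredx()] applies the classifier to a new
#' cohort, either re-deriving the same quantile levels within it (default)
#' or transferring the fitted absolute thresholds.
#'
#' @param expr Log2 expression matrix (genes x samples), typically the
#'   `expression` element of [normalize_expression()].
#' @param modules Named list of gene-id vectors with elements `Pr`, `Er`,
#'   `Im` (e.g. from [read_gmt()]).
#' @param cohort Label recorded with the result.
#' @param min_fraction_present Passed to [metagene_score()].
#' @return An object of class `"cdkpredx"`: per-sample module scores and
#'   high/low calls, the positive/negative label, the fitted thresholds, and
#'   the module gene lists.
#' @seealso [predict.cdkpredx()], [metagene_score()], [dichotomize()]
#' @examples
#' set.seed(1)
#' expr <- matrix(rnorm(40 * 30, 6, 1), 40, 30,
#'                dimnames = list(sprintf("G%02d", 1:40), paste0("S", 1:30)))
#' mods <- list(Pr = sprintf("G%02d", 1:16), Er = sprintf("G%02d", 17:20),
#'              Im = sprintf("G%02d", 21:31))
#' fit <- cdkpredx(expr, mods)
#' print(fit)
#' table(fit$label)
#' @export
cdkpredx <- function(expr, modules, cohort = "derivation",
                     min_fraction_present = 0.5) {
  need <- c("Pr", "Er", "Im")
  if (!all(need %in% names(modules)))
    stop("'modules' must contain gene sets named Pr, Er and Im")
  pr <- metagene_score(expr, modules$Pr, min_fraction_present)
  er <- metagene_score(expr, modules$Er, min_fraction_present)
  im <- metagene_score(expr, modules$Im, min_fraction_present)
  pr_d <- dichotomize(pr, "lower_quartile")
  er_d <- dichotomize(er, "median")
  im_d <- dichotomize(im, "median")
  label <- ifelse(pr_d$call == "high" & er_d$call == "high" &
                    im_d$call == "low", "positive", "negative")
  tab <- data.frame(sample_id = colnames(expr),
                    pr_score = unname(pr), er_score = unname(er),
                    im_score = unname(im),
                    pr_call = unname(pr_d$call), er_call = unname(er_d$call),
                    im_call = unname(im_d$call), label = unname(label),
                    stringsAsFactors = FALSE)
  structure(list(samples = tab,
                 label = structure(label, names = colnames(expr)),
                 thresholds = c(pr = pr_d$threshold, er = er_d$threshold,
                                im = im_d$threshold),
                 quantile_levels = c(pr = 0.25, er = 0.5, im = 0.5),
                 modules = modules[need],
                 missing_genes = list(Pr = attr(pr, "missing"),
                                      Er = attr(er, "missing"),
                                      Im = attr(im, "missing")),
                 cohort = cohort),
            class = "cdkpredx")
}

#' @export
print.cdkpredx <- function(x, digits = 3, ...) {
  n <- nrow(x$samples)
  pos <- sum(x$samples$label == "positive")
  cat("CDKPredX classification (cohort: ", x$cohort, ")\n", sep = "")
  cat("  samples: ", n, "; positive: ", pos,
      sprintf(" (%.1f%%)\n", 100 * pos / n), sep = "")
  cat("  thresholds: Pr >= ", signif(x$thresholds["pr"], digits),
      " (Q1), Er >= ", signif(x$thresholds["er"], digits),
      " (median), Im < ", signif(x$thresholds["im"], digits),
      " (median)\n", sep = "")
  invisible(x)
}

#' @export
summary.cdkpredx <- function(object, ...) {
  s <- object$samples
  out <- list(cohort = object$cohort,
              n = nrow(s),
              prevalence = mean(s$label == "positive"),
              thresholds = object$thresholds,
              call_rates = c(pr_high = mean(s$pr_call == "high"),
                             er_high = mean(s$er_call == "high"),
                             im_high = mean(s$im_call == "high")),
              score_summary = rbind(Pr = summary(s$pr_score),
                                    Er = summary(s$er_score),
                                    Im = summary(s$im_score)))
  class(out) <- "summary.cdkpredx"
  out
}

#' @export
print.summary.cdkpredx <- function(x, ...) {
  cat("CDKPredX summary (cohort: ", x$cohort, ", n = ", x$n, ")\n", sep = "")
  cat(sprintf("  positive prevalence: %.1f%%\n", 100 * x$prevalence))
  cat("  module high-call rates: Pr ",
      sprintf("%.1f%%", 100 * x$call_rates["pr_high"]), ", Er ",
      sprintf("%.1f%%", 100 * x$call_rates["er_high"]), ", Im ",
      sprintf("%.1f%%", 100 * x$call_rates["im_high"]), "\n", sep = "")
  cat("  module score summaries:\n")
  print(round(x$score_summary, 3))
  invisible(x)
}

#' @export
coef.cdkpredx <- function(object, ...) object$thresholds

#' @export
as.data.frame.cdkpredx <- function(x, ...) x$samples

#' @export
plot.cdkpredx <- function(x, ...) {
  s <- x$samples
  pos <- s$label == "positive"
  graphics::plot(s$pr_score, s$im_score,
                 col = ifelse(pos, "firebrick", "grey40"),
                 pch = ifelse(s$er_call == "high", 19, 1),
                 xlab = "Pr module score (log2)",
                 ylab = "Im module score (log2)",
                 main = paste0("CDKPredX (", x$cohort, ")"), ...)
  graphics::abline(v = x$thresholds["pr"], h = x$thresholds["im"],
                   lty = 2, col = "grey60")
  graphics::legend("topleft", bty = "n",
                   legend = c("positive", "negative", "Er high", "Er low"),
                   col = c("firebrick", "grey40", "black", "black"),
                   pch = c(15, 15, 19, 1))
  invisible(x)
}

#' Apply a fitted CDKPredX classifier to an external cohort
#'
#' Default mode `"requantile"` re-derives the same quantile levels (Q1 for
#' Pr, median for Er and Im) within the new cohort, which keeps the
#' classifier comparable across platforms whose absolute expression scales
#' differ; labels are then invariant to any uniform monotone shift of the new
#' cohort. Mode `"absolute"` instead transfers the fitted thresholds on the
#' log2 scale unchanged.
#'
#' @param object A `"cdkpredx"` fit.
#' @param newdata Log2 expression matrix for the external cohort.
#' @param mode `"requantile"` (default) or `"absolute"`.
#' @param cohort Label recorded with the result.
#' @param ... Unused.
#' @return A `"cdkpredx"` object for the external cohort.
#' @export
predict.cdkpredx <- function(object, newdata,
                             mode = c("requantile", "absolute"),
                             cohort = "external", ...) {
  mode <- match.arg(mode)
  if (mode == "requantile")
    return(cdkpredx(newdata, object$modules, cohort = cohort))
  pr <- metagene_score(newdata, object$modules$Pr)
  er <- metagene_score(newdata, object$modules$Er)
  im <- metagene_score(newdata, object$modules$Im)
  thr <- object$thresholds
  calls <- list(pr = ifelse(pr >= thr["pr"], "high", "low"),
                er = ifelse(er >= thr["er"], "high", "low"),
                im = ifelse(im >= thr["im"], "high", "low"))
  label <- ifelse(calls$pr == "high" & calls$er == "high" &
                    calls$im == "low", "positive", "negative")
  tab <- data.frame(sample_id = colnames(newdata),
                    pr_score = unname(pr), er_score = unname(er),
                    im_score = unname(im),
                    pr_call = unname(calls$pr), er_call = unname(calls$er),
                    im_call = unname(calls$im), label = unname(label),
                    stringsAsFactors = FALSE)
  structure(list(samples = tab,
                 label = structure(label, names = colnames(newdata)),
                 thresholds = thr,
                 quantile_levels = object$quantile_levels,
                 modules = object$modules,
                 missing_genes = list(Pr = attr(pr, "missing"),
                                      Er = attr(er, "missing"),
                                      Im = attr(im, "missing")),
                 cohort = cohort,
                 mode = mode),
            class = "cdkpredx")
}

#' Write a CDKPredX result as TSV plus a JSON threshold sidecar
#'
#' @param x A `"cdkpredx"` object.
#' @param path Output TSV path; thresholds go to `<path>.thresholds.json`.
#' @export
write_cdkpredx <- function(x, path) {
  stopifnot(inherits(x, "cdkpredx"))
  utils::write.table(x$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(cohort = x$cohort,
                            thresholds = as.list(x$thresholds),
                            quantile_levels = as.list(x$quantile_levels)),
                       paste0(path, ".thresholds.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
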
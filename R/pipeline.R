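# End-to-end orchestration: a single YAML config drives simulate/load ->
# normalize -> QC -> classify -> associate -> enrich, writing every
# intermediate artifact plus a JSON manifest. Identical config + seed gives
# byte-identical outputs (logs go to stderr; the manifest carries no clock).

.default_thresholds <- function() {
  list(low_count_max = 10, pseudocount = 1, trim_m = 0.30, trim_a = 0.05,
       min_fraction_present = 0.5, padj_cut = 0.05, lfc_cut = 0.5,
       gsea_min_size = 10, gsea_max_size = 500, gsea_n_perm = 1000)
}

.default_stages <- function() {
  list(normalize = TRUE, qc = TRUE, classify = TRUE, associate = TRUE,
       gsea = FALSE)
}

.log_stage <- function(level, stage, msg, log_level = "info") {
  if (log_level == "quiet") return(invisible())
  message(sprintf("%s [%s] %s: %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), level, stage, msg))
}

#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes an equivalent list), checks the full
#' schema and collects every problem before failing: unknown keys, both or
#' neither of the `simulation` / `input` blocks, missing files, bad types,
#' and — when classification is enabled on file input — missing Pr/Er/Im
#' gene sets in the GMT. Valid configs come back with all defaults filled.
#'
#' @param config Path to a YAML file, or a list with the same structure.
#' @return Object of class `"pipeline_config"`; errors list all problems.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML mapping")
  errors <- character(0)
  known <- c("seed", "output_dir", "simulation", "input", "stages",
             "thresholds", "log_level")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    errors <- c(errors, paste0("unknown key(s): ",
                               paste(unknown, collapse = ", ")))
  has_sim <- !is.null(config$simulation)
  has_input <- !is.null(config$input)
  if (has_sim && has_input)
    errors <- c(errors,
                "exactly one of 'simulation' or 'input' must be given, not both")
  if (!has_sim && !has_input)
    errors <- c(errors, "one of 'simulation' or 'input' is required")
  if (is.null(config$seed)) config$seed <- 1L
  if (!is.numeric(config$seed) || length(config$seed) != 1)
    errors <- c(errors, "'seed' must be a single integer")
  if (is.null(config$output_dir)) config$output_dir <- "pipeline_out"
  if (is.null(config$log_level)) config$log_level <- "info"
  if (!config$log_level %in% c("info", "quiet"))
    errors <- c(errors, "'log_level' must be 'info' or 'quiet'")

  stages <- utils::modifyList(.default_stages(),
                              as.list(config$stages %||% list()))
  bad_stage <- setdiff(names(stages), names(.default_stages()))
  if (length(bad_stage))
    errors <- c(errors, paste0("unknown stage(s): ",
                               paste(bad_stage, collapse = ", ")))
  if (!all(vapply(stages, is.logical, logical(1))))
    errors <- c(errors, "stage toggles must be true/false")

  thr <- utils::modifyList(.default_thresholds(),
                           as.list(config$thresholds %||% list()))
  bad_thr <- setdiff(names(thr), names(.default_thresholds()))
  if (length(bad_thr))
    errors <- c(errors, paste0("unknown threshold(s): ",
                               paste(bad_thr, collapse = ", ")))
  num_thr <- setdiff(names(.default_thresholds()), bad_thr)
  for (k in num_thr)
    if (!is.numeric(thr[[k]]) || length(thr[[k]]) != 1)
      errors <- c(errors, paste0("threshold '", k, "' must be one number"))

  sim_cfg <- NULL
  if (has_sim && !has_input) {
    sim_args <- as.list(config$simulation)
    bad_sim <- setdiff(names(sim_args), names(formals(sim_config)))
    if (length(bad_sim))
      errors <- c(errors, paste0("unknown simulation key(s): ",
                                 paste(bad_sim, collapse = ", ")))
    else {
      if (is.null(sim_args$seed)) sim_args$seed <- config$seed
      sim_cfg <- tryCatch(do.call(sim_config, sim_args),
                          error = function(e) {
                            errors <<- c(errors,
                                         paste0("simulation block: ",
                                                conditionMessage(e)))
                            NULL
                          })
    }
  }
  if (has_input && !has_sim) {
    need <- c("counts", "lengths", "gene_sets", "clinical")
    miss <- setdiff(need, names(config$input))
    if (length(miss))
      errors <- c(errors, paste0("input block missing: ",
                                 paste(miss, collapse = ", ")))
    for (k in intersect(need, names(config$input)))
      if (!file.exists(config$input[[k]]))
        errors <- c(errors, paste0("input file not found (", k, "): ",
                                   config$input[[k]]))
    if (isTRUE(stages$classify) && "gene_sets" %in% names(config$input) &&
        file.exists(config$input$gene_sets)) {
      sets <- tryCatch(read_gmt(config$input$gene_sets),
                       error = function(e) NULL)
      missing_mod <- setdiff(c("Pr", "Er", "Im"), names(sets))
      if (length(missing_mod))
        errors <- c(errors,
                    paste0("classification enabled but gene set(s) absent ",
                           "from GMT: ", paste(missing_mod, collapse = ", ")))
    }
  }
  if (length(errors))
    stop("invalid pipeline config:\n  - ",
         paste(errors, collapse = "\n  - "))
  structure(list(seed = as.integer(config$seed),
                 output_dir = config$output_dir,
                 simulation = sim_cfg,
                 input = config$input,
                 stages = stages,
                 thresholds = thr,
                 log_level = config$log_level),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in fixed order — simulate or load, normalize,
#' sample QC, CDKPredX classification, biomarker-by-treatment association,
#' pre-ranked GSEA — writing each stage's artifact into the output directory
#' together with a run manifest (package version, seed, thresholds, per-stage
#' sample and gene accounting, and a per-sample ledger with exclusion
#' reasons). A stage failure aborts the run naming the stage; artifacts from
#' completed stages are retained.
#'
#' @param config A `"pipeline_config"` from [validate_config()], a path to a
#'   YAML config, or an equivalent list.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  thr <- config$thresholds
  lg <- function(stage, msg) .log_stage("info", stage, msg, config$log_level)
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  manifest <- list(package = "cdkpredx",
                   version = as.character(utils::packageVersion("cdkpredx")),
                   seed = config$seed,
                   thresholds = thr,
                   stages = list())
  ledger <- NULL  # sample_id, status, reason

  # --- data ---------------------------------------------------------------
  dat <- run_stage("data", function() {
    if (!is.null(config$simulation)) {
      lg("data", paste0("simulating cohort (n = ",
                        config$simulation$n_samples, ", seed = ",
                        config$simulation$seed, ")"))
      cohort <- simulate_cohort(config$simulation)
      write_cohort(cohort, file.path(out, "cohort"))
      list(counts = cohort$counts, lengths = cohort$lengths,
           gene_sets = cohort$gene_sets, clinical = cohort$clinical)
    } else {
      lg("data", "loading input files")
      counts <- read_matrix_tsv(config$input$counts)
      storage.mode(counts) <- "double"
      len_df <- utils::read.delim(config$input$lengths,
                                  stringsAsFactors = FALSE)
      lengths <- stats::setNames(len_df[[2]], len_df[[1]])[rownames(counts)]
      list(counts = counts, lengths = lengths,
           gene_sets = read_gmt(config$input$gene_sets),
           clinical = utils::read.csv(config$input$clinical,
                                      stringsAsFactors = FALSE))
    }
  })
  n0 <- ncol(dat$counts)
  ledger <- data.frame(sample_id = colnames(dat$counts),
                       status = "retained", reason = "",
                       stringsAsFactors = FALSE)
  manifest$stages$data <- list(n_samples = n0, n_genes = nrow(dat$counts))

  expr <- NULL
  if (isTRUE(config$stages$normalize)) {
    norm <- run_stage("normalize", function() {
      lg("normalize", "low-count filter + length scaling + TMM + log2 TPM")
      normalize_expression(dat$counts, dat$lengths,
                           max_total = thr$low_count_max,
                           pseudocount = thr$pseudocount,
                           trim_m = thr$trim_m, trim_a = thr$trim_a)
    })
    expr <- norm$expression
    write_matrix_tsv(expr, file.path(out, "expression.tsv"))
    manifest$stages$normalize <-
      list(genes_in = nrow(dat$counts), genes_out = nrow(expr),
           genes_filtered = length(norm$filtered_gene_ids),
           tmm_factors = as.list(norm$tmm_factors))
  }

  if (isTRUE(config$stages$qc)) {
    if (is.null(expr)) stop("stage 'qc' failed: requires 'normalize'")
    rep <- run_stage("qc", function() {
      lg("qc", "median-distance sample outlier detection")
      detect_outliers(expr)
    })
    write_outlier_report(rep, file.path(out, "outliers.json"))
    flagged <- rep$flagged_sample_ids
    if (length(flagged)) {
      ledger$status[ledger$sample_id %in% flagged] <- "excluded"
      ledger$reason[ledger$sample_id %in% flagged] <- "expression_outlier"
      expr <- expr[, setdiff(colnames(expr), flagged), drop = FALSE]
    }
    manifest$stages$qc <- list(n_in = n0, n_flagged = length(flagged),
                               n_out = ncol(expr),
                               flagged = flagged,
                               threshold = rep$threshold)
    lg("qc", paste0(length(flagged), " sample(s) excluded"))
  }

  fit <- NULL
  if (isTRUE(config$stages$classify)) {
    if (is.null(expr)) stop("stage 'classify' failed: requires 'normalize'")
    fit <- run_stage("classify", function() {
      lg("classify", "CDKPredX three-module classification")
      cdkpredx(expr, dat$gene_sets,
               min_fraction_present = thr$min_fraction_present)
    })
    write_cdkpredx(fit, file.path(out, "cdkpredx.tsv"))
    manifest$stages$classify <-
      list(n_classified = nrow(fit$samples),
           n_positive = sum(fit$samples$label == "positive"),
           thresholds = as.list(fit$thresholds))
  }

  if (isTRUE(config$stages$associate)) {
    if (is.null(fit)) stop("stage 'associate' failed: requires 'classify'")
    assoc <- run_stage("associate", function() {
      lg("associate", "biomarker x treatment association on orr12")
      cl <- dat$clinical[match(fit$samples$sample_id,
                               dat$clinical$sample_id), ]
      cl$cdkpredx <- fit$samples$label
      logistic_interaction(cl, endpoint = "orr12", arm = "arm",
                           biomarker = "cdkpredx")
    })
    write_association_tsv(assoc, file.path(out, "association.tsv"))
    manifest$stages$associate <-
      list(n = assoc$n,
           p_interaction = assoc$p_interaction,
           strata = lapply(seq_len(nrow(assoc$strata)), function(i)
             as.list(assoc$strata[i, ])))
  }

  if (isTRUE(config$stages$gsea)) {
    if (is.null(expr)) stop("stage 'gsea' failed: requires 'normalize'")
    enr <- run_stage("gsea", function() {
      lg("gsea", "differential ranking + pre-ranked GSEA")
      cl <- dat$clinical[match(colnames(expr), dat$clinical$sample_id), ]
      ranked <- differential_ranking(expr, cl$orr12)
      keep <- vapply(dat$gene_sets, function(s)
        sum(s %in% ranked$gene) >= thr$gsea_min_size, logical(1))
      if (!any(keep)) stop("no gene set reaches gsea_min_size")
      res <- preranked_gsea(ranked, dat$gene_sets[keep],
                            min_size = thr$gsea_min_size,
                            max_size = thr$gsea_max_size,
                            n_perm = thr$gsea_n_perm,
                            seed = config$seed)
      list(ranked = ranked, res = res)
    })
    write_enrichment_tsv(enr$ranked, file.path(out, "ranking.tsv"))
    write_enrichment_tsv(enr$res, file.path(out, "gsea.tsv"))
    manifest$stages$gsea <- list(n_sets = nrow(enr$res),
                                 n_perm = thr$gsea_n_perm)
  }

  manifest$sample_ledger <- lapply(seq_len(nrow(ledger)), function(i)
    as.list(ledger[i, ]))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  lg("done", paste0("artifacts in ", out))
  invisible(manifest)
}
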
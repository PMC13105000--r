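# End-to-end orchestration: score-immune -> call-scna -> associate ->
# tuson -> survival, with pre-flight input validation, a run manifest
# carrying content digests, and machine-readable skip reasons.

#' Build a pipeline configuration
#'
#' Paths may be `NULL`; stages whose inputs are absent are skipped (the
#' gene-level TiSG/iOG stage needs `cn_gene_path`, the cell-type stage
#' `celltype_path`, the survival stage `clinical_path`). All thresholds
#' default to the framework's standard values and are recorded in the run
#' manifest.
#'
#' @param expr_path expression TSV (genes x samples).
#' @param cn_arm_path arm-level copy-number TSV (features x samples).
#' @param clinical_path clinical TSV (optional; enables survival).
#' @param cn_gene_path gene-level copy-number TSV (optional; enables
#'   TiSG/iOG calling).
#' @param celltype_path cell-type score TSV (optional).
#' @param gain_thr,loss_thr association call thresholds (0.2 / -0.2).
#' @param low_pct,high_pct immune-class percentiles (30 / 30).
#' @param q_thr significance threshold on adjusted p (0.05).
#' @param p_filter cell-type association p filter (0.2).
#' @param surv_gain_thr,surv_loss_thr survival categorization thresholds
#'   (0.3 / -0.3).
#' @param min_n minimum usable samples per association model (20).
#' @param tumor_type cohort label.
#' @param seed seed recorded in the manifest (stages are deterministic
#'   given their inputs).
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(expr_path, cn_arm_path, clinical_path = NULL,
                            cn_gene_path = NULL, celltype_path = NULL,
                            gain_thr = 0.2, loss_thr = -0.2,
                            low_pct = 30, high_pct = 30, q_thr = 0.05,
                            p_filter = 0.2, surv_gain_thr = 0.3,
                            surv_loss_thr = -0.3, min_n = 20,
                            tumor_type = "cohort", seed = 1) {
  structure(as.list(environment()), class = "PipelineConfig")
}

#' Run the full association pipeline
#'
#' Validates every referenced input up front (a missing file aborts before
#' any computation), then executes the stages in order, writing one TSV
#' per result, a `MANIFEST.txt` with the effective configuration and the
#' MD5 digest of every input and output, and a human-readable
#' `summary.txt`. A stage failure writes a `FAILED` marker naming the
#' stage and re-raises.
#'
#' @param config a `PipelineConfig` from [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly; outputs on disk.
#' @export
run_pipeline <- function(config, out_dir) {
  kt_assert(inherits(config, "PipelineConfig"), "not a PipelineConfig")
  paths <- config[grepl("_path$", names(config))]
  paths <- paths[!vapply(paths, is.null, TRUE)]
  missing <- names(paths)[!vapply(paths, file.exists, TRUE)]
  if (length(missing) > 0)
    kt_stop(sprintf("missing input file(s): %s",
                    paste(sprintf("%s (%s)", missing,
                                  unlist(paths[missing])), collapse = ", ")),
            "karyotme_config_error")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(x, name) {
    p <- file.path(out_dir, name)
    write_table(x, p)
    outputs <<- c(outputs, p)
    p
  }
  stage <- "load"
  tryCatch({
    expr <- read_expression_matrix(config$expr_path)
    arm <- read_copy_number_table(config$cn_arm_path, level = "arm")

    stage <- "score-immune"
    is_tab <- binarize_immune_score(
      cytotoxic_immune_score(expr),
      low_pct = config$low_pct, high_pct = config$high_pct)
    emit(is_tab, "immune_score.tsv")

    stage <- "call-scna"
    calls <- call_scna(arm, gain_thr = config$gain_thr,
                       loss_thr = config$loss_thr)
    as_tab <- aneuploidy_score(arm)
    emit(unclass(calls), "scna_calls.tsv")
    emit(as_tab, "aneuploidy_score.tsv")

    stage <- "associate"
    models <- expand.grid(direction = c("gain", "loss"),
                          phenotype = c("cold", "hot"),
                          stringsAsFactors = FALSE)
    res <- do.call(rbind, lapply(seq_len(nrow(models)), function(i)
      fit_is_logistic(arm, calls, is_tab, as_tab,
                      direction = models$direction[i],
                      phenotype = models$phenotype[i],
                      min_n = config$min_n, tumor_type = config$tumor_type)))
    res <- bh_adjust(res)
    emit(res, "is_associations.tsv")
    landscape <- build_signed_landscape(
      res[res$phenotype == "cold", ], res[res$phenotype == "hot", ])
    emit(landscape, "is_landscape.tsv")

    if (!is.null(config$celltype_path)) {
      stage <- "associate-celltypes"
      cts <- load_celltype_scores(config$celltype_path, allowed = NULL)
      ct_res <- bh_adjust(rbind(
        fit_celltype_linear(arm, calls, cts, as_tab, "gain",
                            min_n = config$min_n,
                            tumor_type = config$tumor_type),
        fit_celltype_linear(arm, calls, cts, as_tab, "loss",
                            min_n = config$min_n,
                            tumor_type = config$tumor_type)))
      emit(ct_res, "celltype_associations.tsv")
      emit(filter_celltype_associations(
        ct_res[ct_res$direction == "gain", ],
        ct_res[ct_res$direction == "loss", ],
        p_max = config$p_filter), "celltype_filtered.tsv")
    }

    if (!is.null(config$cn_gene_path)) {
      stage <- "tuson"
      gene_cn <- read_copy_number_table(config$cn_gene_path, level = "gene")
      stats <- gene_immune_correlations(gene_cn, expr, is_tab,
                                        tumor_type = config$tumor_type)
      gene_calls <- call_scna(gene_cn, gain_thr = config$gain_thr,
                              loss_thr = config$loss_thr)
      stats <- call_iog_tisg(stats, classify_gene_regions(gene_calls),
                             q_thr = config$q_thr)
      emit(stats, "tuson_calls.tsv")
    }

    if (!is.null(config$clinical_path)) {
      stage <- "survival"
      clinical <- read_clinical_table(config$clinical_path)
      categories <- categorize_for_survival(arm,
                                            gain_thr = config$surv_gain_thr,
                                            loss_thr = config$surv_loss_thr)
      emit(cox_landscape(clinical, categories), "survival_landscape.tsv")
    }
  }, error = function(e) {
    writeLines(sprintf("FAILED at stage '%s': %s", stage,
                       conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop(e)
  })

  manifest <- c(
    sprintf("karyotme_version: %s",
            as.character(utils::packageVersion("karyotme"))),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    sprintf("seed: %d", as.integer(config$seed)),
    sprintf("tumor_type: %s", config$tumor_type),
    sprintf("thresholds: gain=%g loss=%g low_pct=%g high_pct=%g q=%g p_filter=%g surv_gain=%g surv_loss=%g min_n=%d",
            config$gain_thr, config$loss_thr, config$low_pct,
            config$high_pct, config$q_thr, config$p_filter,
            config$surv_gain_thr, config$surv_loss_thr, config$min_n),
    "inputs:",
    sprintf("  %s: %s md5=%s", names(paths), unlist(paths),
            tools::md5sum(unlist(paths))),
    "outputs:",
    sprintf("  %s md5=%s", basename(outputs), tools::md5sum(outputs)))
  writeLines(manifest, file.path(out_dir, "MANIFEST.txt"))
  writeLines(c("karyotme pipeline run",
               sprintf("outputs: %s",
                       paste(basename(outputs), collapse = ", "))),
             file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}
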
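#' Default run configuration
#'
#' All rule thresholds of the design and evaluation workflow with their
#' standard values: genome-wide GWAS significance p < 5e-8, 50 kb lncRNA
#' proximity window, 50 nt coding-transcript trim, 50 nt RNA-repeat trim
#' (panel level) and 120/150 nt probe-level trims, partial-probing windows
#' of 200 nt (CDS tail), 100 nt (penultimate exon) and 150 nt (final exon),
#' intronic-control margins 500/100/50 nt with 200 nt controls, spike-in
#' padding 30-to-50 nt, probing-share thresholds 0.5% (neuronal, inclusive)
#' and 5% (reference contexts, exclusive), CPM pseudocount 1, and a 1-read
#' detection rule. The configuration round-trips losslessly through YAML.
#'
#' @return nested list of class `capture_config`.
#' @export
capture_config <- function() {
  structure(list(
    design = list(
      gwas_p_threshold = 5e-8,
      lncrna_window_nt = 50000,
      coding_trim_nt = 50,
      rna_repeat_trim_nt = 50,
      rna_repeat_classes = c("rRNA", "tRNA", "7SK", "srpRNA"),
      nontarget_trim_nt = 150,
      probe_repeat_trim_nt = 120,
      cds_tail_nt = 200,
      penultimate_exon_nt = 100,
      final_exon_nt = 150,
      intronic_ann_margin_nt = 500,
      intronic_repeat_margin_nt = 100,
      intronic_est_margin_nt = 50,
      intronic_min_piece_nt = 200,
      intronic_control_nt = 200,
      ng_intronic_control_nt = 500,
      spike_min_len_nt = 30,
      spike_pad_to_nt = 50,
      neuronal_share_threshold = 0.005,
      encode_share_threshold = 0.05
    ),
    evaluate = list(
      pseudocount = 1,
      min_reads_detected = 1,
      min_replicates_detected = 1
    ),
    seed = 1L,
    log_level = "info"
  ), class = "capture_config")
}

#' Validate a run configuration
#' @param config `capture_config` (possibly modified).
#' @return `config`, invisibly; errors on invalid values.
#' @export
validate_config <- function(config) {
  d <- config$design
  nt_keys <- grep("_nt$", names(d), value = TRUE)
  for (k in nt_keys) {
    if (!is.numeric(d[[k]]) || is.na(d[[k]]) || d[[k]] < 0) {
      stop("config: ", k, " must be a non-negative number")
    }
  }
  if (d$gwas_p_threshold <= 0 || d$gwas_p_threshold > 1) {
    stop("config: gwas_p_threshold must be in (0, 1]")
  }
  for (k in c("neuronal_share_threshold", "encode_share_threshold")) {
    if (d[[k]] < 0 || d[[k]] > 1) stop("config: ", k, " must be in [0, 1]")
  }
  if (config$evaluate$pseudocount < 0) {
    stop("config: pseudocount must be non-negative")
  }
  invisible(config)
}

#' Read / write a configuration as YAML
#' @param path file path.
#' @return `capture_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- utils::modifyList(unclass(capture_config()), raw)
  class(cfg) <- "capture_config"
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @param config `capture_config` to write.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.log_msg <- function(config, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message("[captureseq] ", ...)
}

#' Run the full capture analysis workflow on a scenario bundle
#'
#' Wires the modules together in the study's order: simulate (or ingest) a
#' scenario, evaluate library- and gene-level enrichment, fit the
#' segmental-regression expression threshold, run spike-in QC, and assign
#' reference stages when a reference is given. Writes a JSON report plus
#' TSV tables when `outdir` is supplied; two runs with the same seed and
#' config produce identical reports.
#'
#' @param scenario scenario name for [make_scenario()], or a bundle already
#'   built by it.
#' @param config `capture_config`.
#' @param reference optional genes x stages reference expression matrix for
#'   stage correlation.
#' @param outdir optional output directory.
#' @return list of class `capture_report`.
#' @export
run_pipeline <- function(scenario = "tf-like", config = capture_config(),
                         reference = NULL, outdir = NULL) {
  validate_config(config)
  bundle <- if (is.character(scenario)) {
    .log_msg(config, "simulating scenario '", scenario, "' (seed ",
             config$seed, ")")
    make_scenario(scenario, seed = config$seed)
  } else {
    scenario
  }
  truth <- bundle$truth
  cm <- bundle$combined
  cpm <- cpm_normalize(cm)
  pre_cols <- cm$meta$phase == "pre"
  post_cols <- cm$meta$phase == "post"

  .log_msg(config, "library-level enrichment")
  target_ids <- truth$target_ids
  pre_frac <- apply(cm$counts[, pre_cols, drop = FALSE], 2, function(v) {
    on_target_fraction(panel = target_ids,
                       gene_counts = stats::setNames(v, rownames(cm$counts)))
  })
  post_frac <- apply(cm$counts[, post_cols, drop = FALSE], 2, function(v) {
    on_target_fraction(panel = target_ids,
                       gene_counts = stats::setNames(v, rownames(cm$counts)))
  })
  ef_samples <- sample_enrichment_factor(pre_frac, post_frac)

  .log_msg(config, "gene-level enrichment")
  targeted_genes <- truth$gene_ids[truth$targeted]
  enr <- gene_enrichment(
    pre_cpm = cpm[, pre_cols, drop = FALSE],
    post_cpm = cpm[, post_cols, drop = FALSE],
    targeted_genes = targeted_genes,
    pseudocount = config$evaluate$pseudocount)

  .log_msg(config, "segmental regression threshold")
  thr <- tryCatch(expression_threshold(enr), error = function(e) {
    .log_msg(config, "threshold fit failed: ", conditionMessage(e))
    NULL
  })

  .log_msg(config, "replicate variability")
  cv_res <- NULL
  if (sum(pre_cols) >= 2 && sum(post_cols) >= 2) {
    pre_cv <- replicate_cv(cpm[targeted_genes, , drop = FALSE],
                           which(pre_cols))
    post_cv <- replicate_cv(cpm[targeted_genes, , drop = FALSE],
                            which(post_cols))
    cv_res <- tryCatch(compare_cv(pre_cv, post_cv),
                       error = function(e) NULL)
  }

  .log_msg(config, "read-balance validation")
  pre_ids <- cm$meta$sample_id[pre_cols]
  post_ids <- cm$meta$sample_id[post_cols]
  n_pairs <- min(length(pre_ids), length(post_ids))
  post_on_target <- colSums(
    cm$counts[rownames(cm$counts) %in% target_ids, post_ids[seq_len(n_pairs)],
              drop = FALSE])
  balance <- validate_read_balance(
    stats::setNames(cm$library_size[pre_ids[seq_len(n_pairs)]],
                    paste0("pair", seq_len(n_pairs))),
    stats::setNames(post_on_target, paste0("pair", seq_len(n_pairs))))

  .log_msg(config, "spike-in QC")
  ladder <- bundle$ladder
  spike_rows <- match(ladder$spike_id, rownames(cm$counts))
  pre_spike <- rowMeans(cm$counts[spike_rows, pre_cols, drop = FALSE])
  post_spike <- rowMeans(cm$counts[spike_rows, post_cols, drop = FALSE])
  pre_total <- mean(cm$library_size[pre_cols])
  post_total <- mean(cm$library_size[post_cols])
  pre_cpkm <- stats::setNames(
    cpkm(pre_spike, ladder$length_nt, pre_total), ladder$spike_id)
  post_cpkm <- stats::setNames(
    cpkm(post_spike, ladder$length_nt, post_total), ladder$spike_id)
  thr_pre <- detection_threshold(
    ladder, cm$counts[spike_rows, pre_cols, drop = FALSE],
    min_reads = config$evaluate$min_reads_detected)
  thr_post <- detection_threshold(
    ladder, cm$counts[spike_rows, post_cols, drop = FALSE],
    min_reads = config$evaluate$min_reads_detected)
  tgt <- ladder$targeted
  spike_qc <- list(
    threshold_pre = thr_pre,
    threshold_post = thr_post,
    threshold_improvement = threshold_improvement(thr_pre, thr_post),
    correlation_pre = tryCatch(
      concentration_correlation(pre_cpkm[tgt], ladder[tgt, , drop = FALSE]),
      error = function(e) NULL),
    correlation_post = tryCatch(
      concentration_correlation(post_cpkm[tgt], ladder[tgt, , drop = FALSE]),
      error = function(e) NULL),
    slope_pre = tryCatch(
      loglog_slope(pre_cpkm[tgt], ladder[tgt, , drop = FALSE]),
      error = function(e) NULL),
    slope_post = tryCatch(
      loglog_slope(post_cpkm[tgt], ladder[tgt, , drop = FALSE]),
      error = function(e) NULL),
    depletion = depletion_factor(pre_cpkm, post_cpkm, ladder)
  )

  stage_res <- NULL
  if (!is.null(reference)) {
    .log_msg(config, "stage correlation")
    stage_res <- stage_correlation(cpm[, post_cols, drop = FALSE],
                                   reference)
  }

  report <- structure(list(
    scenario = bundle$name,
    seed = config$seed,
    sample_enrichment = list(
      pre_on_target = as.list(pre_frac),
      post_on_target = as.list(post_frac),
      ef = as.list(ef_samples),
      median_ef = median_sample_ef(ef_samples),
      expected_ef = truth$expected_ef
    ),
    gene_enrichment = enr,
    success_rate = attr(enr, "success_rate"),
    category_counts = as.list(table(enr$category)),
    expression_threshold = if (!is.null(thr)) list(
      threshold_cpm = thr$threshold_cpm,
      breakpoint_log10 = thr$fit$breakpoint,
      selected_model = thr$fit$selected_model
    ) else NULL,
    cv_comparison = cv_res,
    read_balance = balance,
    spikein_qc = spike_qc,
    stage_assignment = if (!is.null(stage_res)) stage_res$assignment
      else NULL
  ), class = "capture_report")

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(enr, file.path(outdir, "gene_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(balance, file.path(outdir, "read_balance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    json <- report
    json$gene_enrichment <- NULL  # table written as TSV
    json$read_balance <- NULL
    jsonlite::write_json(.jsonable(json), file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

.jsonable <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    lapply(unclass(x), .jsonable)
  } else {
    x
  }
}

#' @export
print.capture_report <- function(x, ...) {
  cat("capture_report (scenario ", x$scenario, ", seed ", x$seed, ")\n",
      "  median sample EF: ", signif(x$sample_enrichment$median_ef, 4),
      " (expected ", signif(x$sample_enrichment$expected_ef, 4), ")\n",
      "  gene categories: ",
      paste(names(x$category_counts), unlist(x$category_counts),
            sep = "=", collapse = ", "), "\n",
      "  enrichment success rate: ", signif(x$success_rate, 4), "%\n",
      sep = "")
  if (!is.null(x$expression_threshold)) {
    cat("  expression threshold: ",
        signif(x$expression_threshold$threshold_cpm, 3), " CPM (",
        x$expression_threshold$selected_model, " selected)\n", sep = "")
  }
  cat("  spike-in threshold improvement: ",
      signif(x$spikein_qc$threshold_improvement, 4), "-fold\n", sep = "")
  invisible(x)
}
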
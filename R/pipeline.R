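# End-to-end driver: normalization, dispersion estimation, the two
# quasi-likelihood contrasts, Cross-MAS partitioning, panel selection, and
# discriminability evaluation of the panel against all genes.

#' Run the full dosage differential-expression pipeline
#'
#' Stages: drop all-zero genes; TMM normalization; NB dispersion and
#' quasi-dispersion estimation; quasi-likelihood F-tests for the knockdown
#' and overexpression contrasts (BH correction and MAS ranking per
#' contrast); Cross-MAS partition (driver excluded); candidate pool from the
#' heads of the condition-unique sets; Spearman correlation of candidates
#' with the driver on pooled log2-CPM; correlation and directionality
#' filters; PCA + logistic-regression evaluation of the selected panel and,
#' for contrast, of all retained genes.
#'
#' @param counts Validated count matrix, genes x samples.
#' @param samples Validated sample table matching `counts`.
#' @param config A [pipeline_config()].
#' @return List of class `dosage_pipeline`: `config`, `norm`, `dispersions`,
#'   `deg_kd`, `deg_oe`, `partition`, `pool`, `rho`, `panel`, `logcpm`,
#'   `eval_panel`, `eval_all`, `n_genes_retained`.
#' @export
run_dosage_pipeline <- function(counts, samples, config = pipeline_config()) {
  validate_count_matrix(counts)
  validate_samples(samples, config$condition_labels, counts = counts)
  counts <- counts[, samples$sample_id, drop = FALSE]
  if (!config$driver_gene %in% rownames(counts)) {
    stop("driver gene '", config$driver_gene, "' not present in the count matrix")
  }

  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  if (!config$driver_gene %in% rownames(counts)) {
    stop("driver gene has zero counts in all samples")
  }

  norm <- tmm_factors(counts)
  offsets <- log(norm$effective_lib_sizes)
  design <- build_design(samples, config$condition_labels)

  disp <- estimate_dispersions(counts, design, offsets)
  deg_kd <- ql_ftest(counts, design, offsets, disp, "kd", config)
  deg_oe <- ql_ftest(counts, design, offsets, disp, "oe", config)

  partition <- crossmas_partition(deg_kd, deg_oe, config$driver_gene, config)
  pool <- candidate_pool(partition, config$top_k_per_set)
  logcpm <- cpm_matrix(counts, norm, log2 = TRUE,
                       prior_count = config$log_prior_count)
  rho <- if (nrow(pool) > 0) {
    spearman_with_driver(logcpm, config$driver_gene, pool$gene_id)
  } else {
    data.frame(gene_id = character(0), rho = numeric(0),
               zero_variance = logical(0), stringsAsFactors = FALSE)
  }
  panel <- select_panel(pool, rho, deg_kd, deg_oe, config)

  labels <- factor(samples$condition,
                   levels = unname(config$condition_labels[c("reference", "kd", "oe")]))
  eval_all <- evaluate_gene_set(logcpm, labels,
                                n_components = config$n_components,
                                ridge = config$ridge,
                                feature_set_label = "all retained genes")
  eval_panel <- NULL
  if (nrow(panel) >= 2) {
    eval_panel <- evaluate_gene_set(logcpm, labels, genes = panel$gene_id,
                                    n_components = min(config$n_components,
                                                       nrow(panel)),
                                    ridge = config$ridge,
                                    feature_set_label = "selected panel")
  } else if (nrow(panel) > 0) {
    warning("panel has fewer than 2 genes; skipping panel evaluation")
  }

  structure(list(config = config, norm = norm, dispersions = disp,
                 deg_kd = deg_kd, deg_oe = deg_oe, partition = partition,
                 pool = pool, rho = rho, panel = panel, logcpm = logcpm,
                 eval_panel = eval_panel, eval_all = eval_all,
                 n_genes_retained = nrow(counts)),
            class = "dosage_pipeline")
}

#' @export
print.dosage_pipeline <- function(x, ...) {
  up_kd <- sum(x$deg_kd$significant & x$deg_kd$log2fc > 0)
  dn_kd <- sum(x$deg_kd$significant & x$deg_kd$log2fc < 0)
  up_oe <- sum(x$deg_oe$significant & x$deg_oe$log2fc > 0)
  dn_oe <- sum(x$deg_oe$significant & x$deg_oe$log2fc < 0)
  cat("Dosage differential-expression pipeline\n")
  cat(sprintf("  genes retained: %d\n", x$n_genes_retained))
  cat(sprintf("  KD vs %s DEGs: %d up, %d down\n",
              x$config$condition_labels[["reference"]], up_kd, dn_kd))
  cat(sprintf("  OE vs %s DEGs: %d up, %d down\n",
              x$config$condition_labels[["reference"]], up_oe, dn_oe))
  cat(sprintf("  unique sets (up/down): KD %d/%d, OE %d/%d; shared %d/%d; discordant %d\n",
              nrow(x$partition$kd_only_up), nrow(x$partition$kd_only_down),
              nrow(x$partition$oe_only_up), nrow(x$partition$oe_only_down),
              nrow(x$partition$shared_up), nrow(x$partition$shared_down),
              nrow(x$partition$discordant)))
  cat(sprintf("  candidate pool: %d genes; panel: %d genes\n",
              nrow(x$pool), nrow(x$panel)))
  if (!is.null(x$eval_panel)) {
    cat(sprintf("  training accuracy: panel %.3f, all genes %.3f\n",
                x$eval_panel$accuracy, x$eval_all$accuracy))
  }
  invisible(x)
}

#' Write all pipeline artifacts to a directory
#'
#' Writes `norm_factors.tsv`, `deg_kd.tsv`, `deg_oe.tsv`,
#' `crossmas_partition.tsv`, `panel.tsv`, and `classification_report.json`
#' (panel report when available, otherwise the all-genes report).
#'
#' @param res A `dosage_pipeline` result.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the output directory.
#' @export
write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  nf <- data.frame(sample_id = names(res$norm$factors),
                   factor = unname(res$norm$factors),
                   lib_size = unname(res$norm$lib_sizes),
                   stringsAsFactors = FALSE)
  .write_table(nf, file.path(outdir, "norm_factors.tsv"))
  write_deg_table(res$deg_kd, file.path(outdir, "deg_kd.tsv"))
  write_deg_table(res$deg_oe, file.path(outdir, "deg_oe.tsv"))
  write_partition(res$partition, file.path(outdir, "crossmas_partition.tsv"))
  write_panel(res$panel, file.path(outdir, "panel.tsv"))
  report <- if (!is.null(res$eval_panel)) res$eval_panel else res$eval_all
  write_classification_report(report, file.path(outdir, "classification_report.json"))
  invisible(outdir)
}
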
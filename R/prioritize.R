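# Biomarker panel selection: candidate pool from the heads of the
# condition-unique Cross-MAS sets, Spearman correlation of each candidate
# with the driver gene across all samples, and the directionality rule
# (down in knockdown, or up in overexpression).

#' Candidate gene pool from a Cross-MAS partition
#'
#' Takes the first `min(k, set size)` genes from each of the four
#' condition-unique sets in their per-set rank order. Disjointness of the
#' sets makes duplicates impossible; the pool has at most `4 * k` genes.
#'
#' @param partition A `crossmas_partition`.
#' @param k Number of genes taken per unique set.
#' @return Data frame `gene_id`, `source` (the originating set), `rank`.
#' @export
candidate_pool <- function(partition, k = 10L) {
  stopifnot(inherits(partition, "crossmas_partition"), k >= 0)
  sets <- c("kd_only_up", "kd_only_down", "oe_only_up", "oe_only_down")
  rows <- lapply(sets, function(s) {
    df <- utils::head(partition[[s]], k)
    if (nrow(df) == 0) return(NULL)
    data.frame(gene_id = df$gene_id, source = s, rank = df$rank,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), source = character(0),
                      rank = integer(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Spearman correlation of genes with the driver gene
#'
#' Rank correlation (average ranks for ties) between each listed gene and the
#' driver, computed on all samples of all three conditions pooled. A gene
#' with zero variance across samples gets `rho = 0` and a `zero_variance`
#' flag (with a warning), never `NaN`.
#'
#' @param logexpr Expression matrix (typically log2-CPM), genes x samples.
#' @param driver_gene Driver gene identifier (must be a row of `logexpr`).
#' @param genes Character vector of gene identifiers to correlate.
#' @return Data frame `gene_id`, `rho`, `zero_variance`.
#' @export
spearman_with_driver <- function(logexpr, driver_gene, genes) {
  if (!driver_gene %in% rownames(logexpr)) {
    stop("driver gene '", driver_gene, "' not present in the expression matrix")
  }
  if (ncol(logexpr) < 3) stop("at least 3 samples required for correlation")
  missing <- setdiff(genes, rownames(logexpr))
  if (length(missing) > 0) {
    stop("gene(s) not in the expression matrix: ", paste(missing, collapse = ", "))
  }
  d <- logexpr[driver_gene, ]
  if (stats::sd(d) == 0) warning("driver gene has zero variance across samples")
  rho <- numeric(length(genes))
  zv <- logical(length(genes))
  for (i in seq_along(genes)) {
    x <- logexpr[genes[i], ]
    if (stats::sd(x) == 0 || stats::sd(d) == 0) {
      rho[i] <- 0
      zv[i] <- TRUE
    } else {
      rho[i] <- stats::cor(x, d, method = "spearman")
    }
  }
  if (any(zv)) {
    warning("zero-variance gene(s), rho set to 0: ",
            paste(genes[zv], collapse = ", "))
  }
  data.frame(gene_id = genes, rho = rho, zero_variance = zv,
             stringsAsFactors = FALSE)
}

#' Select the dosage-sensitive gene panel
#'
#' From the candidate pool, keeps genes with `|rho|` strictly above the
#' threshold, then applies the directionality rule: only genes from the
#' unique down-in-knockdown set (log2FC < 0 in KD, guaranteed by construction
#' and asserted) and the unique up-in-overexpression set (log2FC > 0 in OE)
#' are retained; unique up-in-KD and down-in-OE genes are excluded. The
#' result is sorted by `|rho|` descending.
#'
#' @param pool Candidate pool from [candidate_pool()].
#' @param rho Correlations from [spearman_with_driver()].
#' @param kd,oe DEG tables of the two contrasts.
#' @param config A [pipeline_config()].
#' @param require_positive_rho Optional stricter sign-coherence filter
#'   (`rho > rho_threshold` instead of `|rho| > rho_threshold`); off by
#'   default.
#' @return Data frame of class `gene_panel`: `gene_id`, `source` (`kd_down`
#'   or `oe_up`), `log2fc` (from the source contrast), `rho`, `p_bh`.
#' @export
select_panel <- function(pool, rho, kd, oe, config = pipeline_config(),
                         require_positive_rho = FALSE) {
  m <- merge(pool, rho, by = "gene_id", sort = FALSE)
  keep_rho <- if (require_positive_rho) {
    m$rho > config$rho_threshold
  } else {
    abs(m$rho) > config$rho_threshold
  }
  m <- m[keep_rho & m$source %in% c("kd_only_down", "oe_only_up"), , drop = FALSE]
  if (nrow(m) == 0) {
    warning("empty panel: no candidate passed the correlation and directionality filters")
    out <- data.frame(gene_id = character(0), source = character(0),
                      log2fc = numeric(0), rho = numeric(0), p_bh = numeric(0),
                      stringsAsFactors = FALSE)
    return(structure(out, class = c("gene_panel", "data.frame")))
  }
  lfc_kd <- stats::setNames(kd$log2fc, kd$gene_id)
  p_kd <- stats::setNames(kd$p_bh, kd$gene_id)
  lfc_oe <- stats::setNames(oe$log2fc, oe$gene_id)
  p_oe <- stats::setNames(oe$p_bh, oe$gene_id)
  from_kd <- m$source == "kd_only_down"
  out <- data.frame(
    gene_id = m$gene_id,
    source = ifelse(from_kd, "kd_down", "oe_up"),
    log2fc = ifelse(from_kd, lfc_kd[m$gene_id], lfc_oe[m$gene_id]),
    rho = m$rho,
    p_bh = ifelse(from_kd, p_kd[m$gene_id], p_oe[m$gene_id]),
    stringsAsFactors = FALSE
  )
  bad <- (out$source == "kd_down" & out$log2fc >= 0) |
    (out$source == "oe_up" & out$log2fc <= 0)
  if (any(bad)) {
    stop("internal error: unique-set membership inconsistent with fold-change sign for ",
         paste(out$gene_id[bad], collapse = ", "))
  }
  if (config$driver_gene %in% out$gene_id) {
    stop("internal error: driver gene reached the panel")
  }
  out <- out[order(-abs(out$rho), out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("gene_panel", "data.frame"))
}

#' Write a gene panel table
#'
#' Columns: `gene_id`, `source`, `log2FC`, `rho`, `FDR`.
#'
#' @param panel A `gene_panel`.
#' @param path Output path.
#' @export
write_panel <- function(panel, path) {
  out <- data.frame(gene_id = panel$gene_id, source = panel$source,
                    log2FC = panel$log2fc, rho = panel$rho, FDR = panel$p_bh,
                    stringsAsFactors = FALSE)
  .write_table(out, path)
  invisible(path)
}
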
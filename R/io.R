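# Readers, writers and validated containers for the pipeline's tabular
# artifacts. All readers validate invariants and fail loudly; all writers
# serialise doubles with 17 significant digits so writer %then% reader is the
# identity on valid artifacts.

.detect_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

# 17 significant digits: enough to round-trip an IEEE double exactly.
.write_table <- function(df, path, sep = "\t") {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
}

#' Validate a raw count matrix
#'
#' Checks the invariants of the count-matrix container: unique gene and sample
#' identifiers, at least two samples, and non-negative integral counts.
#'
#' @param counts Numeric matrix, genes in rows, samples in columns, with
#'   `rownames` (gene identifiers) and `colnames` (sample identifiers).
#' @return Invisibly, the validated matrix.
#' @export
validate_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("counts must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix must carry gene identifiers (rownames) and sample identifiers (colnames)")
  }
  dup_g <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_g) > 0) {
    stop("duplicated gene identifiers: ", paste(dup_g, collapse = ", "))
  }
  dup_s <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_s) > 0) {
    stop("duplicated sample identifiers: ", paste(dup_s, collapse = ", "))
  }
  if (ncol(counts) < 2) stop("count matrix must have at least 2 samples")
  if (any(!is.finite(counts))) stop("counts must be finite")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integral")
  invisible(counts)
}

#' Read a gene-by-sample count matrix
#'
#' Expects genes in rows (first column gene identifiers, header row of sample
#' identifiers), the orientation used by GEO supplementary count tables. Use
#' `transpose = TRUE` for samples-in-rows files.
#'
#' @param path Path to a TSV (or CSV) count table.
#' @param sep Field separator; inferred from the file extension when `NULL`.
#' @param transpose If `TRUE`, the file is samples x genes and is transposed
#'   after reading.
#' @return Validated numeric matrix of counts, genes x samples.
#' @export
read_counts <- function(path, sep = NULL, transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .detect_sep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2) stop("count table must have a gene-id column and at least one sample column")
  ids <- df[[1]]
  num <- df[-1]
  for (j in seq_along(num)) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    bad <- which(is.na(v) & !is.na(num[[j]]) & nzchar(num[[j]]))
    bad <- c(bad, which(is.na(num[[j]])))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value at row %d, column '%s'",
                   bad[1], colnames(num)[j]))
    }
    num[[j]] <- v
  }
  m <- as.matrix(num)
  rownames(m) <- ids
  if (transpose) m <- t(m)
  validate_count_matrix(m)
  m
}

#' Write a count matrix
#'
#' @param counts Validated count matrix (genes x samples).
#' @param path Output path.
#' @param sep Field separator; inferred from the extension when `NULL`.
#' @export
write_counts <- function(counts, path, sep = NULL) {
  validate_count_matrix(counts)
  sep <- .detect_sep(path, sep)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_table(df, path, sep = sep)
  invisible(path)
}

#' Validate a sample metadata table
#'
#' @param samples Data frame with columns `sample_id` and `condition`.
#' @param condition_labels Named character vector giving the labels of the
#'   three condition roles, e.g. `c(reference = "WT", kd = "KD", oe = "OE")`.
#' @param counts Optional count matrix; when supplied, sample identifiers must
#'   match its columns exactly.
#' @return Invisibly, the validated table.
#' @export
validate_samples <- function(samples, condition_labels = default_condition_labels(),
                             counts = NULL) {
  if (!is.data.frame(samples) || !all(c("sample_id", "condition") %in% names(samples))) {
    stop("samples must be a data frame with columns 'sample_id' and 'condition'")
  }
  dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
  if (length(dup) > 0) stop("duplicated sample identifiers: ", paste(dup, collapse = ", "))
  unknown <- setdiff(unique(samples$condition), condition_labels)
  if (length(unknown) > 0) {
    stop("unknown condition label(s) ", paste(unknown, collapse = ", "),
         "; allowed labels: ", paste(condition_labels, collapse = ", "))
  }
  tab <- table(factor(samples$condition, levels = condition_labels))
  if (any(tab < 2)) {
    stop("each condition needs at least 2 samples (replication for the GLM); short: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  if (!is.null(counts)) {
    if (!setequal(samples$sample_id, colnames(counts)) ||
        nrow(samples) != ncol(counts)) {
      stop("sample identifiers do not match the count matrix columns")
    }
  }
  invisible(samples)
}

#' Default condition labels
#'
#' The three condition roles of a dosage experiment: reference (wild type),
#' driver knockdown, driver overexpression.
#'
#' @return Named character vector with entries `reference`, `kd`, `oe`.
#' @export
default_condition_labels <- function() {
  c(reference = "WT", kd = "KD", oe = "OE")
}

#' Read a sample metadata table
#'
#' @inheritParams validate_samples
#' @param path Path to a two-column (sample_id, condition) TSV/CSV.
#' @param sep Field separator; inferred from the extension when `NULL`.
#' @return Validated data frame with columns `sample_id`, `condition`.
#' @export
read_metadata <- function(path, condition_labels = default_condition_labels(),
                          sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .detect_sep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "")
  if (!all(c("sample_id", "condition") %in% names(df))) {
    names(df)[1:2] <- c("sample_id", "condition")
  }
  df <- df[, c("sample_id", "condition")]
  validate_samples(df, condition_labels)
  df
}

#' Write a sample metadata table
#' @param samples Validated sample table.
#' @param path Output path.
#' @param sep Field separator; inferred from the extension when `NULL`.
#' @export
write_metadata <- function(samples, path, sep = NULL) {
  sep <- .detect_sep(path, sep)
  .write_table(samples[, c("sample_id", "condition")], path, sep = sep)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields `name`, `description`,
#' then member genes. Duplicate members within a line are dropped; empty sets
#' are dropped with a warning.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of unique member genes.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    # keep trailing empty fields so "name<TAB>desc<TAB>" parses as 3 fields
    fields <- strsplit(paste0(lines[[i]], "\tEND"), "\t", fixed = TRUE)[[1]]
    fields <- fields[-length(fields)]
    if (length(fields) < 3) {
      stop(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields", i))
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      warning(sprintf("dropping empty gene set '%s' (line %d)", fields[1], i))
      next
    }
    sets[[fields[1]]] <- members
  }
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a per-contrast differential expression table
#'
#' Columns written: `gene_id`, `log2FC`, `PValue`, `FDR`, `MAS`, `rank`,
#' `significant`, `direction`.
#'
#' @param tab DEG table as returned by [ql_ftest()].
#' @param path Output path.
#' @param sep Field separator; inferred from the extension when `NULL`.
#' @export
write_deg_table <- function(tab, path, sep = NULL) {
  sep <- .detect_sep(path, sep)
  out <- data.frame(gene_id = tab$gene_id, log2FC = tab$log2fc,
                    PValue = tab$p_raw, FDR = tab$p_bh, MAS = tab$mas,
                    rank = tab$rank, significant = tab$significant,
                    direction = tab$direction, stringsAsFactors = FALSE)
  .write_table(out, path, sep = sep)
  invisible(path)
}

#' Read a differential expression table written by [write_deg_table()]
#' @param path Path to the table.
#' @param sep Field separator; inferred from the extension when `NULL`.
#' @return DEG table data frame (internal column names).
#' @export
read_deg_table <- function(path, sep = NULL) {
  sep <- .detect_sep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  out <- data.frame(gene_id = as.character(df$gene_id),
                    log2fc = as.numeric(df$log2FC),
                    p_raw = as.numeric(df$PValue),
                    p_bh = as.numeric(df$FDR),
                    mas = as.numeric(df$MAS),
                    rank = as.integer(df$rank),
                    significant = as.logical(df$significant),
                    direction = as.character(df$direction),
                    stringsAsFactors = FALSE)
  if (any(out$p_raw <= 0 | out$p_raw > 1) || any(out$p_bh < out$p_raw - 1e-15)) {
    stop("invalid DEG table: p-values out of range or FDR below raw p")
  }
  out
}

#' Pipeline configuration
#'
#' Thresholds and settings for the full analysis. Defaults follow the standard
#' operating point of the method: DEGs at BH-adjusted p < 0.05 with
#' |log2 fold change| > 1, MAS exponents M = A = 1, top 10 genes per
#' condition-unique set, Spearman filter |rho| > 0.2.
#'
#' @param lfc_threshold Positive absolute log2-fold-change threshold (strict).
#' @param alpha BH-adjusted p-value threshold in (0, 1) (strict).
#' @param mas_M,mas_A Non-negative MAS exponents for magnitude and altitude.
#' @param top_k_per_set Number of top-ranked genes taken per unique set.
#' @param rho_threshold Non-negative absolute Spearman correlation threshold.
#' @param driver_gene Identifier of the dosage driver gene.
#' @param n_components Number of principal components used for classification.
#' @param random_seed Integer seed for any stochastic step.
#' @param log_prior_count Positive prior count added before log2.
#' @param condition_labels Named labels for the three condition roles.
#' @param ridge Ridge (weight-decay) penalty of the logistic regression.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(lfc_threshold = 1.0, alpha = 0.05,
                            mas_M = 1.0, mas_A = 1.0,
                            top_k_per_set = 10L, rho_threshold = 0.2,
                            driver_gene = "Mecp2", n_components = 2L,
                            random_seed = 1L, log_prior_count = 1.0,
                            condition_labels = default_condition_labels(),
                            ridge = 1e-4) {
  stopifnot(is.numeric(lfc_threshold), length(lfc_threshold) == 1, lfc_threshold > 0)
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1)
  stopifnot(is.numeric(mas_M), mas_M >= 0, is.numeric(mas_A), mas_A >= 0)
  stopifnot(is.numeric(top_k_per_set), top_k_per_set >= 0)
  stopifnot(is.numeric(rho_threshold), rho_threshold >= 0)
  stopifnot(is.character(driver_gene), length(driver_gene) == 1)
  stopifnot(is.numeric(n_components), n_components >= 1)
  stopifnot(is.numeric(log_prior_count), log_prior_count > 0)
  stopifnot(is.character(condition_labels), length(condition_labels) == 3,
            setequal(names(condition_labels), c("reference", "kd", "oe")))
  stopifnot(is.numeric(ridge), ridge >= 0)
  structure(list(
    lfc_threshold = lfc_threshold, alpha = alpha,
    mas_M = mas_M, mas_A = mas_A,
    top_k_per_set = as.integer(top_k_per_set),
    rho_threshold = rho_threshold, driver_gene = driver_gene,
    n_components = as.integer(n_components),
    random_seed = as.integer(random_seed),
    log_prior_count = log_prior_count,
    condition_labels = condition_labels, ridge = ridge
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Fields absent from the file keep their [pipeline_config()] defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(vals$condition_labels)) {
    vals$condition_labels <- unlist(vals$condition_labels)
  }
  do.call(pipeline_config, vals)
}
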
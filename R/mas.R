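# Magnitude-Altitude scoring and the Cross-MAS partition. MAS combines
# effect size ("magnitude", |log2FC|) and statistical confidence ("altitude",
# |log10 adjusted p|) into a single non-negative score; Cross-MAS compares a
# gene's MAS-based ranks across the two contrasts, assigning shared genes
# their worst (maximum) rank, and splits significant genes into
# condition-unique and shared up/down sets.

#' Magnitude-Altitude Score
#'
#' `MAS = |log2FC|^M * |log10 p_BH|^A`. With the default exponents
#' `M = A = 1`, effect size and significance carry equal weight. An adjusted
#' p-value of 1 gives a score of 0; p-values must be strictly positive
#' (callers floor p at the smallest representable double before scoring).
#'
#' @param log2fc Log2 fold change(s).
#' @param p_bh BH-adjusted p-value(s) in (0, 1].
#' @param M,A Non-negative exponents for magnitude and altitude.
#' @return Non-negative score(s).
#' @export
mas_score <- function(log2fc, p_bh, M = 1, A = 1) {
  stopifnot(M >= 0, A >= 0)
  if (any(!is.finite(p_bh)) || any(p_bh <= 0) || any(p_bh > 1)) {
    stop("p_bh must lie in (0, 1]; floor zero p-values before scoring")
  }
  abs(log2fc)^M * abs(log10(p_bh))^A
}

#' Rank a DEG table by MAS
#'
#' Rank 1 is the gene with the largest MAS. Ties are broken deterministically
#' by smaller adjusted p, then larger |log2FC|, then lexicographic gene
#' identifier, so the ranking is a reproducible permutation.
#'
#' @param tab DEG table with columns `gene_id`, `log2fc`, `p_bh`, `mas`.
#' @return The table with its `rank` column filled in.
#' @export
rank_by_mas <- function(tab) {
  stopifnot(all(c("gene_id", "log2fc", "p_bh", "mas") %in% names(tab)))
  ord <- order(-tab$mas, tab$p_bh, -abs(tab$log2fc), tab$gene_id)
  tab$rank <- integer(nrow(tab))
  tab$rank[ord] <- seq_len(nrow(tab))
  tab
}

#' Significantly up- and downregulated gene sets
#'
#' Strict thresholds: up means `p_bh < alpha` and `log2fc > lfc_threshold`;
#' down means `p_bh < alpha` and `log2fc < -lfc_threshold`. A gene exactly at
#' a threshold is excluded.
#'
#' @param tab DEG table.
#' @param config A [pipeline_config()].
#' @return List with character vectors `up` and `down`.
#' @export
significant_sets <- function(tab, config = pipeline_config()) {
  sig <- tab$p_bh < config$alpha
  list(up = tab$gene_id[sig & tab$log2fc > config$lfc_threshold],
       down = tab$gene_id[sig & tab$log2fc < -config$lfc_threshold])
}

#' Cross-MAS partition of two contrasts
#'
#' Splits significant non-driver genes into six pairwise-disjoint sets:
#' unique up/down per contrast and shared up/down. Unique sets are ordered by
#' their own contrast's MAS rank (ascending); shared sets carry each gene's
#' maximum rank across the two contrasts and are ordered by it (min-max
#' selection is then simply taking the head of that order; ties broken by the
#' smaller of the two ranks, then gene identifier). The driver gene is
#' removed before partitioning. Genes significant in opposite directions in
#' the two contrasts are reported in a `discordant` overflow table, never
#' silently dropped.
#'
#' @param kd,oe Ranked DEG tables for the knockdown and overexpression
#'   contrasts, over the same gene universe.
#' @param driver_gene Driver gene identifier to exclude.
#' @param config A [pipeline_config()].
#' @return List of class `crossmas_partition` with data frames `kd_only_up`,
#'   `kd_only_down`, `oe_only_up`, `oe_only_down` (columns `gene_id`, `rank`),
#'   `shared_up`, `shared_down` (columns `gene_id`, `rank_kd`, `rank_oe`,
#'   `max_rank`) and `discordant` (`gene_id`, `rank_kd`, `rank_oe`,
#'   `direction_kd`, `direction_oe`).
#' @export
crossmas_partition <- function(kd, oe, driver_gene = "Mecp2",
                               config = pipeline_config()) {
  if (!setequal(kd$gene_id, oe$gene_id) || nrow(kd) != nrow(oe)) {
    stop("the two DEG tables must cover the same gene universe")
  }
  kd <- kd[kd$gene_id != driver_gene, , drop = FALSE]
  oe <- oe[oe$gene_id != driver_gene, , drop = FALSE]
  s_kd <- significant_sets(kd, config)
  s_oe <- significant_sets(oe, config)
  rk_kd <- stats::setNames(kd$rank, kd$gene_id)
  rk_oe <- stats::setNames(oe$rank, oe$gene_id)

  sig_oe_any <- union(s_oe$up, s_oe$down)
  sig_kd_any <- union(s_kd$up, s_kd$down)
  disc <- union(intersect(s_kd$up, s_oe$down), intersect(s_kd$down, s_oe$up))

  unique_set <- function(ids, ranks) {
    df <- data.frame(gene_id = ids, rank = unname(ranks[ids]),
                     stringsAsFactors = FALSE)
    df[order(df$rank, df$gene_id), , drop = FALSE]
  }
  shared_set <- function(ids) {
    df <- data.frame(gene_id = ids,
                     rank_kd = unname(rk_kd[ids]), rank_oe = unname(rk_oe[ids]),
                     stringsAsFactors = FALSE)
    df$max_rank <- pmax(df$rank_kd, df$rank_oe)
    df[order(df$max_rank, pmin(df$rank_kd, df$rank_oe), df$gene_id), ,
       drop = FALSE]
  }

  part <- list(
    kd_only_up = unique_set(setdiff(s_kd$up, sig_oe_any), rk_kd),
    kd_only_down = unique_set(setdiff(s_kd$down, sig_oe_any), rk_kd),
    oe_only_up = unique_set(setdiff(s_oe$up, sig_kd_any), rk_oe),
    oe_only_down = unique_set(setdiff(s_oe$down, sig_kd_any), rk_oe),
    shared_up = shared_set(intersect(s_kd$up, s_oe$up)),
    shared_down = shared_set(intersect(s_kd$down, s_oe$down))
  )
  ddf <- data.frame(gene_id = disc,
                    rank_kd = unname(rk_kd[disc]), rank_oe = unname(rk_oe[disc]),
                    direction_kd = ifelse(disc %in% s_kd$up, "up", "down"),
                    direction_oe = ifelse(disc %in% s_oe$up, "up", "down"),
                    stringsAsFactors = FALSE)
  part$discordant <- ddf[order(ddf$gene_id), , drop = FALSE]
  structure(part, class = "crossmas_partition", driver_gene = driver_gene)
}

#' Write a Cross-MAS partition as one table
#'
#' Columns: `gene_id`, `set`, `rank_kd`, `rank_oe`, `max_rank` (ranks absent
#' from a set's contrast are `NA`).
#'
#' @param partition A `crossmas_partition`.
#' @param path Output path.
#' @export
write_partition <- function(partition, path) {
  rows <- list()
  for (s in c("kd_only_up", "kd_only_down")) {
    df <- partition[[s]]
    if (nrow(df) > 0) {
      rows[[s]] <- data.frame(gene_id = df$gene_id, set = s, rank_kd = df$rank,
                              rank_oe = NA_integer_, max_rank = df$rank)
    }
  }
  for (s in c("oe_only_up", "oe_only_down")) {
    df <- partition[[s]]
    if (nrow(df) > 0) {
      rows[[s]] <- data.frame(gene_id = df$gene_id, set = s,
                              rank_kd = NA_integer_, rank_oe = df$rank,
                              max_rank = df$rank)
    }
  }
  for (s in c("shared_up", "shared_down")) {
    df <- partition[[s]]
    if (nrow(df) > 0) {
      rows[[s]] <- data.frame(gene_id = df$gene_id, set = s,
                              rank_kd = df$rank_kd, rank_oe = df$rank_oe,
                              max_rank = df$max_rank)
    }
  }
  df <- partition$discordant
  if (nrow(df) > 0) {
    rows$discordant <- data.frame(gene_id = df$gene_id, set = "discordant",
                                  rank_kd = df$rank_kd, rank_oe = df$rank_oe,
                                  max_rank = pmax(df$rank_kd, df$rank_oe))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), set = character(0),
                      rank_kd = integer(0), rank_oe = integer(0),
                      max_rank = integer(0))
  }
  rownames(out) <- NULL
  .write_table(out, path)
  invisible(path)
}
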
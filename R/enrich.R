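# Local over-representation analysis of gene lists against user-supplied GMT
# gene sets: per-term hypergeometric upper-tail test with BH correction
# across the tested terms.

#' Hypergeometric over-representation analysis
#'
#' For each gene set (after intersection with the background universe and a
#' size filter), computes the hypergeometric upper-tail probability of
#' observing at least the overlap between the query and the set when drawing
#' `|query|` genes from the background without replacement. Query genes
#' outside the background are dropped with a warning. Terms with zero overlap
#' are reported with a raw p-value of 1. BH correction is applied across the
#' tested terms.
#'
#' @param query Character vector of query gene identifiers.
#' @param sets Named list of gene sets (as from [read_gmt()]).
#' @param background Character vector: the gene universe (by convention all
#'   genes of the analysed count matrix).
#' @param min_term_size,max_term_size Term-size bounds (after background
#'   intersection) for a set to be tested.
#' @return Data frame ordered by raw p: `term`, `overlap_count`,
#'   `query_size`, `term_size`, `background_size`, `p_raw`, `p_bh`,
#'   `overlap_genes` (comma-separated, sorted).
#' @export
ora_hypergeometric <- function(query, sets, background,
                               min_term_size = 3L, max_term_size = 2000L) {
  background <- unique(background)
  if (length(background) == 0) stop("background gene universe is empty")
  query <- unique(query)
  outside <- setdiff(query, background)
  if (length(outside) > 0) {
    warning("dropping ", length(outside), " query gene(s) outside the background")
    query <- intersect(query, background)
  }
  N <- length(background)
  q <- length(query)
  rows <- lapply(names(sets), function(nm) {
    term <- intersect(unique(sets[[nm]]), background)
    K <- length(term)
    if (K < min_term_size || K > max_term_size) return(NULL)
    ov <- intersect(query, term)
    k <- length(ov)
    p <- stats::phyper(k - 1, K, N - K, q, lower.tail = FALSE)
    data.frame(term = nm, overlap_count = k, query_size = q, term_size = K,
               background_size = N, p_raw = min(max(p, .Machine$double.xmin), 1),
               p_bh = NA_real_,
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term = character(0), overlap_count = integer(0),
                      query_size = integer(0), term_size = integer(0),
                      background_size = integer(0), p_raw = numeric(0),
                      p_bh = numeric(0), overlap_genes = character(0),
                      stringsAsFactors = FALSE))
  }
  out$p_bh <- bh_adjust(out$p_raw)
  out <- out[order(out$p_raw, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
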
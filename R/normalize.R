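# Trimmed mean of M-values (TMM) between-sample normalization and (log-)CPM
# expression values. Factors scale raw library sizes into effective library
# sizes, entering the GLM as offsets and the correlation/PCA stages through
# log2-CPM.

#' TMM normalization factors
#'
#' For each sample against a reference sample, computes gene-wise log2
#' expression ratios (M) and average log2 abundances (A) over genes with
#' positive counts in both members of the pair, doubly trims the gene set by M
#' and by A, and sets the sample's scaling factor to 2 raised to the
#' precision-weighted mean of the surviving M values (weights are inverse
#' asymptotic binomial variances). Factors are rescaled to geometric mean 1.
#'
#' The reference sample is the one whose upper quartile of non-zero CPM is
#' closest to the mean upper quartile across samples, unless given explicitly.
#'
#' @param counts Validated count matrix, genes x samples.
#' @param trim_m Fraction trimmed from each tail of the M distribution.
#' @param trim_a Fraction trimmed from each tail of the A distribution.
#' @param ref_sample Optional sample identifier to use as reference.
#' @return List of class `tmm_norm` with elements `factors` (named, geometric
#'   mean 1), `effective_lib_sizes` (raw library size x factor), `lib_sizes`,
#'   and `ref_sample`.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05, ref_sample = NULL) {
  validate_count_matrix(counts)
  stopifnot(trim_m >= 0, trim_m < 0.5, trim_a >= 0, trim_a < 0.5)
  lib <- colSums(counts)
  if (any(lib <= 0)) {
    stop("sample(s) with zero library size: ",
         paste(colnames(counts)[lib <= 0], collapse = ", "))
  }
  uq <- vapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]
    x <- x[x > 0]
    stats::quantile(x / lib[j] * 1e6, 0.75, names = FALSE)
  }, numeric(1))
  if (is.null(ref_sample)) {
    ref <- which.min(abs(uq - mean(uq)))
  } else {
    ref <- match(ref_sample, colnames(counts))
    if (is.na(ref)) stop("unknown reference sample: ", ref_sample)
  }
  f <- vapply(seq_len(ncol(counts)), function(j) {
    .tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref], trim_m, trim_a,
              colnames(counts)[j])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  structure(list(factors = f, effective_lib_sizes = lib * f,
                 lib_sizes = lib, ref_sample = colnames(counts)[ref]),
            class = "tmm_norm")
}

# One sample against the reference: doubly trimmed, precision-weighted mean of
# M values. Genes with a zero count in either member are excluded (M is
# undefined at zero).
.tmm_pair <- function(y, yr, n, nr, trim_m, trim_a, sample_name) {
  pos <- y > 0 & yr > 0
  if (!any(pos)) {
    stop("sample '", sample_name,
         "' shares no positively expressed genes with the reference")
  }
  y <- y[pos]
  yr <- yr[pos]
  M <- log2((y / n) / (yr / nr))
  A <- 0.5 * log2((y / n) * (yr / nr))
  # asymptotic variance of M from the binomial delta method
  v <- (n - y) / (n * y) + (nr - yr) / (nr * yr)
  nn <- length(M)
  loM <- floor(nn * trim_m) + 1
  hiM <- nn + 1 - loM
  loA <- floor(nn * trim_a) + 1
  hiA <- nn + 1 - loA
  rM <- rank(M)
  rA <- rank(A)
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep) || sum(v[keep] > 0) == 0) return(1)
  keep <- keep & v > 0
  if (!any(keep)) return(1)
  fac <- 2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
  if (!is.finite(fac) || fac <= 0) 1 else fac
}

#' Counts per million, optionally log2
#'
#' Linear CPM is `count / effective library size * 1e6`. With `log2 = TRUE`
#' the convention is `log2(CPM + prior_count)`: the prior is added on the CPM
#' scale after depth scaling, so a zero count maps to `log2(prior_count)`
#' (exactly 0 for the default prior of 1).
#'
#' @param counts Count matrix, genes x samples.
#' @param norm Optional `tmm_norm` result; when `NULL`, raw library sizes are
#'   used (factors of 1).
#' @param log2 Return log2-transformed values.
#' @param prior_count Positive prior added to CPM before log2.
#' @return Numeric matrix, genes x samples, finite everywhere.
#' @export
cpm_matrix <- function(counts, norm = NULL, log2 = FALSE, prior_count = 1.0) {
  validate_count_matrix(counts)
  stopifnot(prior_count > 0)
  eff <- if (is.null(norm)) colSums(counts) else norm$effective_lib_sizes
  if (length(eff) != ncol(counts) || any(!is.finite(eff)) || any(eff <= 0)) {
    stop("invalid effective library sizes")
  }
  cpm <- sweep(counts, 2, eff, "/") * 1e6
  if (log2) cpm <- base::log2(cpm + prior_count)
  cpm
}
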
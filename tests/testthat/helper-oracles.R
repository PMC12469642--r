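# Independent brute-force oracles and small fixture builders shared across
# the test files. Oracles re-derive each quantity from its definition by
# direct enumeration and share no code with the implementation.

# random NB count matrix with dimnames
random_counts <- function(G, S, seed, mu_log_mean = 5, mu_log_sd = 1.5,
                          size = 8) {
  withr::with_seed(seed, {
    m <- matrix(stats::rnbinom(G * S, mu = exp(stats::rnorm(G, mu_log_mean, mu_log_sd)),
                               size = size),
                G, S, dimnames = list(sprintf("g%05d", seq_len(G)),
                                      paste0("s", seq_len(S))))
  })
  m[rowSums(m) > 0, , drop = FALSE]
}

# TMM oracle: recompute M/A per pair from first principles, select the doubly
# trimmed genes by explicitly derived average ranks, take the
# inverse-variance weighted mean, rescale to geometric mean 1.
oracle_tmm <- function(counts, ref, trim_m = 0.30, trim_a = 0.05) {
  lib <- colSums(counts)
  avg_rank <- function(x) {
    vapply(seq_along(x), function(i) {
      sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
    }, numeric(1))
  }
  f <- vapply(seq_len(ncol(counts)), function(j) {
    y <- counts[, j]; yr <- counts[, ref]
    keep0 <- y > 0 & yr > 0
    y <- y[keep0]; yr <- yr[keep0]
    M <- log2((y / lib[j]) / (yr / lib[ref]))
    A <- 0.5 * log2((y / lib[j]) * (yr / lib[ref]))
    v <- (lib[j] - y) / (lib[j] * y) + (lib[ref] - yr) / (lib[ref] * yr)
    nn <- length(M)
    loM <- floor(nn * trim_m) + 1; hiM <- nn + 1 - loM
    loA <- floor(nn * trim_a) + 1; hiA <- nn + 1 - loA
    rM <- avg_rank(M); rA <- avg_rank(A)
    sel <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA & v > 0
    if (!any(sel)) return(1)
    2^(sum(M[sel] / v[sel]) / sum(1 / v[sel]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

# BH step-up oracle: adj_i = min_{k >= i} p_(k) * m / k, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m / (i:m) * ps[i:m]))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Spearman oracle: average ranks by enumeration, then the Pearson formula
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    vapply(seq_along(v), function(i) sum(v < v[i]) + (sum(v == v[i]) + 1) / 2,
           numeric(1))
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# hypergeometric upper-tail oracle by pmf summation
oracle_hyper_tail <- function(k, K, N, q) {
  kk <- k:min(K, q)
  sum(choose(K, kk) * choose(N - K, q - kk)) / choose(N, q)
}

# random ranked DEG table with controllable significance pattern
random_deg_table <- function(n, seed, frac_sig = 0.3) {
  withr::with_seed(seed, {
    lfc <- stats::rnorm(n, 0, 2)
    p <- stats::runif(n)^3
    sig <- stats::runif(n) < frac_sig
    p[sig] <- p[sig] * 0.04
    lfc[sig] <- sign(lfc[sig]) * (1 + abs(lfc[sig]))
  })
  p_bh <- bh_adjust(pmin(pmax(p, 1e-300), 1))
  tab <- data.frame(gene_id = sprintf("g%05d", seq_len(n)), log2fc = lfc,
                    p_raw = p, p_bh = p_bh,
                    mas = mas_score(lfc, pmax(p_bh, .Machine$double.xmin)),
                    rank = NA_integer_, significant = NA,
                    direction = NA_character_, stringsAsFactors = FALSE)
  cfg <- pipeline_config()
  tab$significant <- tab$p_bh < cfg$alpha & abs(tab$log2fc) > cfg$lfc_threshold
  tab$direction <- ifelse(!tab$significant, "ns", ifelse(tab$log2fc > 0, "up", "down"))
  rank_by_mas(tab)
}

# Cross-MAS oracle: exhaustive membership and sorting from the definitions
oracle_crossmas <- function(kd, oe, driver, alpha = 0.05, lfc = 1) {
  kd <- kd[kd$gene_id != driver, ]
  oe <- oe[oe$gene_id != driver, ]
  up_kd <- kd$gene_id[kd$p_bh < alpha & kd$log2fc > lfc]
  dn_kd <- kd$gene_id[kd$p_bh < alpha & kd$log2fc < -lfc]
  up_oe <- oe$gene_id[oe$p_bh < alpha & oe$log2fc > lfc]
  dn_oe <- oe$gene_id[oe$p_bh < alpha & oe$log2fc < -lfc]
  rk <- function(tab, g) tab$rank[match(g, tab$gene_id)]
  sort_unique <- function(g, tab) {
    g[order(rk(tab, g), g)]
  }
  sort_shared <- function(g) {
    g[order(pmax(rk(kd, g), rk(oe, g)), pmin(rk(kd, g), rk(oe, g)), g)]
  }
  sig_oe <- union(up_oe, dn_oe)
  sig_kd <- union(up_kd, dn_kd)
  list(
    kd_only_up = sort_unique(setdiff(up_kd, sig_oe), kd),
    kd_only_down = sort_unique(setdiff(dn_kd, sig_oe), kd),
    oe_only_up = sort_unique(setdiff(up_oe, sig_kd), oe),
    oe_only_down = sort_unique(setdiff(dn_oe, sig_kd), oe),
    shared_up = sort_shared(intersect(up_kd, up_oe)),
    shared_down = sort_shared(intersect(dn_kd, dn_oe)),
    discordant = sort(union(intersect(up_kd, dn_oe), intersect(dn_kd, up_oe)))
  )
}
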
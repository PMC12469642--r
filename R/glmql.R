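# Negative-binomial GLMs with quasi-likelihood F-tests. The fitter is a
# damped IRLS on the log link with NB2 variance mu + phi * mu^2, vectorized
# across genes (all genes share the design, so each iteration reduces to one
# small symmetric solve per gene, done in closed form for up to 3
# coefficients). Dispersion estimation profiles the Cox-Reid adjusted
# likelihood on a dispersion grid; quasi-dispersions are shrunk towards their
# abundance trend by empirical Bayes (scaled-F moment matching).

.DISP_FLOOR <- 1e-8
.BETA_CAP <- 50

# ---- vectorized linear algebra for symmetric p x p systems, p <= 3 --------

# A: G x p(p+1)/2 packed upper triangle by row (p=3: 11,12,13,22,23,33),
# b: G x p. Returns list(x = G x p, logdet = length-G).
.solve_sym <- function(A, b) {
  p <- ncol(b)
  if (p == 1) {
    det <- A[, 1]
    return(list(x = cbind(b[, 1] / det), logdet = log(det)))
  }
  if (p == 2) {
    a <- A[, 1]; bb <- A[, 2]; d <- A[, 3]
    det <- a * d - bb * bb
    x1 <- (d * b[, 1] - bb * b[, 2]) / det
    x2 <- (-bb * b[, 1] + a * b[, 2]) / det
    return(list(x = cbind(x1, x2), logdet = log(det)))
  }
  if (p == 3) {
    a <- A[, 1]; bb <- A[, 2]; cc <- A[, 3]
    d <- A[, 4]; e <- A[, 5]; f <- A[, 6]
    c11 <- d * f - e * e
    c12 <- cc * e - bb * f
    c13 <- bb * e - cc * d
    c22 <- a * f - cc * cc
    c23 <- bb * cc - a * e
    c33 <- a * d - bb * bb
    det <- a * c11 + bb * c12 + cc * c13
    x1 <- (c11 * b[, 1] + c12 * b[, 2] + c13 * b[, 3]) / det
    x2 <- (c12 * b[, 1] + c22 * b[, 2] + c23 * b[, 3]) / det
    x3 <- (c13 * b[, 1] + c23 * b[, 2] + c33 * b[, 3]) / det
    return(list(x = cbind(x1, x2, x3), logdet = log(det)))
  }
  # general fallback
  G <- nrow(b)
  x <- matrix(NA_real_, G, p)
  logdet <- numeric(G)
  ut <- which(upper.tri(diag(p), diag = TRUE))
  for (g in seq_len(G)) {
    M <- matrix(0, p, p)
    M[ut] <- A[g, ]
    M <- M + t(M) - diag(diag(M))
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) {
      logdet[g] <- NA_real_
    } else {
      x[g, ] <- backsolve(ch, forwardsolve(t(ch), b[g, ]))
      logdet[g] <- 2 * sum(log(diag(ch)))
    }
  }
  list(x = x, logdet = logdet)
}

# column products X[,j]*X[,k] for the packed upper triangle
.design_pairs <- function(X) {
  p <- ncol(X)
  idx <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  XX <- matrix(0, nrow(X), nrow(idx))
  for (i in seq_len(nrow(idx))) XX[, i] <- X[, idx[i, "row"]] * X[, idx[i, "col"]]
  XX
}

# NB deviance per gene; Y, MU: G x n; phi: length G (recycled column-major)
.nb_deviance_rows <- function(Y, MU, phi) {
  t1 <- Y * log(ifelse(Y > 0, Y / MU, 1))
  t2 <- (Y + 1 / phi) * (log1p(phi * Y) - log1p(phi * MU))
  rowSums(2 * (t1 - t2))
}

# NB log-likelihood per gene
.nb_loglik_rows <- function(Y, MU, phi) {
  G <- nrow(Y)
  n <- ncol(Y)
  ll <- stats::dnbinom(as.vector(Y), size = rep_len(1 / phi, G * n),
                       mu = as.vector(MU), log = TRUE)
  rowSums(matrix(ll, G, n))
}

# Damped IRLS for all genes simultaneously.
# Y: G x n counts; X: n x p design; offsets: length n or G x n; phi: length G
# (or scalar). Returns coefficients (G x p, natural-log scale), fitted (G x n),
# deviance, df_residual, converged.
.nbglm_fit_matrix <- function(Y, X, offsets, phi, tol = 1e-8, maxit = 50L) {
  G <- nrow(Y)
  n <- ncol(Y)
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) stop("design matrix is rank-deficient")
  O <- if (is.matrix(offsets)) offsets else matrix(offsets, G, n, byrow = TRUE)
  if (any(!is.finite(O))) stop("offsets must be finite")
  phi <- pmax(rep_len(phi, G), .DISP_FLOOR)
  XX <- .design_pairs(X)

  eval_state <- function(B, rows = NULL) {
    if (is.null(rows)) {
      ETA <- tcrossprod(B, X)
      MU <- pmax(exp(pmin(ETA + O, 60)), 1e-10)
      list(eta = ETA, mu = MU, dev = .nb_deviance_rows(Y, MU, phi))
    } else {
      ETA <- tcrossprod(B[rows, , drop = FALSE], X)
      MU <- pmax(exp(pmin(ETA + O[rows, , drop = FALSE], 60)), 1e-10)
      list(eta = ETA, mu = MU,
           dev = .nb_deviance_rows(Y[rows, , drop = FALSE], MU, phi[rows]))
    }
  }

  # initial coefficients from an unweighted LS fit on log counts
  Z0 <- log(pmax(Y, 0.5)) - O
  B <- t(qr.coef(qrX, t(Z0)))
  B[!is.finite(B)] <- 0
  B <- pmin(pmax(B, -.BETA_CAP), .BETA_CAP)
  st <- eval_state(B)
  ETA <- st$eta; MU <- st$mu; dev <- st$dev
  converged <- rep(FALSE, G)

  for (it in seq_len(maxit)) {
    act <- which(!converged)
    if (length(act) == 0) break
    Ya <- Y[act, , drop = FALSE]
    MUa <- MU[act, , drop = FALSE]
    ETAa <- ETA[act, , drop = FALSE]
    phia <- phi[act]
    W <- MUa / (1 + phia * MUa)
    Zw <- ETAa + (Ya - MUa) / MUa
    A <- W %*% XX
    bb <- (W * Zw) %*% X
    sol <- .solve_sym(A, bb)
    Bnew <- sol$x
    bad0 <- !apply(is.finite(Bnew), 1, all)
    if (any(bad0)) Bnew[bad0, ] <- B[act, , drop = FALSE][bad0, , drop = FALSE]
    Bnew <- pmin(pmax(Bnew, -.BETA_CAP), .BETA_CAP)

    # step halving towards the previous iterate when deviance increases
    Bold <- B[act, , drop = FALSE]
    Btmp <- B
    Btmp[act, ] <- Bnew
    sta <- eval_state(Btmp, act)
    deva <- sta$dev
    h <- 0
    while (h < 15) {
      worse <- which(!is.finite(deva) | deva > dev[act] + 1e-10)
      if (length(worse) == 0) break
      Bnew[worse, ] <- (Bnew[worse, , drop = FALSE] + Bold[worse, , drop = FALSE]) / 2
      Btmp[act, ] <- Bnew
      upd <- eval_state(Btmp, act[worse])
      deva[worse] <- upd$dev
      sta$eta[worse, ] <- upd$eta
      sta$mu[worse, ] <- upd$mu
      h <- h + 1
    }
    still <- !is.finite(deva) | deva > dev[act] + 1e-10
    if (any(still)) {
      # stalled: keep previous iterate and stop updating those genes
      keep <- which(still)
      Bnew[keep, ] <- Bold[keep, , drop = FALSE]
      converged[act[keep]] <- TRUE
      upd <- eval_state(B, act[keep])
      sta$eta[keep, ] <- upd$eta
      sta$mu[keep, ] <- upd$mu
      deva[keep] <- upd$dev
    }
    delta <- apply(abs(Bnew - Bold), 1, max)
    B[act, ] <- Bnew
    ETA[act, ] <- sta$eta
    MU[act, ] <- sta$mu
    dev[act] <- deva
    converged[act[delta < tol]] <- TRUE
  }
  dimnames(B) <- list(rownames(Y), colnames(X))
  list(coefficients = B, fitted = MU, deviance = pmax(dev, 0),
       df_residual = n - qrX$rank, converged = converged)
}

#' Fit a negative-binomial GLM for one gene
#'
#' Log-link NB GLM at fixed dispersion, fit by damped iteratively reweighted
#' least squares (convergence when the largest coefficient change is below
#' `1e-8`, at most 50 iterations; steps that increase the deviance are
#' halved). Coefficients are on the natural-log scale and capped at +/- 50.
#'
#' @param y Integer counts for one gene (length = samples).
#' @param design Design matrix, samples x coefficients, full column rank.
#' @param offsets Natural-log effective library sizes (finite, length =
#'   samples).
#' @param dispersion Positive NB dispersion (floored at `1e-8`).
#' @return List with `coefficients`, `fitted_means`, `deviance`
#'   (`2 * (saturated - fitted log-likelihood)`), `df_residual`, `converged`.
#' @export
fit_nb_glm <- function(y, design, offsets, dispersion) {
  stopifnot(is.numeric(y), length(y) == nrow(design))
  fit <- .nbglm_fit_matrix(matrix(as.numeric(y), nrow = 1), design,
                           matrix(offsets, nrow = 1), dispersion)
  list(coefficients = stats::setNames(fit$coefficients[1, ], colnames(design)),
       fitted_means = fit$fitted[1, ],
       deviance = fit$deviance[1],
       df_residual = fit$df_residual,
       converged = fit$converged[1])
}

#' Build the three-condition design matrix
#'
#' Intercept plus knockdown and overexpression indicators; the reference
#' condition is absorbed into the intercept.
#'
#' @param samples Validated sample table.
#' @param condition_labels Named labels for the three condition roles.
#' @return Numeric matrix, samples x 3, columns `intercept`, `kd`, `oe`;
#'   the sample conditions are attached as attribute `condition`.
#' @export
build_design <- function(samples, condition_labels = default_condition_labels()) {
  validate_samples(samples, condition_labels)
  X <- cbind(intercept = 1,
             kd = as.numeric(samples$condition == condition_labels[["kd"]]),
             oe = as.numeric(samples$condition == condition_labels[["oe"]]))
  rownames(X) <- samples$sample_id
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank-deficient")
  attr(X, "condition") <- samples$condition
  X
}

# Cox-Reid adjusted profile log-likelihood per gene at dispersion phi.
.nb_apl <- function(Y, X, O, phi, XX = NULL) {
  fit <- .nbglm_fit_matrix(Y, X, O, phi)
  MU <- fit$fitted
  phiv <- pmax(rep_len(phi, nrow(Y)), .DISP_FLOOR)
  W <- MU / (1 + phiv * MU)
  if (is.null(XX)) XX <- .design_pairs(X)
  A <- W %*% XX
  sol <- .solve_sym(A, matrix(0, nrow(Y), ncol(X)))
  .nb_loglik_rows(Y, MU, phiv) - 0.5 * sol$logdet
}

#' Estimate NB dispersions and quasi-dispersions
#'
#' Three layers: (1) a common dispersion maximizing the summed Cox-Reid
#' adjusted profile likelihood (APL) over a log-spaced grid with
#' golden-section refinement; (2) a trended dispersion, the running median
#' (span `trend_span` of the genes) of gene-wise APL maximizers ordered by
#' average log2-CPM, floored at `1e-8`; (3) gene-wise quasi-dispersions,
#' `deviance / df_residual` from fits at the trended dispersion, shrunk
#' towards their abundance trend by empirical-Bayes moment matching of a
#' scaled-F model (via [limma::squeezeVar()]; the estimated prior df is
#' infinite when the raw quasi-dispersions are underdispersed).
#'
#' @param counts Count matrix (all-zero genes removed), genes x samples.
#' @param design Design matrix from [build_design()].
#' @param offsets Natural-log effective library sizes.
#' @param grid_range Dispersion grid limits.
#' @param grid_length Number of log-spaced grid points.
#' @param trend_span Running-median span as a fraction of the gene count.
#' @param prior_df Optional fixed prior df overriding the estimate; `0`
#'   disables shrinkage, `Inf` collapses to the trend.
#' @return List of class `dispersion_model`: `common`, `genewise`, `trended`,
#'   `ql_raw`, `ql_shrunk`, `prior_df`, `ave_log_cpm`, `df_residual`.
#' @export
estimate_dispersions <- function(counts, design, offsets,
                                 grid_range = c(1e-6, 10), grid_length = 19L,
                                 trend_span = 0.3, prior_df = NULL) {
  G <- nrow(counts)
  n <- ncol(counts)
  p <- ncol(design)
  if (n - p < 2) stop("quasi-likelihood estimation needs at least 2 residual df")
  if (any(rowSums(counts) <= 0)) stop("remove all-zero genes before dispersion estimation")
  Y <- counts
  XX <- .design_pairs(design)
  eff_lib <- exp(offsets)
  ave_log_cpm <- rowMeans(base::log2(sweep(Y, 2, eff_lib, "/") * 1e6 + 2))

  grid <- exp(seq(log(grid_range[1]), log(grid_range[2]), length.out = grid_length))
  apl <- matrix(NA_real_, G, grid_length)
  for (k in seq_len(grid_length)) {
    apl[, k] <- .nb_apl(Y, design, offsets, grid[k], XX)
  }

  # common dispersion: golden-section refinement of the summed APL
  total <- colSums(apl)
  j <- which.max(total)
  lo <- log(grid[max(1, j - 1)])
  hi <- log(grid[min(grid_length, j + 1)])
  fsum <- function(lphi) sum(.nb_apl(Y, design, offsets, exp(lphi), XX))
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- fsum(x1); f2 <- fsum(x2)
  for (i in seq_len(25)) {
    if (b - a < 1e-4) break
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- fsum(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- fsum(x1)
    }
  }
  common <- exp((a + b) / 2)

  # gene-wise maximizers: grid argmax + quadratic interpolation in log phi
  lgrid <- log(grid)
  jmax <- max.col(apl, ties.method = "first")
  genewise <- grid[jmax]
  interior <- which(jmax > 1 & jmax < grid_length)
  if (length(interior) > 0) {
    jm <- jmax[interior]
    y0 <- apl[cbind(interior, jm - 1L)]
    y1 <- apl[cbind(interior, jm)]
    y2 <- apl[cbind(interior, jm + 1L)]
    h <- lgrid[2] - lgrid[1]
    denom <- y0 - 2 * y1 + y2
    shift <- ifelse(abs(denom) > 1e-12, 0.5 * (y0 - y2) / denom, 0)
    shift <- pmin(pmax(shift, -1), 1)
    genewise[interior] <- exp(lgrid[jm] + shift * h)
  }
  genewise <- pmax(genewise, .DISP_FLOOR)

  # trended dispersion: running median of gene-wise maximizers vs abundance
  if (G >= 10) {
    ord <- order(ave_log_cpm)
    k <- max(3L, 2L * floor(trend_span * G / 2) + 1L)
    k <- min(k, if (G %% 2 == 1) G else G - 1L)
    sm <- stats::runmed(log(genewise[ord]), k, endrule = "median")
    trended <- numeric(G)
    trended[ord] <- exp(sm)
  } else {
    trended <- rep(common, G)
  }
  trended <- pmax(trended, .DISP_FLOOR)

  # quasi-dispersions from fits at the trended dispersion
  fit <- .nbglm_fit_matrix(Y, design, offsets, trended)
  df_res <- fit$df_residual
  s2 <- pmax(fit$deviance, 0) / df_res
  s2 <- pmax(s2, 1e-8)
  sq <- limma::squeezeVar(s2, df = df_res, covariate = ave_log_cpm)
  df_prior <- sq$df.prior
  var_prior <- sq$var.prior
  if (!is.null(prior_df)) {
    df_prior <- prior_df
    if (is.infinite(prior_df)) {
      var_post <- rep_len(var_prior, G)
    } else if (prior_df == 0) {
      var_post <- s2
    } else {
      var_post <- (prior_df * var_prior + df_res * s2) / (prior_df + df_res)
    }
  } else {
    var_post <- sq$var.post
  }

  structure(list(common = common, genewise = genewise, trended = trended,
                 ql_raw = s2, ql_shrunk = var_post,
                 prior_df = if (length(df_prior) > 1) stats::median(df_prior) else df_prior,
                 ave_log_cpm = ave_log_cpm, df_residual = df_res),
            class = "dispersion_model")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: monotone, capped at 1, order-preserving, never
#' below the raw p-values. Thin validated wrapper over
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Quasi-likelihood F-test for one contrast
#'
#' Tests the knockdown or overexpression indicator by comparing the
#' three-group full model against the nested reduced model without that
#' indicator, both fit at the trended dispersion over all samples. Per gene,
#' `F = (deviance_reduced - deviance_full) / shrunk quasi-dispersion` on 1
#' numerator df, with denominator df `df_residual + prior_df`. The log2 fold
#' change is the full-model contrast coefficient divided by `log(2)`; BH
#' adjustment is applied across all retained genes within the contrast, and
#' the MAS score, rank, significance flag and direction are filled in.
#'
#' @param counts Count matrix (all-zero genes removed), genes x samples.
#' @param design Design matrix from [build_design()].
#' @param offsets Natural-log effective library sizes.
#' @param disp `dispersion_model` from [estimate_dispersions()].
#' @param contrast `"kd"` or `"oe"`.
#' @param config A [pipeline_config()].
#' @return DEG table data frame: `gene_id`, `log2fc`, `p_raw`, `p_bh`, `mas`,
#'   `rank`, `significant`, `direction`.
#' @export
ql_ftest <- function(counts, design, offsets, disp, contrast = c("kd", "oe"),
                     config = pipeline_config()) {
  contrast <- match.arg(contrast)
  j <- match(contrast, colnames(design))
  if (is.na(j)) stop("contrast column '", contrast, "' not present in design")
  full <- .nbglm_fit_matrix(counts, design, offsets, disp$trended)
  red <- .nbglm_fit_matrix(counts, design[, -j, drop = FALSE], offsets, disp$trended)
  lr <- pmax(red$deviance - full$deviance, 0)
  Fstat <- lr / disp$ql_shrunk
  df2 <- disp$df_residual + disp$prior_df
  p <- stats::pf(Fstat, 1, df2, lower.tail = FALSE)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  log2fc <- full$coefficients[, j] / log(2)
  p_bh <- bh_adjust(p)
  mas <- mas_score(log2fc, pmax(p_bh, .Machine$double.xmin),
                   M = config$mas_M, A = config$mas_A)
  tab <- data.frame(
    gene_id = rownames(counts),
    log2fc = unname(log2fc),
    p_raw = unname(p),
    p_bh = unname(p_bh),
    mas = unname(mas),
    rank = NA_integer_,
    significant = NA,
    direction = NA_character_,
    stringsAsFactors = FALSE
  )
  tab$significant <- tab$p_bh < config$alpha & abs(tab$log2fc) > config$lfc_threshold
  tab$direction <- ifelse(!tab$significant, "ns",
                          ifelse(tab$log2fc > 0, "up", "down"))
  rank_by_mas(tab)
}
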
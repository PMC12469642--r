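make_design6 <- function() {
  s <- data.frame(sample_id = paste0("s", 1:6),
                  condition = rep(c("WT", "KD", "OE"), each = 2))
  build_design(s)
}

test_that("NB GLM closed forms hold for intercept-only and Poisson limits", {
  X <- cbind(intercept = rep(1, 3))
  f <- fit_nb_glm(c(2, 4, 6), X, offsets = rep(1.3, 3), dispersion = 0.2)
  expect_equal(unname(f$coefficients), log(4) - 1.3, tolerance = 1e-8)
  expect_equal(f$df_residual, 2L)

  # Poisson limit: two-group means 10 and 20 give a log(2) group effect
  X2 <- cbind(intercept = 1, grp = rep(c(0, 1), each = 3))
  f2 <- fit_nb_glm(c(10, 10, 10, 20, 20, 20), X2, offsets = rep(0, 6),
                   dispersion = 1e-12)
  expect_equal(unname(f2$coefficients), c(log(10), log(2)), tolerance = 1e-6)

  # Poisson-limit equivalence against glm() on random genes
  withr::with_seed(71, {
    X3 <- make_design6()
    for (i in 1:5) {
      y <- rpois(6, exp(3 + X3[, "kd"] * 0.8 - X3[, "oe"] * 0.4))
      off <- runif(6, 0, 0.5)
      mine <- fit_nb_glm(y, X3, off, dispersion = 1e-12)
      ref <- stats::glm(y ~ 0 + X3 + offset(off), family = stats::poisson())
      expect_equal(unname(mine$coefficients), unname(stats::coef(ref)),
                   tolerance = 1e-6)
    }
  })
})

test_that("NB coefficients maximize the likelihood (derivative-free oracle)", {
  X <- make_design6()
  withr::with_seed(73, {
    for (i in 1:10) {
      phi <- runif(1, 0.02, 0.3)
      mu <- exp(rnorm(1, 4, 1) + X[, "kd"] * rnorm(1, 0, 1) + X[, "oe"] * rnorm(1, 0, 1))
      y <- rnbinom(6, mu = mu, size = 1 / phi)
      if (sum(y) == 0) next
      off <- runif(6, 0, 0.3)
      fit <- fit_nb_glm(y, X, off, phi)
      nll <- function(b) {
        -sum(stats::dnbinom(y, mu = exp(drop(X %*% b) + off), size = 1 / phi, log = TRUE))
      }
      opt <- stats::optim(fit$coefficients + 0.05, nll, method = "Nelder-Mead",
                          control = list(maxit = 20000, reltol = 1e-15))
      expect_lt(max(abs(fit$coefficients - opt$par)), 1e-5)
      # deviance is twice the gap to the saturated log-likelihood
      sat <- sum(stats::dnbinom(y, mu = pmax(y, 1e-10), size = 1 / phi, log = TRUE))
      expect_equal(fit$deviance, 2 * (sat + nll(fit$coefficients)), tolerance = 1e-6)
    }
  })
})

test_that("degenerate genes fit without divergence", {
  X <- make_design6()
  # zero counts in a whole condition: damped IRLS converges, coefficient capped
  f <- fit_nb_glm(c(20, 25, 0, 0, 30, 28), X, offsets = rep(0, 6), dispersion = 0.1)
  expect_true(all(is.finite(f$coefficients)))
  expect_true(all(abs(f$coefficients) <= 50))
  expect_true(all(is.finite(f$fitted_means)))
  expect_error(fit_nb_glm(c(1, 2, 3, 4, 5, 6), cbind(a = rep(1, 6), b = rep(1, 6)),
                          offsets = rep(0, 6), dispersion = 0.1),
               "rank-deficient")
})

test_that("dispersion estimation recovers the truth and its Poisson limit", {
  cfg <- simulation_config(n_genes = 2000L, n_per_group = 4L,
                           driver_kd_factor = 1, driver_oe_factor = 1,
                           dosage_jitter_sd = 0, dispersion_mean = 0.1,
                           dispersion_shape = 1e6, seed = 81L)
  sim <- simulate_experiment(cfg)
  counts <- sim$counts[rowSums(sim$counts) > 0, ]
  norm <- tmm_factors(counts)
  des <- build_design(sim$samples)
  disp <- estimate_dispersions(counts, des, log(norm$effective_lib_sizes))
  expect_gt(disp$common, 0.07)
  expect_lt(disp$common, 0.13)
  # trended dispersions live near the common value for constant-phi data
  expect_lt(abs(stats::median(disp$trended) - 0.1), 0.05)

  # Poisson data: common dispersion collapses towards zero
  withr::with_seed(83, {
    G <- 800
    pois <- matrix(rpois(G * 6, lambda = exp(rnorm(G, 4.5, 1))), G, 6,
                   dimnames = list(sprintf("g%04d", 1:G), paste0("s", 1:6)))
  })
  pois <- pois[rowSums(pois) > 0, ]
  s <- data.frame(sample_id = paste0("s", 1:6),
                  condition = rep(c("WT", "KD", "OE"), each = 2))
  disp_p <- estimate_dispersions(pois, build_design(s), log(colSums(pois)))
  expect_lte(disp_p$common, 0.01)
})

test_that("quasi-dispersion shrinkage honours the prior degrees of freedom", {
  counts <- random_counts(400, 6, seed = 87)
  s <- data.frame(sample_id = colnames(counts),
                  condition = rep(c("WT", "KD", "OE"), each = 2))
  des <- build_design(s)
  off <- log(colSums(counts))
  d0 <- estimate_dispersions(counts, des, off, prior_df = 0)
  expect_equal(d0$ql_shrunk, d0$ql_raw)
  dI <- estimate_dispersions(counts, des, off, prior_df = Inf)
  expect_equal(stats::sd(dI$ql_shrunk / dI$ql_raw) > 0, TRUE)
  dE <- estimate_dispersions(counts, des, off)
  # estimated-prior shrinkage pulls raw quasi-dispersions towards the trend
  expect_true(all(dE$ql_shrunk >= pmin(dE$ql_raw, dI$ql_shrunk) - 1e-12))
  expect_true(all(dE$ql_shrunk <= pmax(dE$ql_raw, dI$ql_shrunk) + 1e-12))
  expect_error(estimate_dispersions(counts[, 1:3],
                                    des[1:3, c("intercept", "kd")], off[1:3]),
               "residual df")
})

test_that("the QL F-test is exact in degenerate cases and detects planted signal", {
  # constant rows: the contrast coefficient is exactly 0, so the reduced and
  # full deviances coincide and F = 0, p = 1
  counts <- matrix(50L, 20, 6, dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:6)))
  s <- data.frame(sample_id = paste0("s", 1:6),
                  condition = rep(c("WT", "KD", "OE"), each = 2))
  des <- build_design(s)
  off <- rep(log(1e4), 6)
  disp <- list(trended = rep(0.1, 20), ql_shrunk = rep(1, 20),
               prior_df = 3, df_residual = 3)
  tab <- ql_ftest(counts, des, off, disp, "kd")
  # the deviance difference vanishes up to IRLS convergence noise (~1e-13),
  # so F ~ 0 and p ~ 1
  expect_equal(tab$p_raw, rep(1, 20), tolerance = 1e-5)
  expect_equal(tab$log2fc, rep(0, 20), tolerance = 1e-6)
  expect_lt(max(tab$mas), 1e-10)

  # a strongly planted gene reaches significance at n = 4 per group
  cfg <- simulation_config(n_genes = 1000L, n_per_group = 4L,
                           class_counts = c(kd_up = 1L),
                           planted_lfc_magnitude = 3,
                           dispersion_mean = 0.05, seed = 91L)
  sim <- simulate_experiment(cfg)
  counts2 <- sim$counts[rowSums(sim$counts) > 0, ]
  norm <- tmm_factors(counts2)
  des2 <- build_design(sim$samples)
  off2 <- log(norm$effective_lib_sizes)
  disp2 <- estimate_dispersions(counts2, des2, off2)
  kd <- ql_ftest(counts2, des2, off2, disp2, "kd")
  g <- sim$truth$gene_id[sim$truth$class == "kd_up"]
  expect_lt(kd$p_bh[kd$gene_id == g], 0.05)
  expect_gt(kd$log2fc[kd$gene_id == g], 1)
})

test_that("estimated fold changes recover planted truth on average", {
  cfg <- default_paperlike_config(n_per_group = 8L, seed = 95L)
  sim <- simulate_experiment(cfg)
  counts <- sim$counts[rowSums(sim$counts) > 0, ]
  norm <- tmm_factors(counts)
  des <- build_design(sim$samples)
  off <- log(norm$effective_lib_sizes)
  disp <- estimate_dispersions(counts, des, off)
  kd <- ql_ftest(counts, des, off, disp, "kd")
  tr <- sim$truth[sim$truth$class != "null" & sim$truth$class != "driver" &
                    sim$truth$gene_id %in% kd$gene_id, ]
  err <- kd$log2fc[match(tr$gene_id, kd$gene_id)] - tr$true_lfc_kd
  expect_lt(abs(mean(err)), 0.15)
})

test_that("BH adjustment matches the step-up brute force and its properties", {
  expect_equal(bh_adjust(0.03), 0.03)
  p_eq <- rep(0.2, 7)
  expect_equal(bh_adjust(p_eq), p_eq)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               oracle_bh(c(0.01, 0.02, 0.03, 0.04)))
  withr::with_seed(97, {
    for (i in 1:50) {
      p <- runif(sample(1:40, 1))
      adj <- bh_adjust(p)
      expect_identical(adj, oracle_bh(p))
      expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
      # order-preserving with the input
      expect_true(all(diff(adj[order(p)]) >= -1e-15))
    }
  })
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})
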
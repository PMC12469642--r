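make_partition <- function(seed_kd = 141, seed_oe = 151, n = 200,
                           driver = "drv") {
  kd <- random_deg_table(n, seed = seed_kd)
  oe <- random_deg_table(n, seed = seed_oe)
  crossmas_partition(kd, oe, driver)
}

test_that("the candidate pool takes the head of each unique set", {
  part <- make_partition()
  pool <- candidate_pool(part, 10)
  sizes <- table(factor(pool$source, levels = c("kd_only_up", "kd_only_down",
                                                "oe_only_up", "oe_only_down")))
  expect_identical(unname(as.integer(sizes)),
                   c(min(10L, nrow(part$kd_only_up)),
                     min(10L, nrow(part$kd_only_down)),
                     min(10L, nrow(part$oe_only_up)),
                     min(10L, nrow(part$oe_only_down))))
  expect_lte(nrow(pool), 40L)
  expect_identical(anyDuplicated(pool$gene_id), 0L)
  # per-set ordering preserved
  for (s in unique(pool$source)) {
    expect_identical(pool$gene_id[pool$source == s],
                     utils::head(part[[s]]$gene_id, 10))
  }
  # a full complement of four deep sets yields the 40-gene pool
  kd <- random_deg_table(2000, seed = 161, frac_sig = 0.5)
  oe <- random_deg_table(2000, seed = 163, frac_sig = 0.5)
  part2 <- crossmas_partition(kd, oe, "none")
  if (all(vapply(part2[c("kd_only_up", "kd_only_down", "oe_only_up",
                         "oe_only_down")], nrow, 1L) >= 10)) {
    expect_identical(nrow(candidate_pool(part2, 10)), 40L)
  }
  expect_identical(nrow(candidate_pool(part, 0)), 0L)
})

test_that("Spearman correlation matches its definitional oracle", {
  withr::with_seed(171, {
    d <- rnorm(12)
    X <- rbind(
      inc = exp(d) + 5,            # strictly increasing transform
      dec = -3 * d + 1,            # order reversal
      ties = round(rnorm(12) * 2) / 2,
      noise = rnorm(12)
    )
    X <- rbind(X, drv = d)
    colnames(X) <- paste0("s", 1:12)
  })
  rho <- spearman_with_driver(X, "drv", c("inc", "dec", "ties", "noise"))
  expect_equal(rho$rho[rho$gene_id == "inc"], 1)
  expect_equal(rho$rho[rho$gene_id == "dec"], -1)
  for (g in c("ties", "noise")) {
    expect_equal(rho$rho[rho$gene_id == g],
                 oracle_spearman(X[g, ], X["drv", ]), tolerance = 1e-12)
  }
  # zero-variance gene flagged with rho 0, not NaN
  X2 <- rbind(X, flat = rep(2, 12))
  expect_warning(r2 <- spearman_with_driver(X2, "drv", c("flat", "inc")),
                 "zero-variance")
  expect_equal(r2$rho[r2$gene_id == "flat"], 0)
  expect_true(r2$zero_variance[r2$gene_id == "flat"])
  expect_error(spearman_with_driver(X[, 1:2], "drv", "inc"), "3 samples")
  expect_error(spearman_with_driver(X, "absent", "inc"), "absent")
})

test_that("panel selection applies correlation then directionality filters", {
  pool <- data.frame(
    gene_id = c("a", "b", "c", "d", "e"),
    source = c("kd_only_down", "kd_only_up", "oe_only_up", "oe_only_down",
               "kd_only_down"),
    rank = 1:5, stringsAsFactors = FALSE
  )
  rho <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                    rho = c(0.5, 0.9, -0.4, 0.8, 0.1),
                    zero_variance = FALSE, stringsAsFactors = FALSE)
  kd <- data.frame(gene_id = letters[1:5], log2fc = c(-2, 3, 0.2, 0.1, -1.5),
                   p_bh = rep(0.01, 5), stringsAsFactors = FALSE)
  oe <- data.frame(gene_id = letters[1:5], log2fc = c(0, 0.2, 2.5, -2, 0),
                   p_bh = rep(0.02, 5), stringsAsFactors = FALSE)
  panel <- select_panel(pool, rho, kd, oe, pipeline_config())
  # a: kd_down, |rho| 0.5 -> kept; b: kd_up excluded by directionality even
  # at rho 0.9; c: oe_up, |rho| 0.4 -> kept (absolute value); d: oe_down
  # excluded; e: |rho| 0.1 below threshold
  expect_identical(panel$gene_id, c("a", "c"))
  expect_identical(panel$source, c("kd_down", "oe_up"))
  expect_equal(panel$log2fc, c(-2, 2.5))
  expect_equal(panel$p_bh, c(0.01, 0.02))
  # sorted by |rho| descending
  expect_true(all(diff(abs(panel$rho)) <= 0))

  # optional sign-coherence flag drops negative correlations
  panel2 <- select_panel(pool, rho, kd, oe, pipeline_config(),
                         require_positive_rho = TRUE)
  expect_identical(panel2$gene_id, "a")

  # empty panel warns and returns a zero-row frame
  rho0 <- rho
  rho0$rho <- 0
  expect_warning(p0 <- select_panel(pool, rho0, kd, oe, pipeline_config()),
                 "empty panel")
  expect_identical(nrow(p0), 0L)
})

test_that("raising the correlation threshold never grows the panel", {
  part <- make_partition(seed_kd = 181, seed_oe = 191)
  pool <- candidate_pool(part, 10)
  withr::with_seed(193, {
    rho <- data.frame(gene_id = pool$gene_id, rho = runif(nrow(pool), -1, 1),
                      zero_variance = FALSE, stringsAsFactors = FALSE)
  })
  kd <- random_deg_table(200, seed = 181)
  oe <- random_deg_table(200, seed = 191)
  sizes <- vapply(c(0, 0.2, 0.4, 0.6, 0.8), function(thr) {
    suppressWarnings(nrow(select_panel(pool, rho, kd, oe,
                                       pipeline_config(rho_threshold = thr))))
  }, 1L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("panel genes nest inside the pool and exclude the driver end-to-end", {
  sim <- simulate_experiment(default_paperlike_config(n_genes = 800L, seed = 23L))
  res <- run_dosage_pipeline(sim$counts, sim$samples, pipeline_config())
  expect_true(all(res$panel$gene_id %in% res$pool$gene_id))
  uniq <- c(res$partition$kd_only_up$gene_id, res$partition$kd_only_down$gene_id,
            res$partition$oe_only_up$gene_id, res$partition$oe_only_down$gene_id)
  expect_true(all(res$pool$gene_id %in% uniq))
  expect_false("Mecp2" %in% c(res$pool$gene_id, res$panel$gene_id))
  # planted dosage-tracking genes that reach the panel are positively
  # correlated with the driver
  trk <- sim$truth$gene_id[grepl("dosage_tracking", sim$truth$class)]
  got <- res$panel[res$panel$gene_id %in% trk, ]
  expect_gt(nrow(got), 0)
  expect_true(all(got$rho > 0))
})
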
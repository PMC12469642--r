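# Negative-binomial count simulator for a three-condition dosage experiment
# with planted, truth-labelled gene classes. The generator is first-class,
# tested code: every downstream stage of the pipeline is validated against the
# truth table it emits.

.sim_classes <- c("kd_up", "kd_down", "oe_up", "oe_down",
                  "shared_up", "shared_down",
                  "dosage_tracking_kd", "dosage_tracking_oe")

#' Simulation configuration
#'
#' Parameters of the synthetic three-condition experiment. Library sizes and
#' baseline relative abundances are log-normal; gene-wise NB dispersions are
#' gamma-distributed. The driver gene's expression is multiplied by
#' `driver_kd_factor` in KD samples and `driver_oe_factor` in OE samples, each
#' with per-sample log-normal jitter; dosage-tracking genes follow the
#' realized per-sample driver dosage raised to `dosage_exponent` in their
#' focal perturbed group (and in the reference group), and to
#' `dosage_exponent * dosage_offside_exponent` in the other perturbed group,
#' so that they respond monotonically to driver dosage across all samples
#' while remaining condition-unique at the DEG thresholds.
#'
#' @param n_genes Number of genes, including the driver.
#' @param n_per_group Samples per condition.
#' @param lib_size_mean,lib_size_cv Mean and coefficient of variation of the
#'   log-normal library sizes.
#' @param baseline_log_mean_mu,baseline_log_mean_sigma Natural-log mean and sd
#'   of baseline relative abundances.
#' @param dispersion_mean,dispersion_shape Mean and gamma shape of gene-wise
#'   NB dispersions.
#' @param driver_kd_factor Driver expression multiplier in KD, in (0, 1).
#' @param driver_oe_factor Driver expression multiplier in OE, > 1.
#' @param class_counts Named integer vector of planted gene counts; names from
#'   `kd_up`, `kd_down`, `oe_up`, `oe_down`, `shared_up`, `shared_down`,
#'   `dosage_tracking_kd`, `dosage_tracking_oe`. Remaining genes are null.
#' @param planted_lfc_magnitude Absolute log2 fold change planted in the
#'   unique and shared classes.
#' @param dosage_exponent Exponent linking tracking-gene expression to driver
#'   dosage in the focal group.
#' @param dosage_offside_exponent Fraction of `dosage_exponent` applied in the
#'   non-focal perturbed group (keeps tracking genes condition-unique).
#' @param dosage_jitter_sd Sd (natural-log scale) of per-sample jitter on the
#'   driver dosage.
#' @param planted_floor_baseline If `TRUE` (default), planted non-null genes
#'   draw their baseline log-abundance from the upper half of the baseline
#'   distribution (left-truncated at `baseline_log_mean_mu`), so planted
#'   signal is quantifiable at the simulated depth.
#' @param driver_gene Identifier given to the driver gene.
#' @param condition_labels Named labels for the three condition roles.
#' @param seed Integer seed; the same configuration and seed give
#'   byte-identical output.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000L, n_per_group = 4L,
                              lib_size_mean = 1e6, lib_size_cv = 0.15,
                              baseline_log_mean_mu = 4.0,
                              baseline_log_mean_sigma = 2.0,
                              dispersion_mean = 0.1, dispersion_shape = 2.0,
                              driver_kd_factor = 0.25, driver_oe_factor = 4.0,
                              class_counts = integer(0),
                              planted_lfc_magnitude = 1.5,
                              dosage_exponent = 1.0,
                              dosage_offside_exponent = 0.25,
                              dosage_jitter_sd = 0.15,
                              planted_floor_baseline = TRUE,
                              driver_gene = "Mecp2",
                              condition_labels = default_condition_labels(),
                              seed = 1L) {
  cc <- stats::setNames(integer(length(.sim_classes)), .sim_classes)
  if (length(class_counts) > 0) {
    unknown <- setdiff(names(class_counts), .sim_classes)
    if (length(unknown) > 0) stop("unknown planted class(es): ", paste(unknown, collapse = ", "))
    cc[names(class_counts)] <- as.integer(class_counts)
  }
  stopifnot(n_genes >= 2, n_per_group >= 1)
  stopifnot(lib_size_mean > 0, lib_size_cv >= 0)
  stopifnot(dispersion_mean > 0, dispersion_shape > 0)
  # factor 1 = unperturbed driver, used for pure-null experiments
  stopifnot(driver_kd_factor > 0, driver_kd_factor <= 1, driver_oe_factor >= 1)
  stopifnot(all(cc >= 0))
  if (sum(cc) > n_genes - 1) {
    stop("sum of class_counts (", sum(cc), ") exceeds n_genes - 1 (driver included in n_genes)")
  }
  stopifnot(planted_lfc_magnitude > 0, dosage_exponent > 0,
            dosage_offside_exponent >= 0, dosage_offside_exponent < 1,
            dosage_jitter_sd >= 0)
  structure(list(
    n_genes = as.integer(n_genes), n_per_group = as.integer(n_per_group),
    lib_size_mean = lib_size_mean, lib_size_cv = lib_size_cv,
    baseline_log_mean_mu = baseline_log_mean_mu,
    baseline_log_mean_sigma = baseline_log_mean_sigma,
    dispersion_mean = dispersion_mean, dispersion_shape = dispersion_shape,
    driver_kd_factor = driver_kd_factor, driver_oe_factor = driver_oe_factor,
    class_counts = cc, planted_lfc_magnitude = planted_lfc_magnitude,
    dosage_exponent = dosage_exponent,
    dosage_offside_exponent = dosage_offside_exponent,
    dosage_jitter_sd = dosage_jitter_sd,
    planted_floor_baseline = isTRUE(planted_floor_baseline),
    driver_gene = driver_gene, condition_labels = condition_labels,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Default study-scale simulation configuration
#'
#' The reference condition set of the package: 2000 genes, 4 samples per
#' condition, a 4-fold driver knockdown/overexpression, and planted classes
#' whose condition-unique down-in-KD and up-in-OE sets are dominated by 10 and
#' 6 dosage-tracking genes respectively, so that a correctly working pipeline
#' is expected to recover a 16-gene panel. Planted non-null genes are fewer
#' than 10% of all genes, preserving the majority-null assumption behind TMM.
#'
#' @param ... Overrides forwarded to [simulation_config()].
#' @return A validated `simulation_config`.
#' @export
default_paperlike_config <- function(...) {
  args <- list(...)
  defaults <- list(
    n_genes = 2000L, n_per_group = 4L,
    class_counts = c(kd_up = 25L, kd_down = 2L, oe_up = 0L, oe_down = 3L,
                     shared_up = 10L, shared_down = 10L,
                     dosage_tracking_kd = 10L, dosage_tracking_oe = 6L)
  )
  do.call(simulation_config, utils::modifyList(defaults, args))
}

#' Simulate a three-condition dosage experiment
#'
#' Draws NB counts gene-wise with mean
#' `library size x relative abundance x effect` and gene-wise dispersion, and
#' returns the count matrix, the sample table, the per-gene truth table, and
#' the realized per-sample driver dosage.
#'
#' @param config A [simulation_config()].
#' @return List with elements `counts` (genes x samples matrix), `samples`
#'   (data frame `sample_id`, `condition`), `truth` (data frame `gene_id`,
#'   `class`, `true_lfc_kd`, `true_lfc_oe`), and `dosage` (named numeric
#'   vector of realized driver dosage per sample, reference = 1).
#' @export
simulate_experiment <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, .simulate_experiment_impl(config))
}

.simulate_experiment_impl <- function(cfg) {
  G <- cfg$n_genes
  npg <- cfg$n_per_group
  labels <- cfg$condition_labels
  conditions <- rep(labels[c("reference", "kd", "oe")], each = npg)
  S <- length(conditions)
  sample_ids <- paste(conditions, rep(seq_len(npg), times = 3), sep = "_")
  is_kd <- conditions == labels[["kd"]]
  is_oe <- conditions == labels[["oe"]]

  # gene classes; positions shuffled so class is not confounded with row order
  cc <- cfg$class_counts
  classes <- rep("null", G)
  planted_idx <- sample.int(G, sum(cc) + 1L)
  classes[planted_idx[1L]] <- "driver"
  pos <- 1L
  for (cl in .sim_classes) {
    if (cc[[cl]] > 0) {
      classes[planted_idx[pos + seq_len(cc[[cl]])]] <- cl
      pos <- pos + cc[[cl]]
    }
  }
  gene_ids <- sprintf("g%05d", seq_len(G))
  gene_ids[classes == "driver"] <- cfg$driver_gene

  # library sizes, baselines, dispersions
  sdlog <- sqrt(log(1 + cfg$lib_size_cv^2))
  lib <- stats::rlnorm(S, meanlog = log(cfg$lib_size_mean) - sdlog^2 / 2, sdlog = sdlog)
  logab <- stats::rnorm(G, cfg$baseline_log_mean_mu, cfg$baseline_log_mean_sigma)
  if (cfg$planted_floor_baseline) {
    pl <- classes != "null"
    logab[pl] <- cfg$baseline_log_mean_mu +
      abs(logab[pl] - cfg$baseline_log_mean_mu)
  }
  abund <- exp(logab)
  prop <- abund / sum(abund)
  phi <- stats::rgamma(G, shape = cfg$dispersion_shape,
                       rate = cfg$dispersion_shape / cfg$dispersion_mean)
  phi <- pmax(phi, 1e-6)

  # realized driver dosage per sample (reference dosage 1, with jitter)
  dosage <- rep(1, S)
  dosage[is_kd] <- cfg$driver_kd_factor
  dosage[is_oe] <- cfg$driver_oe_factor
  dosage <- dosage * exp(stats::rnorm(S, 0, cfg$dosage_jitter_sd))
  names(dosage) <- sample_ids

  # per-gene, per-sample multiplicative effects
  E <- matrix(1, G, S)
  L <- 2^cfg$planted_lfc_magnitude
  e_full <- cfg$dosage_exponent
  e_off <- cfg$dosage_exponent * cfg$dosage_offside_exponent
  for (cl in unique(classes)) {
    rows <- which(classes == cl)
    if (cl %in% c("null")) next
    if (cl == "driver") {
      E[rows, ] <- rep(dosage, each = length(rows))
    } else if (cl == "kd_up") {
      E[rows, is_kd] <- L
    } else if (cl == "kd_down") {
      E[rows, is_kd] <- 1 / L
    } else if (cl == "oe_up") {
      E[rows, is_oe] <- L
    } else if (cl == "oe_down") {
      E[rows, is_oe] <- 1 / L
    } else if (cl == "shared_up") {
      E[rows, is_kd | is_oe] <- L
    } else if (cl == "shared_down") {
      E[rows, is_kd | is_oe] <- 1 / L
    } else if (cl == "dosage_tracking_kd") {
      eff <- ifelse(is_oe, dosage^e_off, dosage^e_full)
      E[rows, ] <- rep(eff, each = length(rows))
    } else if (cl == "dosage_tracking_oe") {
      eff <- ifelse(is_kd, dosage^e_off, dosage^e_full)
      E[rows, ] <- rep(eff, each = length(rows))
    }
  }

  MU <- (prop * E) %*% diag(lib)
  counts <- matrix(stats::rnbinom(G * S, mu = as.vector(MU),
                                  size = rep(1 / phi, times = S)),
                   nrow = G, ncol = S,
                   dimnames = list(gene_ids, sample_ids))

  lfc_kd <- numeric(G)
  lfc_oe <- numeric(G)
  m <- cfg$planted_lfc_magnitude
  lfc_kd[classes == "kd_up"] <- m
  lfc_kd[classes == "kd_down"] <- -m
  lfc_oe[classes == "oe_up"] <- m
  lfc_oe[classes == "oe_down"] <- -m
  lfc_kd[classes == "shared_up"] <- m
  lfc_oe[classes == "shared_up"] <- m
  lfc_kd[classes == "shared_down"] <- -m
  lfc_oe[classes == "shared_down"] <- -m
  lfc_kd[classes == "dosage_tracking_kd"] <- e_full * log2(cfg$driver_kd_factor)
  lfc_oe[classes == "dosage_tracking_kd"] <- e_off * log2(cfg$driver_oe_factor)
  lfc_kd[classes == "dosage_tracking_oe"] <- e_off * log2(cfg$driver_kd_factor)
  lfc_oe[classes == "dosage_tracking_oe"] <- e_full * log2(cfg$driver_oe_factor)
  lfc_kd[classes == "driver"] <- log2(cfg$driver_kd_factor)
  lfc_oe[classes == "driver"] <- log2(cfg$driver_oe_factor)

  list(
    counts = counts,
    samples = data.frame(sample_id = sample_ids, condition = unname(conditions),
                         stringsAsFactors = FALSE),
    truth = data.frame(gene_id = gene_ids, class = classes,
                       true_lfc_kd = lfc_kd, true_lfc_oe = lfc_oe,
                       stringsAsFactors = FALSE),
    dosage = dosage
  )
}

#' Write a simulated experiment to disk
#'
#' Writes `counts.tsv`, `meta.tsv` and `truth.tsv` into `outdir`.
#'
#' @param sim Result of [simulate_experiment()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the output directory.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_counts(sim$counts, file.path(outdir, "counts.tsv"))
  write_metadata(sim$samples, file.path(outdir, "meta.tsv"))
  .write_table(sim$truth, file.path(outdir, "truth.tsv"))
  invisible(outdir)
}
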
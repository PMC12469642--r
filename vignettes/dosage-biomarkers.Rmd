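---
title: "Finding dosage-sensitive biomarker panels in three-condition RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding dosage-sensitive biomarker panels in three-condition RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossmas)
```

## The problem

Some regulatory genes are *dosage drivers*: both their loss and their excess
cause disease, and both shift the transcriptome. The canonical example is
MeCP2 in neurons, where knockdown (KD) models Rett syndrome and
overexpression (OE) models MECP2 duplication syndrome. Given raw RNA-seq
counts from three conditions — a reference group ("WT"), a driver-knockdown
group and a driver-overexpression group — `crossmas` asks: *which genes
track the driver's dosage*, falling when the driver falls and rising when it
rises? A compact set of such genes is a candidate transcriptional surrogate
for driver status.

The pipeline has five statistical stages, each exposed as an ordinary
function and composed by `run_dosage_pipeline()`:

1. **Normalization.** Trimmed-mean-of-M-values (TMM) scaling factors convert
   raw library sizes into effective library sizes. Per sample-vs-reference
   pair, gene-wise log2 expression ratios (M) and average log2 abundances
   (A) are computed over genes positive in both samples, the gene set is
   doubly trimmed (30% of each M tail, 5% of each A tail by default), and
   the factor is 2 raised to the precision-weighted mean of the surviving M
   values, with inverse asymptotic binomial variances as weights. Factors
   are rescaled to geometric mean 1. The reference sample is the one whose
   upper quartile of non-zero CPM is closest to the cross-sample mean upper
   quartile — the standard practice of the cited method, made explicit and
   configurable here.

2. **Differential expression.** Per gene, a negative-binomial GLM with log
   link is fit over *all* samples with design `intercept + KD + OE` and
   offsets `log(library size x TMM factor)`. Each contrast is a
   quasi-likelihood (QL) F-test of the nested pair: full model with both
   indicators against a reduced model dropping the tested indicator. The
   statistic is `F = (deviance_reduced - deviance_full) / s2_g` on 1
   numerator degree of freedom, where `s2_g` is the gene's empirical-Bayes
   shrunk quasi-dispersion, with denominator df
   `residual df + prior df`. Genes with BH-adjusted p below 0.05 *and*
   |log2FC| above 1 (both strict) are called differentially expressed.

3. **MAS ranking.** Each gene gets a Magnitude–Altitude Score
   `MAS = |log2FC|^M * |log10 p_BH|^A` (defaults `M = A = 1`, weighting
   effect size and confidence equally); rank 1 is the largest score. Ties
   are broken by smaller adjusted p, then larger |log2FC|, then gene
   identifier, so ranks are a reproducible permutation. Adjusted p-values
   are floored at the smallest positive double before the log, since the
   score diverges at p = 0.

4. **Cross-MAS partition and panel selection.** Significant non-driver genes
   are split into six disjoint sets — unique up/down per contrast and shared
   up/down — with shared genes carrying their *worst* (maximum) rank across
   the two contrasts and shared sets ordered by it; selecting the head of
   that order is exactly the min–max rule. Genes significant in opposite
   directions in the two contrasts go to a separate `discordant` table
   rather than being dropped. The candidate pool takes the top
   `top_k_per_set` (default 10) genes of each unique set; candidates are
   then filtered by absolute Spearman correlation with the driver across all
   pooled samples (strictly above 0.2 by default, computed on log2-CPM) and
   by directionality: only unique-down-in-KD and unique-up-in-OE genes can
   represent positive dosage tracking, so the other two unique sets are
   excluded.

5. **Discriminability evaluation.** Samples are projected onto the first two
   principal components of the gene-centred log2-CPM matrix (no variance
   scaling; component signs fixed by making the largest-magnitude loading
   positive), and a multinomial logistic regression with a small ridge
   penalty (1e-4) is fit on the scores and evaluated **on the same
   samples**. The reported accuracy is a training-set separability measure,
   deliberately so: the question is whether the panel separates the observed
   conditions, not out-of-sample prediction, and the package labels it
   accordingly.

## Dispersion estimation in detail

The NB dispersion controls how much biological variability the test
tolerates. Three layers are estimated:

* a **common** dispersion maximizing the summed Cox–Reid adjusted profile
  likelihood (the NB log-likelihood at the per-gene IRLS fit, penalised by
  half the log-determinant of the weighted information `X'WX`) over a
  log-spaced grid on `[1e-6, 10]` with golden-section refinement;
* a **trended** dispersion: per-gene grid maximizers (with quadratic
  interpolation between grid points) smoothed by a running median over genes
  ordered by average log2-CPM, with a span of 30% of the genes, floored at
  `1e-8`;
* gene-wise **quasi-dispersions**: `deviance / residual df` from fits at the
  trended dispersion, shrunk towards their abundance trend by moment
  matching of a scaled-F model (`limma::squeezeVar`); when the raw ratios
  are underdispersed the estimated prior df is infinite and the ratios
  collapse to the trend.

Whether the original analyses used common, trended or tagwise dispersions —
and which QL shrinkage settings — is not documented in this level of
detail anywhere we could follow, so exact numeric replication of any other
implementation is not claimed; the choices above are standard, configurable,
and every piece is oracle-tested (closed forms in the Poisson limit,
derivative-free likelihood maximization for coefficients, planted-truth
simulations for the dispersion layers).

## What the synthetic data emulate

`simulate_experiment()` draws NB counts with mean
`library size x relative abundance x effect` and gamma-distributed gene-wise
dispersions. Library sizes and baseline abundances are log-normal
(defaults: mean 1e6 with CV 0.15; natural-log abundance mean 4, sd 2).
The driver's expression is multiplied by 0.25 in KD and 4 in OE, each with
per-sample log-normal jitter (sd 0.15) — the *realized* dosage. Planted
classes are truth-labelled: condition-unique and shared up/down genes with
|log2FC| 1.5, and dosage-tracking genes whose effect is the realized dosage
raised to an exponent (default 1).

Three generator choices deserve explanation:

* **Off-side attenuation.** A gene tracking dosage symmetrically in both
  perturbed groups would be significant in both contrasts and land in the
  discordant list, not in the condition-unique sets the panel is built from.
  Tracking genes therefore get the full exponent in their focal perturbed
  group (and in WT) and a quarter of it in the other perturbed group:
  the off-side log2FC (~0.5) stays below the DEG threshold while the
  response remains monotone in dosage, which is what the Spearman filter
  needs. Real dosage targets with asymmetric sensitivity behave this way;
  perfectly symmetric targets would be found by both contrasts and
  deliberately classified as shared/discordant rather than condition-unique.
* **Planted genes are quantifiable.** Planted (non-null) genes draw their
  baseline abundance from the upper half of the abundance distribution.
  Biomarker candidates are by construction measurable genes; planting
  effects on near-zero-count genes would test sequencing depth, not the
  method.
* **Default class counts.** The default configuration
  (`default_paperlike_config()`: 2000 genes, 4 samples per group) plants 10
  KD-side and 6 OE-side dosage-tracking genes, so a correctly working
  pipeline is *expected* to recover a 16-gene panel, alongside 25/2/0/3
  unique up/down and 10+10 shared genes (86 planted genes, under 10% of the
  genome, preserving the majority-null assumption TMM relies on). The
  shared classes are kept small for a structural reason: with only three
  groups, a shared gene sits near Spearman rho of +/-0.2 with the driver
  (borderline for the filter), and whenever one-sided power misses it in
  exactly one contrast it leaks into a condition-unique set. Likewise, *any*
  condition-unique DE gene acquires |rho| of roughly 0.6 through group
  structure alone, so in this three-group design the correlation filter
  mainly removes discordant and noisy candidates rather than unique-set
  genes — a near-degeneracy the dosage jitter only partly lifts. Simulated
  panels should therefore be read as "tracking genes plus occasional
  unique/shared leakage", which mirrors how the filters behave on real data
  where correlation structure is richer.

What the generator does **not** emulate: batch effects, gene length and GC
biases, read-level noise, correlated genes, or cell-type mixtures. Passing
the planted-truth tests shows the statistics are implemented correctly and
are well calibrated under NB sampling; it does not certify performance on
data violating those assumptions.

## Numerical choices and degenerate inputs

* IRLS convergence at max |coefficient change| < 1e-8, at most 50
  iterations, with step halving whenever a step increases the deviance;
  coefficients capped at |ln-scale| 50 so genes with an all-zero condition
  converge to the cap instead of diverging.
* All-zero genes are removed before fitting (nothing else is filtered by
  default; an abundance filter is a user decision).
* Genes with zero counts in either member of a TMM pair are excluded from
  that pair's M/A computation (M is undefined at zero).
* Zero-variance genes get Spearman rho 0 with a flag, never NaN.
* Strict threshold inequalities everywhere (a gene at log2FC exactly 1 or
  adjusted p exactly 0.05 is not called).
* Problem sizes used by the test-suite simulations (2000 genes, 4–8 samples
  per group) are the package's reference conditions: large enough for
  calibration and trend estimation to be meaningful, small enough that the
  whole validation suite runs in well under a minute.

## Known limitations

* Two contrasts only (KD and OE against reference); the partition API
  leaves room for more but v1 does not generalise.
* Training-set accuracy is an optimistic separability measure by design;
  no cross-validation is offered, and none is claimed.
* The enrichment module is a transparent local hypergeometric ORA over
  user-supplied GMT sets with BH correction. It is not a re-implementation
  of any web service's proprietary correction, and term-level agreement
  with such services is not claimed; its default background (all genes of
  the analysed matrix) is explicit and reproducible.
* The two-group-subset reading of "full vs reduced model" (testing each
  contrast on only the two involved groups) is not the default; the package
  fits one three-group model and drops one indicator, which uses all
  samples to estimate the baseline and dispersion. Users wanting the subset
  behaviour can simply subset their inputs.

## A minimal session

```{r example, eval = FALSE}
sim <- simulate_experiment(default_paperlike_config(seed = 1))
res <- run_dosage_pipeline(sim$counts, sim$samples, pipeline_config())
print(res)
head(res$panel)

# how many planted tracking genes did the panel recover?
planted <- sim$truth$gene_id[grepl("dosage_tracking", sim$truth$class)]
sum(res$panel$gene_id %in% planted)

# persist every artifact
write_pipeline_outputs(res, "results/")
```
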
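# Discriminability evaluation of a gene set: PCA of samples on gene-centred
# log2 expression, then multinomial logistic regression on the leading
# principal components. Evaluation is on the training samples by design: the
# question is how well the gene set separates the observed conditions, not
# out-of-sample prediction.

#' Principal component scores of samples
#'
#' Centres each gene (no unit-variance scaling) and projects samples onto the
#' top right-singular vectors of the samples x genes matrix. The sign of each
#' component is fixed deterministically: the gene loading with the largest
#' magnitude is made positive.
#'
#' @param logexpr Expression matrix (typically log2-CPM), genes x samples.
#' @param genes Optional subset of gene identifiers; `NULL` uses all genes.
#' @param n_components Number of components to return.
#' @return List with `scores` (samples x `n_components`),
#'   `explained_variance` (fraction of total variance per returned component,
#'   non-increasing), and `loadings` (genes x `n_components`).
#' @export
pca_scores <- function(logexpr, genes = NULL, n_components = 2L) {
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(logexpr))
    if (length(missing) > 0) {
      stop("gene(s) not in the expression matrix: ", paste(missing, collapse = ", "))
    }
    logexpr <- logexpr[genes, , drop = FALSE]
  }
  X <- t(logexpr)
  n <- nrow(X)
  if (n_components > min(n - 1, ncol(X))) {
    stop("n_components must be at most min(n_samples - 1, n_genes)")
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  k <- n_components
  d2 <- sv$d^2
  U <- sv$u[, seq_len(k), drop = FALSE]
  V <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) {
      V[, j] <- -V[, j]
      U[, j] <- -U[, j]
    }
  }
  scores <- U %*% diag(sv$d[seq_len(k)], nrow = k)
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(k)))
  dimnames(V) <- list(colnames(X), paste0("PC", seq_len(k)))
  list(scores = scores,
       explained_variance = d2[seq_len(k)] / sum(d2),
       loadings = V)
}

#' Fit and evaluate a multinomial logistic regression on PC scores
#'
#' Fits a multinomial logistic regression with a small ridge (weight-decay)
#' penalty for numerical stability on the supplied component scores, then
#' evaluates it on the same samples. The reported accuracy is therefore a
#' training-set separability measure, not an out-of-sample estimate.
#'
#' @param scores Samples x components score matrix.
#' @param labels Condition label per sample (2 or 3 distinct values).
#' @param ridge Ridge penalty (weight decay) of the fit.
#' @param feature_set_label Free-text label describing the feature set.
#' @return List of class `classification_report`: `accuracy`, `confusion`
#'   (rows = true condition, columns = predicted), `pc_scores`,
#'   `explained_variance` (if attached to `scores`), `feature_set_label`.
#' @export
fit_eval_logreg <- function(scores, labels, ridge = 1e-4,
                            feature_set_label = "") {
  labels <- factor(labels)
  if (nlevels(labels) < 2) {
    stop("at least 2 distinct condition labels required")
  }
  if (length(labels) != nrow(scores)) {
    stop("labels must have one entry per sample")
  }
  df <- data.frame(scores, check.names = TRUE)
  df$.label <- labels
  fit <- nnet::multinom(.label ~ ., data = df, decay = ridge,
                        trace = FALSE, maxit = 1000)
  pred <- stats::predict(fit, newdata = df)
  pred <- factor(pred, levels = levels(labels))
  confusion <- table(truth = labels, predicted = pred)
  accuracy <- sum(diag(confusion)) / length(labels)
  structure(list(accuracy = accuracy,
                 confusion = confusion,
                 pc_scores = scores,
                 feature_set_label = feature_set_label),
            class = "classification_report")
}

#' Evaluate how well a gene set separates the conditions
#'
#' Convenience wrapper: PCA scores for the gene set, then
#' [fit_eval_logreg()].
#'
#' @inheritParams pca_scores
#' @param labels Condition label per sample.
#' @param ridge Ridge penalty of the logistic regression.
#' @param feature_set_label Free-text label describing the gene set.
#' @return A `classification_report` with `explained_variance` attached.
#' @export
evaluate_gene_set <- function(logexpr, labels, genes = NULL,
                              n_components = 2L, ridge = 1e-4,
                              feature_set_label = "") {
  pc <- pca_scores(logexpr, genes = genes, n_components = n_components)
  rep <- fit_eval_logreg(pc$scores, labels, ridge = ridge,
                         feature_set_label = feature_set_label)
  rep$explained_variance <- pc$explained_variance
  rep
}

#' Write a classification report as JSON
#' @param report A `classification_report`.
#' @param path Output path.
#' @export
write_classification_report <- function(report, path) {
  out <- list(
    feature_set_label = report$feature_set_label,
    accuracy = report$accuracy,
    confusion = list(
      labels = rownames(report$confusion),
      counts = unclass(unname(apply(report$confusion, 1, as.integer,
                                    simplify = FALSE)))
    ),
    explained_variance = report$explained_variance,
    pc_scores = apply(report$pc_scores, 2, identity, simplify = FALSE)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
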
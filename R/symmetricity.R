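#' Interhemispheric symmetricity vector
#'
#' Elementwise absolute distance `d_i = |f_i_left - f_i_right|` between
#' the radiomics feature vectors of homologous left and right ROIs. Zero
#' everywhere for a perfectly mirror-symmetric brain.
#'
#' @param f_left,f_right numeric feature vectors in the same registry
#'   order and of equal length.
#' @return nonnegative numeric vector of the same length.
#' @export
symmetricity_vector <- function(f_left, f_right) {
  if (length(f_left) != length(f_right)) {
    stop("feature vectors differ in length")
  }
  out <- abs(as.numeric(f_left) - as.numeric(f_right))
  names(out) <- names(f_left)
  out
}

#' Assemble a cohort symmetricity matrix
#'
#' @param vectors list of per-subject symmetricity vectors (equal length).
#' @param labels character vector, `"patient"` or `"control"` per subject.
#' @return a `symmetricity_matrix`: numeric matrix (subjects x features)
#'   with attributes `labels` and `normalized = FALSE`.
#' @export
symmetricity_matrix <- function(vectors, labels) {
  stopifnot(length(vectors) == length(labels))
  labels <- match.arg(labels, c("patient", "control"), several.ok = TRUE)
  M <- do.call(rbind, lapply(vectors, as.numeric))
  colnames(M) <- names(vectors[[1]])
  structure(M, labels = labels, normalized = FALSE,
            class = c("symmetricity_matrix", "matrix", "array"))
}

#' Column-wise Z-transform of a symmetricity matrix
#'
#' Standardizes each feature column to mean 0 and (population) SD 1 over
#' subjects, yielding the normalized symmetricity matrix. Zero-variance
#' columns are set to 0 with a warning listing their indices. Idempotent.
#'
#' @param M a [symmetricity_matrix()] (or plain matrix, >= 2 rows).
#' @return the normalized matrix (attribute `normalized = TRUE`).
#' @export
normalize_matrix <- function(M) {
  stopifnot(nrow(M) >= 2L)
  mu <- colMeans(M)
  sigma <- sqrt(colMeans(sweep(M, 2, mu)^2))
  zero <- sigma == 0
  sigma[zero] <- 1
  Z <- sweep(sweep(M, 2, mu), 2, sigma, "/")
  if (any(zero)) {
    Z[, zero] <- 0
    warning("zero-variance columns set to 0: ",
            paste(which(zero), collapse = ", "))
  }
  attrs <- attributes(M)
  attributes(Z) <- c(attributes(Z)[c("dim", "dimnames")],
                     attrs[setdiff(names(attrs), c("dim", "dimnames", "normalized"))])
  attr(Z, "normalized") <- TRUE
  attr(Z, "zero_variance") <- which(zero)
  Z
}

#' Hierarchical clustering of feature columns
#'
#' Agglomerative clustering (average linkage) of the feature columns of a
#' normalized symmetricity matrix under correlation distance
#' `1 - |Pearson r|`, cut to exactly `k` clusters. Grouping by absolute
#' correlation collects redundant features regardless of sign, which is
#' the goal when one representative per cluster will be selected.
#' Zero-variance columns carry no signal and are assigned to the largest
#' cluster. Deterministic given its inputs.
#'
#' @param M_norm normalized symmetricity matrix.
#' @param k number of clusters (`2 <= k <=` number of non-constant
#'   columns).
#' @param method linkage passed to [stats::hclust()].
#' @return integer vector, length `ncol(M_norm)`, values in `1..k`.
#' @export
cluster_features <- function(M_norm, k, method = "average") {
  p <- ncol(M_norm)
  sigma <- sqrt(colMeans(sweep(M_norm, 2, colMeans(M_norm))^2))
  live <- which(sigma > 0)
  if (k < 1L || k > length(live)) {
    stop("k must be between 1 and the number of non-constant columns (",
         length(live), ")")
  }
  r <- suppressWarnings(cor(M_norm[, live, drop = FALSE]))
  d <- stats::as.dist(1 - abs(r))
  hc <- hclust(d, method = method)
  cl_live <- cutree(hc, k = k)
  out <- integer(p)
  out[live] <- cl_live
  if (length(live) < p) {
    biggest <- as.integer(names(which.max(table(cl_live))))
    out[-live] <- biggest
  }
  out
}

#' Fisher inter-intra class variance ratio (FICVR)
#'
#' `|mu_p - mu_c| / sqrt(sigma_p^2 + sigma_c^2)` with population
#' (divide-by-n) variances, scoring how well one feature separates
#' patients from controls. If both class variances are zero the ratio is
#' `Inf` when the means differ and 0 when all values are equal.
#'
#' @param values numeric vector of one feature over subjects.
#' @param labels `"patient"`/`"control"` per subject (both present).
#' @return a single nonnegative number (possibly `Inf`).
#' @export
ficvr <- function(values, labels) {
  p <- values[labels == "patient"]
  c_ <- values[labels == "control"]
  if (length(p) == 0L || length(c_) == 0L) {
    stop("both classes must be present")
  }
  num <- mean(p) - mean(c_)
  den <- sqrt(mean((p - mean(p))^2) + mean((c_ - mean(c_))^2))
  if (den == 0) {
    return(if (num == 0) 0 else Inf)
  }
  abs(num / den)
}

#' Cluster-based feature selection by maximum |FICVR|
#'
#' Clusters the feature columns into `k` groups ([cluster_features()]) and
#' selects, per cluster, the feature with the largest [ficvr()] (ties
#' broken toward the lowest registry index).
#'
#' @param M_norm normalized symmetricity matrix.
#' @param labels class labels per row.
#' @param k number of clusters/selected features (default 10).
#' @return a `selection_result`: list with `selected` (k feature column
#'   indices, ordered by cluster id), `cluster` (per-feature cluster
#'   assignment) and `ficvr` (per-feature FICVR values).
#' @export
select_features <- function(M_norm, labels = attr(M_norm, "labels"), k = 10L) {
  stopifnot(!is.null(labels), length(labels) == nrow(M_norm))
  cl <- cluster_features(M_norm, k)
  fv <- apply(M_norm, 2, ficvr, labels = labels)
  selected <- vapply(seq_len(k), function(g) {
    members <- which(cl == g)
    members[which.max(fv[members])]  # which.max: first (lowest index) on ties
  }, integer(1))
  structure(list(selected = selected, cluster = cl, ficvr = fv, k = k),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d features selected from %d clusters\n",
              length(x$selected), x$k))
  nm <- names(x$ficvr)[x$selected]
  df <- data.frame(index = x$selected,
                   feature = if (is.null(nm)) NA else nm,
                   ficvr = round(x$ficvr[x$selected], 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' L2-penalized logistic regression (Newton/IRLS)
#'
#' Minimizes `(1/n) * sum(log-loss) + (lambda/2) * ||beta||^2` (intercept
#' unpenalized). A compact deterministic solver used by all classifier
#' harnesses in the package; the fixed penalty keeps separable folds
#' finite.
#'
#' @param X numeric matrix (n x p).
#' @param y 0/1 response.
#' @param lambda ridge penalty strength (default 1.0).
#' @param weights optional nonnegative case weights (mean-normalized).
#' @param maxit,tol Newton iteration controls.
#' @return list with `beta` (length p + 1, intercept first) and
#'   `predict(newX)` returning probabilities.
#' @export
ridge_logistic <- function(X, y, lambda = 1.0, weights = NULL,
                           maxit = 100L, tol = 1e-10) {
  X <- as.matrix(X)
  n <- nrow(X)
  y <- as.numeric(y)
  w <- if (is.null(weights)) rep(1, n) else weights / mean(weights)
  Xa <- cbind(1, X)
  p1 <- ncol(Xa)
  pen <- diag(c(0, rep(lambda, p1 - 1L)), p1)
  beta <- numeric(p1)
  for (it in seq_len(maxit)) {
    eta <- drop(Xa %*% beta)
    mu <- plogis(eta)
    grad <- -drop(crossprod(Xa, w * (y - mu))) / n + pen %*% beta
    W <- w * mu * (1 - mu)
    H <- crossprod(Xa, Xa * W) / n + pen
    step <- solve(H + diag(1e-12, p1), grad)
    beta <- beta - step
    if (max(abs(step)) < tol) break
  }
  beta <- drop(beta)
  list(beta = beta,
       predict = function(newX) {
         plogis(drop(cbind(1, as.matrix(newX)) %*% beta))
       })
}

# Seeded stratified fold assignment (round-robin within class).
stratified_folds <- function(labels, folds, seed) {
  f <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      f[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  f
}

# Binary metrics at a 0.5 probability cutoff.
binary_metrics <- function(prob, truth) {
  pred <- prob >= 0.5
  tp <- sum(pred & truth == 1)
  tn <- sum(!pred & truth == 0)
  fp <- sum(pred & truth == 0)
  fn <- sum(!pred & truth == 1)
  c(accuracy = (tp + tn) / length(truth),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Cross-validated symmetricity diagnosis
#'
#' Stratified k-fold cross-validation of an L2-penalized logistic
#' regression on the selected symmetricity features. Features are
#' standardized inside each training fold only (fold means/SDs applied to
#' the held-out fold), so no information leaks from validation to
#' training. Metrics are averaged over folds; fold AUCs undefined for
#' single-class held-out folds are dropped with a warning.
#'
#' @param M_norm normalized symmetricity matrix.
#' @param labels `"patient"`/`"control"` per row.
#' @param selected feature column indices to use (e.g. from
#'   [select_features()]).
#' @param folds number of CV folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @param lambda ridge penalty.
#' @param standardize standardize features inside each training fold
#'   (default). `FALSE` centers only, which makes the all-features model
#'   exactly rotation-invariant (see [diagnosis_baselines()]).
#' @return a `petsym_cv` list: `auc`, `accuracy`, `sensitivity`,
#'   `specificity` (fold means), `fold_auc`, `pooled_auc`, `prob`
#'   (out-of-fold probabilities), `folds`, `seed`.
#' @export
diagnose_cv <- function(M_norm, labels = attr(M_norm, "labels"),
                        selected = seq_len(ncol(M_norm)), folds = 10L,
                        seed = 1L, lambda = 1.0, standardize = TRUE) {
  stopifnot(!is.null(labels), length(labels) == nrow(M_norm))
  y <- as.integer(labels == "patient")
  X <- as.matrix(M_norm)[, selected, drop = FALSE]
  fold <- stratified_folds(labels, folds, seed)
  prob <- numeric(nrow(X))
  fold_stats <- matrix(NA_real_, folds, 4,
                       dimnames = list(NULL, c("auc", "accuracy",
                                               "sensitivity", "specificity")))
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L) stop("degenerate fold: single-class training split")
    mu <- colMeans(X[tr, , drop = FALSE])
    sg <- if (standardize) apply(X[tr, , drop = FALSE], 2, sd) else rep(1, ncol(X))
    sg[sg == 0 | is.na(sg)] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sg, "/")
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, mu), 2, sg, "/")
    fit <- ridge_logistic(Xtr, y[tr], lambda = lambda)
    p <- fit$predict(Xte)
    prob[!tr] <- p
    if (length(unique(y[!tr])) == 2L) {
      fold_stats[f, "auc"] <- roc_auc(p, y[!tr])
    }
    fold_stats[f, 2:4] <- binary_metrics(p, y[!tr])
  }
  if (anyNA(fold_stats[, "auc"])) {
    warning("single-class held-out fold(s): fold AUC averaged over ",
            sum(!is.na(fold_stats[, "auc"])), " folds")
  }
  structure(list(auc = mean(fold_stats[, "auc"], na.rm = TRUE),
                 accuracy = mean(fold_stats[, "accuracy"], na.rm = TRUE),
                 sensitivity = mean(fold_stats[, "sensitivity"], na.rm = TRUE),
                 specificity = mean(fold_stats[, "specificity"], na.rm = TRUE),
                 fold_auc = fold_stats[, "auc"],
                 pooled_auc = roc_auc(prob, y),
                 prob = prob, folds = folds, seed = seed),
            class = "petsym_cv")
}

#' @export
print.petsym_cv <- function(x, ...) {
  cat(sprintf(paste0("<petsym_cv> %d-fold CV: AUC %.3f (pooled %.3f), ",
                     "acc %.3f, sens %.3f, spec %.3f\n"),
              x$folds, x$auc, x$pooled_auc, x$accuracy, x$sensitivity,
              x$specificity))
  invisible(x)
}

#' Baseline classifiers for the symmetricity diagnosis
#'
#' Runs, under the same cross-validation harness as [diagnose_cv()]:
#' each single feature alone (mono-feature), all features, and a
#' PCA-reduced model (components fitted on the training fold only,
#' enough to explain `pca_var` of the variance). With all components
#' retained, PCA + ridge is equivalent to the all-features ridge model
#' (rotation invariance of the L2 penalty).
#'
#' @inheritParams diagnose_cv
#' @param pca_var fraction of variance the PCA components must explain
#'   (1 keeps all components).
#' @param mono_features column indices to evaluate individually
#'   (default: all columns).
#' @return data frame with one row per baseline (`feature_set`, `auc`,
#'   `accuracy`, `sensitivity`, `specificity`).
#' @export
diagnosis_baselines <- function(M_norm, labels = attr(M_norm, "labels"),
                                folds = 10L, seed = 1L, lambda = 1.0,
                                pca_var = 0.95,
                                mono_features = seq_len(ncol(M_norm))) {
  row_of <- function(name, cv) {
    data.frame(feature_set = name, auc = cv$auc, accuracy = cv$accuracy,
               sensitivity = cv$sensitivity, specificity = cv$specificity)
  }
  mono <- lapply(mono_features, function(j) {
    cv <- suppressWarnings(diagnose_cv(M_norm, labels, selected = j,
                                       folds = folds, seed = seed,
                                       lambda = lambda))
    nm <- colnames(M_norm)[j]
    row_of(paste0("mono:", if (is.null(nm)) j else nm), cv)
  })
  all_cv <- suppressWarnings(diagnose_cv(M_norm, labels,
                                         folds = folds, seed = seed,
                                         lambda = lambda))
  pca_cv <- suppressWarnings(pca_diagnose_cv(M_norm, labels, folds, seed,
                                             lambda, pca_var))
  out <- rbind(do.call(rbind, mono), row_of("all_features", all_cv),
               row_of(sprintf("pca_%.0f%%", 100 * pca_var), pca_cv))
  rownames(out) <- NULL
  out
}

# PCA (train-fold only) + ridge logistic under the shared CV harness.
pca_diagnose_cv <- function(M_norm, labels, folds, seed, lambda, pca_var) {
  y <- as.integer(labels == "patient")
  X <- as.matrix(M_norm)
  fold <- stratified_folds(labels, folds, seed)
  prob <- numeric(nrow(X))
  fold_stats <- matrix(NA_real_, folds, 4)
  for (f in seq_len(folds)) {
    tr <- fold != f
    pc <- prcomp(X[tr, , drop = FALSE], center = TRUE, scale. = FALSE)
    ev <- pc$sdev^2
    ncomp <- if (pca_var >= 1) length(ev) else {
      max(1L, which(cumsum(ev) / sum(ev) >= pca_var)[1])
    }
    ncomp <- min(ncomp, sum(ev > 1e-12))
    Xtr <- pc$x[, seq_len(ncomp), drop = FALSE]
    Xte <- predict(pc, X[!tr, , drop = FALSE])[, seq_len(ncomp), drop = FALSE]
    fit <- ridge_logistic(Xtr, y[tr], lambda = lambda)
    p <- fit$predict(Xte)
    prob[!tr] <- p
    if (length(unique(y[!tr])) == 2L) fold_stats[f, 1] <- roc_auc(p, y[!tr])
    fold_stats[f, 2:4] <- binary_metrics(p, y[!tr])
  }
  structure(list(auc = mean(fold_stats[, 1], na.rm = TRUE),
                 accuracy = mean(fold_stats[, 2], na.rm = TRUE),
                 sensitivity = mean(fold_stats[, 3], na.rm = TRUE),
                 specificity = mean(fold_stats[, 4], na.rm = TRUE),
                 pooled_auc = roc_auc(prob, y), prob = prob,
                 folds = folds, seed = seed),
            class = "petsym_cv")
}
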
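test_that("symmetricity vectors are elementwise absolute distances", {
  expect_equal(symmetricity_vector(c(1, 2), c(3, -2)), c(2, 4))
  f <- rnorm(10)
  expect_equal(symmetricity_vector(f, f), rep(0, 10))
  a <- rnorm(10); b <- rnorm(10)
  expect_identical(symmetricity_vector(a, b), symmetricity_vector(b, a))
  expect_error(symmetricity_vector(1:3, 1:4), "length")
})

test_that("normalize_matrix produces idempotent population z-scores", {
  M <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(2, 4, 9))
  expect_warning(Z <- normalize_matrix(M), "zero-variance.*2")
  r <- sqrt(3 / 2)
  expect_equal(unname(Z[, "a"]), c(-r, 0, r), tolerance = 1e-12)
  expect_equal(unname(Z[, "b"]), c(0, 0, 0))
  expect_equal(colMeans(Z), c(a = 0, b = 0, c = 0), tolerance = 1e-12)
  Z2 <- suppressWarnings(normalize_matrix(Z))
  expect_equal(unclass(Z2)[, ], unclass(Z)[, ], tolerance = 1e-10)
})

test_that("feature clustering recovers redundant column groups deterministically", {
  M <- make_toy_matrix()
  Mn <- normalize_matrix(M)
  cl <- cluster_features(Mn, k = 10)
  expect_length(cl, 30)
  expect_equal(sort(unique(cl)), 1:10)
  # the three columns of each constructed block land in one cluster
  blocks <- split(cl, rep(1:10, each = 3))
  expect_true(all(vapply(blocks, function(b) length(unique(b)) == 1L,
                         logical(1))))
  expect_identical(cl, cluster_features(Mn, k = 10))
  # k = number of columns -> singleton clusters
  expect_equal(sort(unique(cluster_features(Mn, k = 30))), 1:30)
  expect_error(cluster_features(Mn, k = 31), "between 1 and")
})

test_that("FICVR matches hand computation and its invariances", {
  vals <- c(1, 3, 0, 0)
  labs <- c("patient", "patient", "control", "control")
  expect_equal(ficvr(vals, labs), 2)              # |2 - 0| / sqrt(1 + 0)
  expect_equal(ficvr(c(1, 1, 1, 1), labs), 0)
  expect_equal(ficvr(c(2, 2, 1, 1), labs), Inf)   # zero variances, means differ
  # scale and affine invariance (a != 0)
  v <- rnorm(20)
  l <- rep(c("patient", "control"), 10)
  for (a in c(3, -2)) {
    expect_equal(ficvr(a * v + 1, l), ficvr(v, l), tolerance = 1e-12)
  }
  expect_error(ficvr(vals, rep("patient", 4)), "both classes")
})

test_that("select_features picks one maximal-|FICVR| feature per cluster", {
  M <- make_toy_matrix()
  Mn <- normalize_matrix(M)
  sel <- select_features(Mn, k = 10)
  expect_length(sel$selected, 10)
  expect_length(unique(sel$cluster[sel$selected]), 10)
  # exhaustive per-cluster scan
  for (g in 1:10) {
    members <- which(sel$cluster == g)
    best <- max(sel$ficvr[members])
    chosen <- sel$selected[g]
    expect_equal(sel$ficvr[[chosen]], best)
    expect_equal(chosen, members[which.max(sel$ficvr[members])])
  }
  # tie-break toward the lowest index: two identical signal columns share
  # a cluster and the same FICVR, so the first must win
  set.seed(41)
  labs <- rep(c("patient", "control"), c(12, 8))
  sig <- rnorm(20) + 3 * (labs == "patient")
  Mt <- cbind(sig, sig, matrix(rnorm(20 * 4), 20, 4))
  attr(Mt, "labels") <- labs
  Mtn <- suppressWarnings(normalize_matrix(Mt))
  st <- select_features(Mtn, labs, k = 2)
  dup_cluster <- st$cluster[1]
  expect_identical(st$cluster[1], st$cluster[2])
  expect_equal(st$selected[dup_cluster], 1L)
})

test_that("selection is invariant to subject order", {
  M <- make_toy_matrix()
  Mn <- normalize_matrix(M)
  sel <- select_features(Mn, k = 5)
  set.seed(1)
  perm <- sample(nrow(Mn))
  Mp <- Mn[perm, ]
  attr(Mp, "labels") <- attr(Mn, "labels")[perm]
  selp <- select_features(Mp, k = 5)
  expect_identical(sort(sel$selected), sort(selp$selected))
})

test_that("cross-validated diagnosis separates an easy cohort and is seeded", {
  M <- make_toy_matrix()
  Mn <- normalize_matrix(M)
  sel <- select_features(Mn, k = 10)
  cv <- diagnose_cv(Mn, selected = sel$selected, folds = 10, seed = 2)
  expect_equal(cv$auc, 1.0)
  cv2 <- diagnose_cv(Mn, selected = sel$selected, folds = 10, seed = 2)
  expect_identical(cv$fold_auc, cv2$fold_auc)
})

test_that("permuted labels give chance-level AUC", {
  M <- make_toy_matrix()
  Mn <- normalize_matrix(M)
  sel <- select_features(Mn, k = 5)
  set.seed(77)
  aucs <- replicate(20, {
    perm <- sample(attr(Mn, "labels"))
    suppressWarnings(diagnose_cv(Mn, labels = perm, selected = sel$selected,
                                 folds = 5, seed = 3))$pooled_auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("ridge_logistic agrees with glmnet at the same fixed penalty", {
  skip_if_not_installed("glmnet")
  set.seed(8)
  n <- 80
  X <- matrix(rnorm(n * 3), n, 3)
  y <- rbinom(n, 1, plogis(0.5 + X %*% c(1, -1, 0.5)))
  fit <- ridge_logistic(X, y, lambda = 0.3)
  g <- glmnet::glmnet(X, y, family = "binomial", alpha = 0, lambda = 0.3,
                      standardize = FALSE, thresh = 1e-12)
  expect_equal(unname(fit$beta),
               unname(as.numeric(coef(g))), tolerance = 1e-4)
})

test_that("baselines: PCA with all components equals the all-features model", {
  M <- make_toy_matrix(n_pat = 12, n_ctl = 8, p = 12)
  Mn <- normalize_matrix(M)
  all_cv <- diagnose_cv(Mn, folds = 5, seed = 4, standardize = FALSE)
  pca_cv <- petsym:::pca_diagnose_cv(Mn, attr(Mn, "labels"), folds = 5,
                                     seed = 4, lambda = 1, pca_var = 1)
  expect_equal(pca_cv$prob, all_cv$prob, tolerance = 1e-6)
})

test_that("the selected-feature model dominates mono-feature baselines on easy cohorts", {
  wins <- vapply(1:5, function(s) {
    M <- make_toy_matrix(seed = 100 + s)
    Mn <- normalize_matrix(M)
    sel <- select_features(Mn, k = 10)
    sel_auc <- suppressWarnings(
      diagnose_cv(Mn, selected = sel$selected, folds = 5, seed = s))$auc
    tab <- diagnosis_baselines(Mn, folds = 5, seed = s,
                               mono_features = seq(1, 30, by = 3))
    best_mono <- max(tab$auc[grepl("^mono:", tab$feature_set)])
    sel_auc >= best_mono
  }, logical(1))
  expect_true(all(wins))
})
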
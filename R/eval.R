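#' Dice overlap coefficient of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`. Two empty masks are defined to
#' agree perfectly (Dice 1): for control cases both the reference and a
#' correct prediction contain no focus. Empty-vs-nonempty gives 0.
#'
#' @param a,b logical arrays of identical shape.
#' @return number in [0, 1].
#' @export
dice_coef <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  sa <- sum(a)
  sb <- sum(b)
  if (sa + sb == 0L) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with average ranks for ties; equals the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param scores numeric scores (larger = more positive).
#' @param labels 0/1 (or logical) class labels, both classes present.
#' @return number in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Jensen-Shannon divergence of two cubes' intensity histograms
#'
#' Histograms share `bins` equal-width bins over the pooled range of the
#' two cubes; the divergence uses base-2 logarithms, so it lies in
#' [0, 1], is symmetric, and is 0 iff the histograms are equal.
#'
#' @param cube_a,cube_b numeric arrays of identical shape.
#' @param bins number of shared histogram bins (default 64).
#' @return number in [0, 1].
#' @export
js_divergence <- function(cube_a, cube_b, bins = 64L) {
  if (length(cube_a) == 0L || length(cube_b) == 0L) stop("empty cubes")
  if (!identical(dim(cube_a), dim(cube_b))) stop("cube shapes differ")
  rng <- range(c(cube_a, cube_b))
  if (rng[2] <= rng[1]) return(0)
  width <- (rng[2] - rng[1]) / bins
  bin_of <- function(v) pmin(bins, floor((v - rng[1]) / width) + 1)
  p <- tabulate(bin_of(as.numeric(cube_a)), bins) / length(cube_a)
  q <- tabulate(bin_of(as.numeric(cube_b)), bins) / length(cube_b)
  m <- (p + q) / 2
  kl <- function(x, y) {
    ok <- x > 0
    sum(x[ok] * (log2(x[ok]) - log2(y[ok])))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

#' Jensen-Shannon + logistic-regression PoC baseline
#'
#' The classical non-deep baseline: one scalar JS divergence per PoC fed
#' to an L2-penalized logistic regression under the package's stratified
#' CV harness. Self-paired (perfectly symmetric) PoCs have JS 0 and are
#' therefore scored consistently on the normal side of any monotone rule.
#'
#' @param pocs list of `poc` objects (or a [poc_dataset()]).
#' @param labels 0/1 labels per PoC (taken from the dataset if omitted).
#' @param folds CV folds.
#' @param seed fold seed.
#' @param bins histogram bins for [js_divergence()].
#' @return a `petsym_cv` result (see [diagnose_cv()]) with the JS feature
#'   attached as `js`.
#' @export
js_lr_baseline <- function(pocs, labels = NULL, folds = 10L, seed = 1L,
                           bins = 64L) {
  if (inherits(pocs, "poc_dataset")) {
    labels <- labels %||% pocs$labels
    pocs <- pocs$pocs
  }
  stopifnot(!is.null(labels), length(labels) == length(pocs))
  js <- vapply(pocs, function(p) js_divergence(p$cube_a, p$cube_b, bins),
               numeric(1))
  M <- matrix(js, ncol = 1, dimnames = list(NULL, "js"))
  lab <- ifelse(labels == 1, "patient", "control")
  cv <- suppressWarnings(diagnose_cv(M, lab, selected = 1L, folds = folds,
                                     seed = seed))
  cv$js <- js
  cv
}

#' Run the end-to-end phantom pipeline
#'
#' Orchestrates the whole framework on a synthetic cohort: phantom
#' generation, Z-mapping, pair-of-cubes extraction with subject-disjoint
#' splits, Siamese training, heat-map localization (bilateral
#' thresholding then template-based lateralization), asymmetry-index
#' grading, and the JS-LR baseline. Optionally also runs the
#' symmetricity-radiomics diagnosis arm.
#'
#' @param config named list or path to a YAML file. Recognized entries
#'   (defaults in parentheses): `n_patients` (20), `n_controls` (6),
#'   `seed` (1), `noise_sd` (0.05), `contrast_range` (c(0.15, 0.45)),
#'   `shape` (c(48, 56, 48)), `cube_n` (16), `stride` (4),
#'   `train_stride` (8), `epochs` (16), `batch_size` (128),
#'   `augment_positives` (2), `threshold` (NULL = adaptive),
#'   `radiomics` (FALSE), `out_dir` (NULL: no artifacts written).
#' @return an `eval_report`: per-case localization table (`cases`), mean
#'   Dice over patients (`mean_dice`), grading confusion matrix
#'   (`confusion`), polarity/severity accuracy, PoC AUC of the Siamese
#'   model and of the JS-LR baseline, optional radiomics CV metrics, and
#'   the config used.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    n_patients = 20L, n_controls = 6L, seed = 1L, noise_sd = 0.05,
    contrast_range = c(0.15, 0.45), shape = c(48L, 56L, 48L),
    cube_n = 16L, stride = 4L, train_stride = 8L, epochs = 16L,
    batch_size = 128L, augment_positives = 2L, threshold = NULL,
    radiomics = FALSE, out_dir = NULL), config)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cohort <- stage("phantom", generate_cohort(
    cfg$n_patients, cfg$n_controls, contrast_range = cfg$contrast_range,
    seed = cfg$seed, noise_sd = cfg$noise_sd, shape = cfg$shape))
  is_patient <- vapply(cohort, function(cs) any(cs$focus_mask), logical(1))

  ds <- stage("poc", poc_dataset(cohort, n = cfg$cube_n,
                                 stride = cfg$train_stride,
                                 seed = cfg$seed,
                                 augment_positives = cfg$augment_positives))
  scfg <- siamese_config("tiny", input_n = cfg$cube_n,
                         epochs = cfg$epochs, batch_size = cfg$batch_size,
                         seed = cfg$seed)
  model <- stage("train", siamese_train(siamese_build(scfg), ds))

  test_idx <- which(ds$split == "test")
  poc_auc <- if (length(unique(ds$labels[test_idx])) == 2L) {
    roc_auc(predict(model, ds$pocs[test_idx]), ds$labels[test_idx])
  } else NA_real_
  js_cv <- stage("js_lr", js_lr_baseline(ds$pocs[test_idx],
                                         ds$labels[test_idx],
                                         folds = 5L, seed = cfg$seed))

  template <- stage("template", normative_template(cohort))
  cases <- data.frame(case = seq_along(cohort),
                      label = ifelse(is_patient, "patient", "control"),
                      dice = NA_real_, truth_level = NA_character_,
                      pred_level = NA_character_,
                      truth_polarity = NA_character_,
                      pred_polarity = NA_character_)
  heatmaps <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    cs <- cohort[[i]]
    zm <- to_zmap(cs$volume)
    hm <- stage("heatmap", siamese_heatmap(model, zm, n = cfg$cube_n,
                                           stride = cfg$stride))
    heatmaps[[i]] <- hm
    pred <- stage("localize", localize_focus(hm, threshold = cfg$threshold))
    pred <- lateralize_focus(pred, zm, template)
    cases$dice[i] <- dice_coef(pred, cs$focus_mask)
    if (is_patient[i]) {
      cases$truth_level[i] <- paste(cs$truth$severity,
                                    paste0(cs$truth$polarity, "metabolism"))
      cases$truth_polarity[i] <- cs$truth$polarity
      if (any(pred)) {
        g <- stage("grade", grade_metabolic(ai_profile(cs$volume, pred)))
        cases$pred_level[i] <- g$level
        cases$pred_polarity[i] <- g$polarity
      }
    }
  }
  pat <- cases[cases$label == "patient", ]
  confusion <- table(truth = pat$truth_level, predicted = pat$pred_level,
                     useNA = "ifany")
  report <- structure(list(
    cases = cases,
    mean_dice = mean(pat$dice),
    poc_auc = poc_auc,
    js_lr_auc = js_cv$auc,
    polarity_accuracy = mean(pat$pred_polarity == pat$truth_polarity,
                             na.rm = FALSE),
    severity_accuracy = mean(pat$pred_level == pat$truth_level,
                             na.rm = FALSE),
    confusion = confusion,
    model_history = model$history,
    config = cfg,
    seed = cfg$seed),
    class = "eval_report")

  if (isTRUE(cfg$radiomics)) {
    report$radiomics <- radiomics_arm(cohort, seed = cfg$seed)
  }
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(heatmaps)) {
      write_volume(heatmaps[[i]]$data,
                   file.path(cfg$out_dir, sprintf("heatmap_%02d.nii.gz", i)),
                   spacing = heatmaps[[i]]$spacing)
    }
    json <- report[c("mean_dice", "poc_auc", "js_lr_auc",
                     "polarity_accuracy", "severity_accuracy", "seed")]
    jsonlite::write_json(json, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

# Symmetricity-radiomics diagnosis on a phantom cohort: extract the 386
# features of both temporal ROIs per case, build the normalized
# symmetricity matrix, select 10 features, cross-validate.
radiomics_arm <- function(cohort, k = 10L, folds = 10L, seed = 1L) {
  vecs <- lapply(cohort, function(cs) {
    zm <- to_zmap(cs$volume)
    symmetricity_vector(extract_all(zm, cs$roi_left),
                        extract_all(zm, cs$roi_right))
  })
  labels <- vapply(cohort, function(cs) {
    if (any(cs$focus_mask)) "patient" else "control"
  }, character(1))
  M <- symmetricity_matrix(vecs, labels)
  Mn <- suppressWarnings(normalize_matrix(M))
  sel <- select_features(Mn, labels, k = k)
  cv <- suppressWarnings(diagnose_cv(Mn, labels, selected = sel$selected,
                                     folds = folds, seed = seed))
  list(selection = sel, cv = cv, matrix = Mn)
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat(sprintf("  mean Dice (patients):   %.3f\n", x$mean_dice))
  cat(sprintf("  PoC AUC (Siamese/test): %s\n",
              ifelse(is.na(x$poc_auc), "NA", sprintf("%.3f", x$poc_auc))))
  cat(sprintf("  PoC AUC (JS-LR):        %.3f\n", x$js_lr_auc))
  cat(sprintf("  polarity accuracy:      %s\n",
              ifelse(is.na(x$polarity_accuracy), "NA",
                     sprintf("%.0f%%", 100 * x$polarity_accuracy))))
  cat(sprintf("  severity accuracy:      %s\n",
              ifelse(is.na(x$severity_accuracy), "NA",
                     sprintf("%.0f%%", 100 * x$severity_accuracy))))
  cat("  grading confusion matrix:\n")
  print(x$confusion)
  invisible(x)
}
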
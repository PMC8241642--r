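test_that("Dice handles identical, disjoint, partial and empty masks", {
  d <- c(10, 10, 10)
  a <- array(FALSE, d); a[1:5, 1:5, 1:4] <- TRUE            # 100 voxels
  b <- array(FALSE, d); b[1:5, 1:5, 3:6] <- TRUE            # 100, overlap 50
  expect_equal(dice_coef(a, a), 1)
  expect_equal(dice_coef(a, b), 0.5)
  disj <- array(FALSE, d); disj[8:10, 8:10, 8:10] <- TRUE
  expect_equal(dice_coef(a, disj), 0)
  expect_equal(dice_coef(array(FALSE, d), array(FALSE, d)), 1)
  expect_equal(dice_coef(a, array(FALSE, d)), 0)
  expect_identical(dice_coef(a, b), dice_coef(b, a))
  expect_error(dice_coef(a, array(FALSE, c(5, 5, 5))), "differ")
})

test_that("roc_auc equals the all-pairs comparison count and behaves at the null", {
  set.seed(15)
  scores <- rnorm(50)
  labels <- rbinom(50, 1, 0.4)
  scores[labels == 1] <- scores[labels == 1] + 0.5
  scores[3] <- scores[7]  # force a tie
  pairwise <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    cmp <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
    mean(cmp)
  }
  expect_equal(roc_auc(scores, labels), pairwise(scores, labels),
               tolerance = 1e-12)
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)

  set.seed(16)
  s0 <- rnorm(1e4); y0 <- rbinom(1e4, 1, 0.5)
  expect_lt(abs(roc_auc(s0, y0) - 0.5), 0.02)

  # complement identity for tie-free scores
  expect_equal(roc_auc(scores + rnorm(50, 0, 1e-9), labels) +
                 roc_auc(-(scores + rnorm(50, 0, 1e-9)), labels), 1,
               tolerance = 1e-6)
  expect_error(roc_auc(scores, rep(1, 50)), "both classes")
})

test_that("roc_auc agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(20)
  s <- rnorm(80); y <- rbinom(80, 1, 0.5)
  s[y == 1] <- s[y == 1] + 1
  expect_equal(roc_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("JS divergence is a bounded symmetric histogram distance", {
  a <- array(rnorm(64), c(4, 4, 4))
  expect_equal(js_divergence(a, a), 0)
  # disjoint supports: maximum 1 bit
  lo <- array(runif(64, 0, 1), c(4, 4, 4))
  hi <- array(runif(64, 9, 10), c(4, 4, 4))
  expect_equal(js_divergence(lo, hi), 1)
  # hand-computed two-bin case: histograms (3/4, 1/4) vs (1/4, 3/4)
  pa <- array(c(0, 0, 0, 1), c(4, 1, 1))
  pb <- array(c(0, 1, 1, 1), c(4, 1, 1))
  hand <- 0.75 * log2(0.75 / 0.5) + 0.25 * log2(0.25 / 0.5)
  expect_equal(js_divergence(pa, pb, bins = 2), hand, tolerance = 1e-12)
  expect_equal(js_divergence(pa, pb), js_divergence(pb, pa))
  b <- array(rnorm(64, 2), c(4, 4, 4))
  expect_gte(js_divergence(a, b), 0)
  expect_lte(js_divergence(a, b), 1)
})

test_that("the JS-LR baseline separates the trivially separable PoC set", {
  ds <- separable_poc_dataset(n = 160, seed = 31)
  cv <- js_lr_baseline(ds, folds = 5, seed = 1)
  expect_gte(cv$auc, 0.9)
  # self-paired PoCs have JS exactly 0
  self_js <- cv$js[ds$labels == 0]
  expect_true(all(self_js == 0))
  cv2 <- js_lr_baseline(ds, folds = 5, seed = 1)
  expect_identical(cv$prob, cv2$prob)
})

test_that("the demo pipeline runs end to end and is reproducible", {
  cfgl <- list(n_patients = 4, n_controls = 2, seed = 5,
               shape = c(40L, 48L, 40L), epochs = 2L, batch_size = 64L,
               train_stride = 8L, stride = 4L, augment_positives = 1L)
  rep1 <- run_pipeline(cfgl)
  expect_s3_class(rep1, "eval_report")
  expect_equal(nrow(rep1$cases), 6)
  expect_true(all(rep1$cases$dice >= 0 & rep1$cases$dice <= 1))
  expect_true(is.finite(rep1$js_lr_auc))
  expect_true(!is.null(rep1$confusion))
  rep2 <- run_pipeline(cfgl)
  expect_identical(rep1$cases, rep2$cases)
  expect_identical(rep1$mean_dice, rep2$mean_dice)
})
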
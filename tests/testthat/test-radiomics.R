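test_that("quantization uses half-open equal-width bins, top inclusive", {
  d <- c(3, 1, 1)
  vals <- array(c(0, 0.5, 1), d)
  q <- quantize_roi(vals, array(TRUE, d), G = 4)
  expect_equal(as.integer(q$labels), c(1L, 3L, 4L))

  # G = 2 on a 0..1 ramp: lower half -> 1, upper half (max inclusive) -> 2
  ramp <- array(seq(0, 1, length.out = 8), c(8, 1, 1))
  q2 <- quantize_roi(ramp, array(TRUE, c(8, 1, 1)), G = 2)
  expect_equal(as.integer(q2$labels), c(rep(1L, 4), rep(2L, 4)))

  const <- quantize_roi(array(2, d), array(TRUE, d), G = 8)
  expect_true(all(const$labels == 1L))
  expect_error(quantize_roi(vals, array(FALSE, d)), "empty")
})

test_that("intensity features use population moments and excess kurtosis", {
  f <- intensity_features(c(-1, 1))
  expect_equal(unname(f[c("mean", "variance")]), c(0, 1))
  expect_equal(unname(f["energy"]), 2)

  fc <- intensity_features(rep(3, 10))
  expect_equal(unname(fc[c("variance", "skewness", "kurtosis", "entropy")]),
               c(0, 0, 0, 0))

  set.seed(99)
  g <- intensity_features(rnorm(1e5))
  expect_lt(abs(g[["skewness"]]), 0.05)
  expect_lt(abs(g[["kurtosis"]]), 0.05)

  expect_error(intensity_features(1), "at least 2")
})

test_that("GLCM features match hand-enumerable cases", {
  # constant ROI: single cell (1,1) with all mass
  qc <- quantize_roi(array(5, c(3, 3, 3)), array(TRUE, c(3, 3, 3)), 8)
  fc <- glcm_features(qc)
  expect_equal(unname(fc[c("energy", "contrast", "entropy")]), c(1, 0, 0))

  # 2x1x1 ROI with levels (1,2): symmetric pair mass 0.5/0.5, contrast 1
  q2 <- list(labels = array(c(1L, 2L), c(2, 1, 1)), G = 2L)
  class(q2) <- "quantized_roi"
  P <- petsym:::glcm_matrix(q2)
  expect_equal(P, matrix(c(0, .5, .5, 0), 2))
  expect_equal(unname(glcm_features(q2)["contrast"]), 1)

  expect_error(glcm_features(list(labels = array(1L, c(1, 1, 1)), G = 2L)),
               "no voxel pairs")
})

test_that("texture features are invariant to left-right mirroring of the ROI", {
  q <- random_qroi(d = 5, G = 5, seed = 8)
  qm <- q
  qm$labels <- flip_lr(q$labels)
  expect_equal(glcm_features(q), glcm_features(qm), tolerance = 1e-12)
  expect_equal(ngtdm_features(q), ngtdm_features(qm), tolerance = 1e-12)
  expect_equal(glzsm_features(q), glzsm_features(qm), tolerance = 1e-12)
})

test_that("NGTDM of a constant ROI has zero contrast", {
  q <- quantize_roi(array(1, c(3, 3, 3)), array(TRUE, c(3, 3, 3)), 4)
  f <- ngtdm_features(q)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["busyness"]), 0)
})

test_that("GLZSM closed forms: single zone and checkerboard", {
  # constant ROI of V voxels: one zone of size V, ZP = 1/V
  V <- 24
  q <- quantize_roi(array(1, c(2, 3, 4)), array(TRUE, c(2, 3, 4)), 4)
  f <- glzsm_features(q)
  expect_equal(unname(f["ZP"]), 1 / V)
  expect_equal(unname(f["LZE"]), V^2)
  expect_equal(unname(f["SZE"]), 1 / V^2)

  # checkerboard: 26-connectivity joins diagonal same-level voxels, so use
  # a 1D stripe where alternating levels give all zones size 1
  d <- c(8, 1, 1)
  stripe <- array(rep(c(0, 1), 4), d)
  qs <- quantize_roi(stripe, array(TRUE, d), 2)
  fs <- glzsm_features(qs)
  expect_equal(unname(fs["SZE"]), 1)
  expect_equal(unname(fs["ZP"]), 1)

  # shifting all gray levels up changes HGZE but not ZSN
  q1 <- list(labels = array(c(1L, 1L, 2L, 2L), c(4, 1, 1)), G = 4L)
  q2 <- list(labels = array(c(3L, 3L, 4L, 4L), c(4, 1, 1)), G = 4L)
  class(q1) <- class(q2) <- "quantized_roi"
  expect_false(glzsm_features(q1)[["HGZE"]] == glzsm_features(q2)[["HGZE"]])
  expect_equal(glzsm_features(q1)[["ZSN"]], glzsm_features(q2)[["ZSN"]])
})

test_that("histogram features are order statistics of the ROI", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  f <- histogram_features(v)
  expect_equal(unname(f["p50"]), 5.5)
  expect_equal(unname(f["iqr"]), unname(quantile(v, .75) - quantile(v, .25)))
  expect_equal(unname(f["range"]), 9)
  expect_equal(unname(f["mad_mean"]), mean(abs(v - mean(v))))
})
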
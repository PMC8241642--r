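test_that("cube origin grids tile with an edge-aligned final cube", {
  expect_equal(petsym:::cube_origins(96, 48, 48), c(1, 49))   # 2 per axis
  expect_equal(petsym:::cube_origins(48, 48, 48), 1)
  expect_equal(petsym:::cube_origins(24, 16, 8), c(1, 9))
  expect_equal(petsym:::cube_origins(20, 16, 8), c(1, 5))     # edge-aligned tail
  expect_error(petsym:::cube_origins(10, 16, 8), "smaller")
})

test_that("partition pairs congruent mirrored cubes over both hemispheres", {
  d <- c(16, 8, 8)
  set.seed(2)
  a <- array(rnorm(prod(d)), d)
  z <- as_toy_zmap(a)
  pocs <- partition_pocs(z, n = 8, stride = 8)
  expect_length(pocs, 2)  # one per hemisphere
  expect_setequal(vapply(pocs, `[[`, character(1), "side"), c("left", "right"))
  pl <- pocs[[which(vapply(pocs, `[[`, character(1), "side") == "left")]]
  expect_identical(pl$cube_a, a[1:8, , ])
  expect_identical(pl$cube_b, a[16:9, , ])

  # mirror-symmetric input: every PoC has identical cubes
  sym <- (a + flip_lr(a)) / 2
  psym <- partition_pocs(as_toy_zmap(sym), n = 8, stride = 4)
  expect_true(all(vapply(psym, function(p) identical(p$cube_a, p$cube_b),
                         logical(1))))
  expect_error(partition_pocs(z, n = 32), "smaller")
})

test_that("low brain-mask coverage cubes are dropped", {
  d <- c(16, 8, 8)
  mask <- array(FALSE, d)
  mask[7:10, , ] <- TRUE  # only near the midline
  z <- as_toy_zmap(array(rnorm(prod(d)), d), mask)
  pocs <- partition_pocs(z, n = 8, stride = 8, min_coverage = 0.3)
  expect_length(pocs, 0)
  pocs2 <- partition_pocs(z, n = 8, stride = 8, min_coverage = 0.2)
  expect_length(pocs2, 2)
})

test_that("labelling is inclusive at the threshold and monotone in the mask", {
  d <- c(16, 8, 8)
  z <- as_toy_zmap(array(rnorm(prod(d)), d))
  pocs <- partition_pocs(z, n = 8, stride = 8)

  empty <- array(FALSE, d)
  expect_true(all(vapply(label_pocs(pocs, empty), `[[`, numeric(1),
                         "label") == 0))

  # exactly min_frac * n^3 voxels: 0.005 * 512 = 2.56 -> threshold at 3 with
  # min_frac chosen to make the boundary integral
  thr_frac <- 4 / 512
  m4 <- array(FALSE, d); m4[1:4, 1, 1] <- TRUE   # 4 voxels in the left cube
  m3 <- array(FALSE, d); m3[1:3, 1, 1] <- TRUE
  lab4 <- label_pocs(pocs, m4, min_frac = thr_frac)
  lab3 <- label_pocs(pocs, m3, min_frac = thr_frac)
  expect_true(all(vapply(lab4, `[[`, numeric(1), "label") == 1))  # both sides: or-rule
  expect_true(all(vapply(lab3, `[[`, numeric(1), "label") == 0))

  # monotone: growing the mask never flips positive -> negative
  big <- m4; big[1:6, 1:4, 1:4] <- TRUE
  labb <- label_pocs(pocs, big, min_frac = thr_frac)
  expect_true(all(vapply(labb, `[[`, numeric(1), "label") >=
                    vapply(lab4, `[[`, numeric(1), "label")))

  # a focus filling one cube labels that PoC positive everywhere relevant
  full <- array(FALSE, d); full[1:8, , ] <- TRUE
  expect_true(all(vapply(label_pocs(pocs, full), `[[`, numeric(1),
                         "label") == 1))
})

test_that("augmentation preserves labels, pair symmetry and is seeded", {
  d <- c(16, 8, 8)
  z <- as_toy_zmap(array(rnorm(prod(d)), d))
  poc <- label_pocs(partition_pocs(z, n = 8, stride = 8),
                    array(FALSE, d))[[1]]

  # identity augmentation: all transform draws forced to no-ops
  set.seed(1)
  id <- augment_poc(poc, flip_prob = 0, alpha_max = 0,
                    scale_range = c(1, 1), shift_range = c(0, 0))
  expect_identical(id$cube_a, poc$cube_a)
  expect_identical(id$cube_b, poc$cube_b)

  # symmetric pair stays symmetric under the shared transform
  symp <- poc
  symp$cube_b <- symp$cube_a
  set.seed(9)
  ag <- augment_poc(symp)
  expect_equal(ag$cube_a, ag$cube_b, tolerance = 1e-12)
  expect_identical(ag$label, symp$label)

  set.seed(5); a1 <- augment_poc(poc)
  set.seed(5); a2 <- augment_poc(poc)
  expect_identical(a1$cube_a, a2$cube_a)
})

test_that("sample weights are inverse-frequency with equal class masses", {
  expect_equal(sample_weights(rep(c(0, 1), 50)), rep(1, 100))
  w <- sample_weights(rep(c(0, 1), c(90, 10)))
  expect_equal(unique(w[1:90]), 100 / 180)
  expect_equal(unique(w[91:100]), 5)
  expect_equal(sum(w[1:90]), sum(w[91:100]))
  expect_equal(sum(w), 100)
  expect_true(all(w > 0))
  expect_error(sample_weights(rep(1, 5)), "both classes")
})

test_that("poc_dataset builds subject-disjoint splits with balanced weights", {
  cohort <- small_cohort(n_pat = 4, n_ctl = 2, seed = 3)
  ds <- poc_dataset(cohort, n = 16, stride = 8, seed = 2,
                    augment_positives = 1)
  expect_s3_class(ds, "poc_dataset")
  # subjects never straddle splits
  tab <- table(ds$subjects, ds$split)
  expect_true(all(rowSums(tab > 0) == 1))
  tr <- ds$split == "train"
  expect_true(all(ds$weights[tr] > 0))
  y <- ds$labels[tr]
  expect_equal(sum(ds$weights[tr][y == 1]), sum(ds$weights[tr][y == 0]),
               tolerance = 1e-9)
})
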
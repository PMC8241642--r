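test_that("model construction is seeded with a 1024-entry embedding", {
  cfg <- siamese_config("tiny", seed = 4)
  m1 <- siamese_build(cfg)
  m2 <- siamese_build(cfg)
  expect_identical(m1$params, m2$params)
  m3 <- siamese_build(siamese_config("tiny", seed = 5))
  expect_false(identical(m1$params, m3$params))

  set.seed(1)
  cube <- array(rnorm(16^3), c(16, 16, 16))
  t0 <- proc.time()
  e <- siamese_embed(m1, cube)
  expect_lt((proc.time() - t0)[["elapsed"]], 1)
  expect_length(e, 1024)
  expect_true(all(is.finite(e)))
})

test_that("scores are symmetric, probabilistic, and constant on self-pairs", {
  m <- siamese_build(siamese_config("tiny", seed = 2))
  set.seed(3)
  for (i in 1:5) {
    a <- array(rnorm(16^3), c(16, 16, 16))
    b <- array(rnorm(16^3), c(16, 16, 16))
    p_ab <- siamese_score(m, list(cube_a = a, cube_b = b))
    p_ba <- siamese_score(m, list(cube_a = b, cube_b = a))
    expect_identical(p_ab, p_ba)
    expect_gt(p_ab, 0)
    expect_lt(p_ab, 1)
    p_self <- siamese_score(m, list(cube_a = a, cube_b = a))
    expect_identical(p_self, plogis(m$params$head$b))
  }
})

test_that("training refuses single-class sets and tracks the best epoch", {
  ds <- separable_poc_dataset(n = 60, seed = 8)
  ds$labels[ds$split == "train"] <- 0
  m <- siamese_build(siamese_config("tiny", seed = 1, epochs = 2))
  expect_error(siamese_train(m, ds), "both classes")

  ds2 <- separable_poc_dataset(n = 120, seed = 9)
  m2 <- siamese_train(siamese_build(siamese_config("tiny", seed = 1,
                                                   epochs = 3,
                                                   batch_size = 32)), ds2)
  expect_true(m2$trained)
  h <- m2$history
  best <- which(h$val_auc == max(h$val_auc))
  expect_equal(m2$best_epoch, best[which.min(h$val_loss[best])])
})

test_that("numerical gradients match the backpropagated gradients", {
  # finite-difference check of the full loss on a micro configuration
  cfg <- siamese_config("tiny", input_n = 8L, stem_channels = 2L,
                        stage_channels = c(2L, 3L), stage_blocks = c(1L, 1L),
                        stage_strides = c(1L, 2L), embedding_dim = 6L,
                        seed = 3)
  m <- siamese_build(cfg)
  set.seed(4)
  a <- array(rnorm(8^3), c(8, 8, 8))
  b <- array(rnorm(8^3), c(8, 8, 8))
  y <- 1
  loss_at <- function(params) {
    ea <- petsym:::tower_forward(params, petsym:::stack_cubes(list(a)))$embed
    eb <- petsym:::tower_forward(params, petsym:::stack_cubes(list(b)))$embed
    u <- abs(ea - eb)
    p <- plogis(drop(crossprod(params$head$w, u)) + params$head$b)
    -(y * log(p) + (1 - y) * log(1 - p))
  }
  # analytic gradients
  fa <- petsym:::tower_forward(m$params, petsym:::stack_cubes(list(a)))
  fb <- petsym:::tower_forward(m$params, petsym:::stack_cubes(list(b)))
  u <- abs(fa$embed - fb$embed)
  p <- plogis(drop(crossprod(m$params$head$w, u)) + m$params$head$b)
  dz <- p - y
  du <- m$params$head$w * dz
  gea <- du * sign(fa$embed - fb$embed)
  ga <- petsym:::tower_backward(m$params, fa$cache, gea)
  gb <- petsym:::tower_backward(m$params, fb$cache, -gea)
  g <- petsym:::add_grads(ga, gb)

  eps <- 1e-5
  check <- function(s, b, conv, idx) {
    pp <- m$params
    pm <- m$params
    pp$stages[[s]][[b]][[conv]]$w[idx] <- pp$stages[[s]][[b]][[conv]]$w[idx] + eps
    pm$stages[[s]][[b]][[conv]]$w[idx] <- pm$stages[[s]][[b]][[conv]]$w[idx] - eps
    num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
    ana <- g$stages[[s]][[b]][[conv]]$w[idx]
    expect_equal(ana, num, tolerance = 1e-4)
  }
  check(1L, 1L, "conv1", 5L)   # weight inside block 1
  check(2L, 1L, "conv2", 2L)
  check(2L, 1L, "proj", 1L)
  # stem weights (3-level path)
  pp <- m$params; pm <- m$params
  pp$stem$w[4] <- pp$stem$w[4] + eps
  pm$stem$w[4] <- pm$stem$w[4] - eps
  expect_equal(g$stem$w[4], (loss_at(pp) - loss_at(pm)) / (2 * eps),
               tolerance = 1e-4)
  # fc weights
  pp <- m$params; pm <- m$params
  pp$fc$W[3, 2] <- pp$fc$W[3, 2] + eps
  pm$fc$W[3, 2] <- pm$fc$W[3, 2] - eps
  expect_equal(g$fc$W[3, 2], (loss_at(pp) - loss_at(pm)) / (2 * eps),
               tolerance = 1e-4)
})

test_that("heat maps are constant on symmetric inputs and bounded in [0,1]", {
  cs <- generate_case(phantom_config(shape = c(40, 48, 40),
                                     focus_contrast = 0, noise_sd = 0,
                                     seed = 12))
  zm <- to_zmap(cs$volume)
  m <- siamese_build(siamese_config("tiny", seed = 2))
  hm <- siamese_heatmap(m, zm, n = 16, stride = 8, allow_untrained = TRUE)
  expect_error(siamese_heatmap(m, zm), "untrained")
  covered <- zm$mask & hm$coverage > 0
  expect_equal(unique(hm$data[covered]), hm$baseline)
  expect_true(all(hm$data >= 0 & hm$data <= 1))
  expect_identical(dim(hm$data), dim(zm$data))
})

test_that("localization thresholds behave monotonically at the extremes", {
  cs <- generate_case(phantom_config(shape = c(40, 48, 40),
                                     focus_contrast = -0.4, noise_sd = 0.05,
                                     seed = 14))
  zm <- to_zmap(cs$volume)
  m <- siamese_build(siamese_config("tiny", seed = 2))
  hm <- siamese_heatmap(m, zm, n = 16, stride = 8, allow_untrained = TRUE)

  all0 <- localize_focus(hm, threshold = 0, keep = "all")
  expect_identical(all0, zm$mask)                  # whole brain mask
  over <- localize_focus(hm, threshold = max(hm$data) + 1e-9)
  expect_false(any(over))
  # lowering the threshold never shrinks the raw mask
  m1 <- localize_focus(hm, threshold = 0.52, keep = "all")
  m2 <- localize_focus(hm, threshold = 0.45, keep = "all")
  expect_true(all(m2[m1]))

  # adaptive mode on a null (symmetric, noise-free) case gives no focus
  null <- generate_case(phantom_config(shape = c(40, 48, 40),
                                       focus_contrast = 0, noise_sd = 0,
                                       seed = 15))
  zn <- to_zmap(null$volume)
  hn <- siamese_heatmap(m, zn, n = 16, stride = 8, allow_untrained = TRUE)
  expect_false(any(localize_focus(hn)))
})

test_that("lateralization keeps the hemisphere deviating from the template", {
  cohort <- small_cohort(n_pat = 1, n_ctl = 2, seed = 21, noise_sd = 0.02)
  template <- normative_template(cohort)
  cs <- cohort[[1]]
  zm <- to_zmap(cs$volume)
  bilat <- cs$focus_mask | flip_lr(cs$focus_mask)
  uni <- lateralize_focus(bilat, zm, template)
  expect_identical(uni, cs$focus_mask)
  expect_identical(lateralize_focus(array(FALSE, dim(bilat)), zm, template),
                   array(FALSE, dim(bilat)))
})
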
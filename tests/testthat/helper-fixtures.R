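# Shared fixtures, all generated in code.

# A small brain_volume with an all-TRUE mask.
toy_volume <- function(d = c(6, 6, 6), seed = 1) {
  set.seed(seed)
  brain_volume(array(rnorm(prod(d), 100, 10), d), mask = array(TRUE, d))
}

# A zmap-classed object from a plain array (all-TRUE mask).
as_toy_zmap <- function(a, mask = array(TRUE, dim(a))) {
  structure(list(data = a, spacing = c(1, 1, 1), mask = mask),
            class = c("zmap", "brain_volume"))
}

# Random quantized ROI on a full dxdxd grid (G gray levels).
random_qroi <- function(d = 4, G = 4, seed = 1) {
  set.seed(seed)
  vals <- array(runif(d^3), c(d, d, d))
  quantize_roi(vals, array(TRUE, c(d, d, d)), G)
}

# Tiny phantom cohort for fast pipeline-ish tests.
small_cohort <- function(n_pat = 3, n_ctl = 2, seed = 7, noise_sd = 0.05) {
  generate_cohort(n_pat, n_ctl, seed = seed, noise_sd = noise_sd,
                  shape = c(40L, 48L, 40L))
}

# Labelled symmetricity-style matrix built from latent block factors:
# blocks of 3 columns share one latent (one anti-correlated), and the
# first k_signal blocks carry a patient-vs-control shift on the latent.
make_toy_matrix <- function(n_pat = 18, n_ctl = 12, p = 30, k_signal = 4,
                            shift = 3, seed = 5) {
  set.seed(seed)
  n <- n_pat + n_ctl
  labels <- rep(c("patient", "control"), c(n_pat, n_ctl))
  M <- matrix(0, n, p)
  nblock <- p %/% 3L
  for (b in seq_len(nblock)) {
    u <- rnorm(n)
    if (b <= k_signal) u[labels == "patient"] <- u[labels == "patient"] + shift
    j <- 3L * (b - 1L)
    M[, j + 1] <- u + rnorm(n, 0, 0.1)
    M[, j + 2] <- 2 * u + rnorm(n, 0, 0.1)
    M[, j + 3] <- -u + rnorm(n, 0, 0.1)
  }
  colnames(M) <- sprintf("f%02d", seq_len(p))
  structure(M, labels = labels,
            class = c("symmetricity_matrix", "matrix", "array"))
}

# Linearly separable synthetic PoC dataset: negatives are identical
# pairs, positives differ by a large constant blob in one cube.
separable_poc_dataset <- function(n = 400, seed = 11, n_cube = 16) {
  set.seed(seed)
  labels <- rep(c(0, 1), length.out = n)
  mk <- function(pos) {
    base <- array(rnorm(n_cube^3, 0, 0.5), rep(n_cube, 3))
    a <- base
    if (pos) {
      ctr <- sample(seq(5, n_cube - 4), 3, replace = TRUE)
      for (i in -3:3) for (j in -3:3) for (k in -3:3) {
        if (i^2 + j^2 + k^2 <= 9) {
          a[ctr[1] + i, ctr[2] + j, ctr[3] + k] <-
            a[ctr[1] + i, ctr[2] + j, ctr[3] + k] + 2
        }
      }
    }
    structure(list(cube_a = a, cube_b = base, origin = c(1L, 1L, 1L),
                   side = "left", label = as.numeric(pos), subject = "S1"),
              class = "poc")
  }
  pocs <- lapply(labels == 1, mk)
  split <- sample(rep(c("train", "val", "test"), times = round(n * c(.6, .2, .2))))
  split <- split[seq_len(n)]
  w <- rep(NA_real_, n)
  w[split == "train"] <- sample_weights(labels[split == "train"])
  structure(list(pocs = pocs, split = split, labels = labels,
                 subjects = rep("S1", n), weights = w,
                 n = n_cube, stride = n_cube %/% 2L, seed = seed),
            class = "poc_dataset")
}
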
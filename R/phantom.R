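#' Phantom generator configuration
#'
#' Parameters of the synthetic symmetric brain phantom. The phantom stands
#' in for a clinical cohort: an exactly mirror-symmetric smooth background
#' (ellipsoidal brain with a cortical-like bright shell), an optional
#' unilateral spherical focus whose intensity is scaled by `1 + delta`
#' inside a temporal region of interest, point-spread blurring, and
#' additive Gaussian noise.
#'
#' Defaults: a 48 x 56 x 48 grid at 3 mm spacing, blur FWHM 4.4 mm
#' (matching the reconstructed resolution of a clinical PET scanner at the
#' center of the field of view), and noise SD equal to 5% of the mean
#' within-brain intensity.
#'
#' @param shape integer length-3 grid dimensions (left-right axis first).
#' @param spacing_mm voxel spacing in mm.
#' @param fwhm_mm full width at half maximum of the Gaussian blur, mm.
#' @param noise_sd additive Gaussian noise SD as a fraction of the mean
#'   within-brain intensity of the noise-free volume.
#' @param focus_contrast multiplicative contrast `delta`: focus intensity
#'   is background times `1 + delta`; `delta < 0` plants a hypometabolic
#'   focus, `delta > 0` a hypermetabolic one, `0` none. `|delta| < 1`.
#' @param focus_radius_mm radius of the spherical focus, mm. The default
#'   (14 mm) keeps the lesion-diameter-to-cube-edge ratio of the
#'   desk-scale setup (28 mm vs 48 mm cubes) comparable to clinical
#'   lobar abnormalities against full-size cubes.
#' @param focus_side `"left"` or `"right"`.
#' @param lobulated if `TRUE`, the focus is a union of three overlapping
#'   spheres (irregular-shape stress mode for Dice experiments).
#' @param seed integer RNG seed; identical seeds give bit-identical cases.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(shape = c(48L, 56L, 48L),
                           spacing_mm = c(3, 3, 3),
                           fwhm_mm = 4.4,
                           noise_sd = 0.05,
                           focus_contrast = 0,
                           focus_radius_mm = 14,
                           focus_side = c("left", "right"),
                           lobulated = FALSE,
                           seed = 1L) {
  focus_side <- match.arg(focus_side)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape > 0L),
            abs(focus_contrast) < 1, noise_sd >= 0,
            fwhm_mm >= 0, focus_radius_mm > 0)
  structure(list(shape = shape, spacing_mm = as.numeric(spacing_mm),
                 fwhm_mm = fwhm_mm, noise_sd = noise_sd,
                 focus_contrast = focus_contrast,
                 focus_radius_mm = focus_radius_mm,
                 focus_side = focus_side, lobulated = lobulated,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Voxel-center coordinates (mm) relative to the grid center, per axis.
# Symmetric about the mid-grid mirror plane for even extents.
axis_coords <- function(n, sp) (seq_len(n) - (n + 1) / 2) * sp

#' Generate one synthetic phantom case
#'
#' Builds the mirror-symmetric background, plants the focus (if
#' `focus_contrast != 0`), blurs at `fwhm_mm`, and adds noise. The
#' ground-truth severity class comes from the *analytically* expected
#' asymmetric index: the blur recovers only a fraction `R` (the
#' partial-volume recovery coefficient, the mean of the blurred focus
#' indicator over the focus) of the planted contrast, giving an expected
#' `AI = 2 delta R / (2 + delta R)`, thresholded at 0.15 like the
#' grading rule. Truth is therefore independent of the image-based
#' per-slice AI measurement that [grade_metabolic()] performs.
#'
#' @param cfg a [phantom_config()].
#' @return a `phantom_case`: list with `volume` (a [brain_volume()] of the
#'   noisy image), `clean` (noise-free blurred array), `focus_mask`
#'   (logical array; all-`FALSE` for controls), `roi_left`, `roi_right`
#'   (mirrored temporal ROIs), and `truth` (side, delta, polarity,
#'   severity, `ai_expected`).
#' @export
generate_case <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  d <- cfg$shape
  sp <- cfg$spacing_mm
  cx <- axis_coords(d[1], sp[1])
  cy <- axis_coords(d[2], sp[2])
  cz <- axis_coords(d[3], sp[3])
  semi <- c(0.92, 0.92, 0.90) * c(max(abs(cx)), max(abs(cy)), max(abs(cz)))
  X <- array(cx, d)
  Y <- array(rep(cy, each = d[1]), d)
  Z <- array(rep(cz, each = d[1] * d[2]), d)
  rho <- sqrt((X / semi[1])^2 + (Y / semi[2])^2 + (Z / semi[3])^2)
  brain <- rho <= 1
  # cortical-like shell: moderate interior, bright rim near rho ~ 0.8
  bg <- array(0, d)
  bg[brain] <- 100 * (0.55 + 0.45 * exp(-((rho[brain] - 0.80) / 0.18)^2))

  # mirrored temporal ROIs: lateral-inferior ellipsoids
  roi_center <- c(0.58 * semi[1], -0.12 * semi[2], -0.38 * semi[3])
  roi_semi <- c(17, 21, 17)
  roi_left <- ((X + roi_center[1]) / roi_semi[1])^2 +
    ((Y - roi_center[2]) / roi_semi[2])^2 +
    ((Z - roi_center[3]) / roi_semi[3])^2 <= 1 & rho <= 0.98
  roi_right <- flip_lr(roi_left)

  focus <- array(FALSE, d)
  delta <- cfg$focus_contrast
  if (delta != 0) {
    roi <- if (cfg$focus_side == "left") roi_left else roi_right
    focus <- with_seed(cfg$seed + 1L, place_focus(roi, X, Y, Z,
                                                  cfg$focus_radius_mm,
                                                  cfg$lobulated))
  }
  # blur background and lesion increment separately: the background blur
  # is re-symmetrized to cancel float rounding, so a delta = 0 phantom is
  # *exactly* mirror-symmetric; by linearity the sum equals blurring the
  # lesioned image directly.
  bgb <- gauss_blur3(bg, cfg$fwhm_mm, sp)
  bgb <- (bgb + flip_lr(bgb)) / 2
  clean <- bgb
  if (delta != 0) {
    inc <- array(0, d)
    inc[focus] <- bg[focus] * delta
    clean <- clean + gauss_blur3(inc, cfg$fwhm_mm, sp)
  }
  noisy <- clean
  if (cfg$noise_sd > 0) {
    s <- cfg$noise_sd * mean(clean[brain])
    noisy <- clean + with_seed(cfg$seed + 2L, array(rnorm(length(clean), 0, s), d))
  }
  # severity ground truth from the analytically expected AI: the blur
  # recovers only a fraction R of the planted contrast inside the focus
  # (partial-volume effect), so the expected asymmetry of the focus is
  # AI = 2 * delta*R / (2 + delta*R). Thresholded at 0.15 like the
  # grading rule, this defines truth independently of the image-based
  # per-slice AI measurement.
  truth <- list(side = if (delta != 0) cfg$focus_side else NA_character_,
                delta = delta, polarity = NA_character_,
                severity = NA_character_, ai_expected = NA_real_)
  if (delta != 0) {
    ind <- array(0, d)
    ind[focus] <- 1
    R <- mean(gauss_blur3(ind, cfg$fwhm_mm, sp)[focus])
    de <- delta * R
    truth$ai_expected <- 2 * de / (2 + de)
    truth$polarity <- if (delta < 0) "hypo" else "hyper"
    truth$severity <- if (abs(truth$ai_expected) > 0.15) "severe" else "mild"
  }
  structure(list(volume = brain_volume(noisy, spacing = sp, mask = brain),
                 clean = clean, focus_mask = focus,
                 roi_left = roi_left, roi_right = roi_right,
                 truth = truth, config = cfg),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  t <- x$truth
  if (is.na(t$side)) {
    cat("<phantom_case> control (no focus)\n")
  } else {
    cat(sprintf("<phantom_case> %s %s focus, delta = %+0.2f, expected AI = %+0.3f\n",
                t$severity, t$side, t$delta, t$ai_expected))
  }
  invisible(x)
}

# Choose a seeded focus placement wholly inside `roi`; error if impossible.
place_focus <- function(roi, X, Y, Z, radius_mm, lobulated) {
  sphere_at <- function(c0, r) {
    (X - c0[1])^2 + (Y - c0[2])^2 + (Z - c0[3])^2 <= r^2
  }
  make_focus <- function(c0) {
    if (!lobulated) return(sphere_at(c0, radius_mm))
    r <- radius_mm * 0.75
    off <- radius_mm * 0.45
    u <- matrix(rnorm(9), 3)
    u <- sweep(u, 2, sqrt(colSums(u^2)), "/")
    sphere_at(c0, r) | sphere_at(c0 + off * u[, 1], r) |
      sphere_at(c0 + off * u[, 2], r)
  }
  cand <- which(roi)
  if (length(cand) == 0L) stop("focus ROI is empty")
  ord <- sample(cand, min(length(cand), 60L))
  for (i in ord) {
    c0 <- c(X[i], Y[i], Z[i])
    f <- make_focus(c0)
    if (any(f) && all(roi[f])) return(f)
  }
  # fall back to the ROI centroid
  c0 <- c(mean(X[cand]), mean(Y[cand]), mean(Z[cand]))
  f <- make_focus(c0)
  if (!any(f) || !all(roi[f])) {
    stop("focus (radius ", radius_mm, " mm) does not fit inside the ROI")
  }
  f
}

# Separable Gaussian blur with zero-padded boundaries (symmetric kernel,
# so exact mirror symmetry of symmetric inputs is preserved).
gauss_blur3 <- function(a, fwhm_mm, spacing_mm) {
  if (fwhm_mm <= 0) return(a)
  d <- dim(a)
  for (ax in 1:3) {
    sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / spacing_mm[ax]
    r <- ceiling(3 * sigma)
    if (r < 1) next
    k <- exp(-((-r:r)^2) / (2 * sigma^2))
    k <- k / sum(k)
    a <- convolve_axis(a, k, ax)
  }
  a
}

# 1D convolution of a 3D array along axis `ax` (zero padding).
convolve_axis <- function(a, k, ax) {
  d <- dim(a)
  perm <- c(ax, setdiff(1:3, ax))
  m <- matrix(aperm(a, perm), nrow = d[ax])
  r <- (length(k) - 1L) %/% 2L
  n <- d[ax]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) {
    off <- j - r - 1L
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    out[ok, ] <- out[ok, ] + k[j] * m[src[ok], ]
  }
  aperm(array(out, d[perm]), order(perm))
}

#' Generate a synthetic cohort
#'
#' Patients receive a unilateral focus with contrast magnitude drawn
#' uniformly from `contrast_range` and sign chosen hypometabolic with
#' probability `hypo_frac` (hypometabolism dominates in temporal lobe
#' epilepsy); controls have no focus. Per-case seeds are derived
#' deterministically from `seed`.
#'
#' @param n_patients,n_controls non-negative case counts.
#' @param contrast_range length-2 positive range of `|delta|`.
#' @param seed cohort seed.
#' @param hypo_frac probability that a patient's focus is hypometabolic.
#' @param ... further arguments passed to [phantom_config()] (e.g.
#'   `shape`, `noise_sd`).
#' @return list of `phantom_case` objects with a `label` element
#'   (`"patient"`/`"control"`) attached to each.
#' @export
generate_cohort <- function(n_patients, n_controls,
                            contrast_range = c(0.15, 0.45),
                            seed = 1L, hypo_frac = 0.8, ...) {
  stopifnot(n_patients >= 0, n_controls >= 0)
  n <- n_patients + n_controls
  if (n == 0L) return(list())
  seeds <- derive_seeds(seed, n)
  draws <- with_seed(seed, list(
    mag = runif(n, contrast_range[1], contrast_range[2]),
    hypo = runif(n) < hypo_frac,
    side = sample(c("left", "right"), n, replace = TRUE)))
  lapply(seq_len(n), function(i) {
    patient <- i <= n_patients
    delta <- if (patient) draws$mag[i] * (if (draws$hypo[i]) -1 else 1) else 0
    cfg <- phantom_config(focus_contrast = delta,
                          focus_side = draws$side[i],
                          seed = seeds[i], ...)
    case <- generate_case(cfg)
    case$label <- if (patient) "patient" else "control"
    case
  })
}
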
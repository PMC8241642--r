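# Cube origin grid along one axis: stride steps, final cube edge-aligned.
cube_origins <- function(extent, n, stride) {
  if (n > extent) stop("volume smaller than the cube size")
  o <- seq.int(1L, extent - n + 1L, by = stride)
  last <- extent - n + 1L
  if (tail(o, 1L) != last) o <- c(o, last)
  o
}

#' Partition a Z-map into pairs-of-cubes (PoCs)
#'
#' Cubes of `n^3` voxels tile each hemisphere half-grid on a stride grid
#' (the final cube per axis is edge-aligned); each cube is paired with
#' the congruent cube at the mirrored contralateral location. Cubes whose
#' footprint covers less than `min_coverage` of the brain mask are
#' dropped. Both hemispheres are enumerated, so a PoC exists with
#' `cube_a` on either side (`side` records which).
#'
#' @param zmap a [to_zmap()] result (or `brain_volume`).
#' @param n cube edge length in voxels (48 at clinical resolution; the
#'   tiny desk-scale presets use 16).
#' @param stride origin step in voxels; overlapping cubes (`stride =
#'   n/2`) smooth the downstream heat map. Default `n %/% 2`.
#' @param min_coverage minimum brain-mask fraction of the cube footprint.
#' @return list of `poc` objects: `cube_a`, `cube_b` (mirrored
#'   contralateral cube), `origin` (half-grid voxel index), `side`,
#'   `label` (`NA` until [label_pocs()]).
#' @export
partition_pocs <- function(zmap, n = 48L, stride = max(1L, n %/% 2L),
                           min_coverage = 0.05) {
  stopifnot(inherits(zmap, "brain_volume"), stride >= 1L)
  halves <- split_mirror(zmap$data)
  mhalves <- split_mirror(zmap$mask)
  hd <- dim(halves$left)
  if (any(n > hd)) stop("volume smaller than the cube size")
  og <- expand.grid(x = cube_origins(hd[1], n, stride),
                    y = cube_origins(hd[2], n, stride),
                    z = cube_origins(hd[3], n, stride))
  out <- list()
  for (side in c("left", "right")) {
    a <- if (side == "left") halves$left else halves$right
    b <- if (side == "left") halves$right else halves$left
    ma <- if (side == "left") mhalves$left else mhalves$right
    for (r in seq_len(nrow(og))) {
      ix <- og$x[r] + seq_len(n) - 1L
      iy <- og$y[r] + seq_len(n) - 1L
      iz <- og$z[r] + seq_len(n) - 1L
      if (mean(ma[ix, iy, iz]) < min_coverage) next
      out[[length(out) + 1L]] <- structure(
        list(cube_a = a[ix, iy, iz], cube_b = b[ix, iy, iz],
             origin = c(og$x[r], og$y[r], og$z[r]), side = side,
             label = NA_real_, subject = NA_character_),
        class = "poc")
    }
  }
  out
}

#' Label PoCs from a focus mask
#'
#' A PoC is abnormal (`label = 1.0`) iff the focus voxels inside the
#' footprint of `cube_a` *or* of its mirrored counterpart reach
#' `min_frac * n^3` (boundary inclusive); otherwise normal (`0.0`).
#' Labelling is monotone in the mask: enlarging the focus never turns a
#' positive PoC negative.
#'
#' @param pocs list of `poc` from [partition_pocs()].
#' @param focus_mask logical array congruent with the source volume.
#' @param min_frac focus volume fraction threshold (default 0.005: a
#'   cube is large relative to a small focus).
#' @return the list with `label` filled in.
#' @export
label_pocs <- function(pocs, focus_mask, min_frac = 0.005) {
  stopifnot(length(dim(focus_mask)) == 3L)
  fh <- split_mirror(array(as.logical(focus_mask), dim(focus_mask)))
  lapply(pocs, function(p) {
    n <- dim(p$cube_a)[1]
    a <- if (p$side == "left") fh$left else fh$right
    b <- if (p$side == "left") fh$right else fh$left
    ix <- p$origin[1] + seq_len(n) - 1L
    iy <- p$origin[2] + seq_len(n) - 1L
    iz <- p$origin[3] + seq_len(n) - 1L
    thr <- min_frac * n^3
    p$label <- as.numeric(sum(a[ix, iy, iz]) >= thr ||
                            sum(b[ix, iy, iz]) >= thr)
    p
  })
}

#' Augment a PoC
#'
#' Randomly composes label-preserving transforms applied *identically* to
#' both cubes: axis flips, a smooth radial coordinate distortion
#' `r -> r * (1 + alpha * r^2)` (grid-normalized radius, trilinear
#' resampling with border clamping), and a global intensity scale and
#' shift. Because both cubes receive the same transform, the pair's
#' symmetry structure (and hence its label) is preserved.
#'
#' @param poc a labeled `poc`.
#' @param flip_prob per-axis flip probability.
#' @param alpha_max maximum |alpha| of the radial distortion.
#' @param scale_range,shift_range intensity modification ranges.
#' @return an augmented `poc` (label unchanged).
#' @export
augment_poc <- function(poc, flip_prob = 0.5, alpha_max = 0.05,
                        scale_range = c(0.9, 1.1),
                        shift_range = c(-0.05, 0.05)) {
  flips <- runif(3) < flip_prob
  alpha <- runif(1, -alpha_max, alpha_max)
  scale <- runif(1, scale_range[1], scale_range[2])
  shift <- runif(1, shift_range[1], shift_range[2])
  tf <- function(cube) {
    for (ax in which(flips)) {
      idx <- rep(list(quote(expr = )), 3)
      idx[[ax]] <- seq.int(dim(cube)[ax], 1L)
      cube <- do.call(`[`, c(list(cube), idx, list(drop = FALSE)))
    }
    if (alpha != 0) cube <- radial_warp(cube, alpha)
    cube * scale + shift
  }
  poc$cube_a <- tf(poc$cube_a)
  poc$cube_b <- tf(poc$cube_b)
  poc
}

# Radial polynomial warp r -> r (1 + alpha r^2) in grid-normalized
# coordinates about the cube center; trilinear sampling, border clamp.
radial_warp <- function(cube, alpha) {
  d <- dim(cube)
  ctr <- (d + 1) / 2
  hw <- pmax((d - 1) / 2, 1)
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  u <- cbind((g$x - ctr[1]) / hw[1], (g$y - ctr[2]) / hw[2],
             (g$z - ctr[3]) / hw[3])
  r2 <- rowSums(u^2)
  src <- u * (1 + alpha * r2)
  sx <- pmin(pmax(src[, 1] * hw[1] + ctr[1], 1), d[1])
  sy <- pmin(pmax(src[, 2] * hw[2] + ctr[2], 1), d[2])
  sz <- pmin(pmax(src[, 3] * hw[3] + ctr[3], 1), d[3])
  array(trilinear(cube, sx, sy, sz), d)
}

# Trilinear interpolation of a 3D array at (possibly fractional) voxel
# coordinates (1-based, assumed within bounds).
trilinear <- function(a, x, y, z) {
  d <- dim(a)
  x0 <- pmin(floor(x), d[1] - 1L); y0 <- pmin(floor(y), d[2] - 1L)
  z0 <- pmin(floor(z), d[3] - 1L)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  at <- function(i, j, k) a[cbind(i, j, k)]
  v000 <- at(x0, y0, z0);     v100 <- at(x0 + 1, y0, z0)
  v010 <- at(x0, y0 + 1, z0); v110 <- at(x0 + 1, y0 + 1, z0)
  v001 <- at(x0, y0, z0 + 1); v101 <- at(x0 + 1, y0, z0 + 1)
  v011 <- at(x0, y0 + 1, z0 + 1); v111 <- at(x0 + 1, y0 + 1, z0 + 1)
  (v000 * (1 - fx) + v100 * fx) * (1 - fy) * (1 - fz) +
    (v010 * (1 - fx) + v110 * fx) * fy * (1 - fz) +
    (v001 * (1 - fx) + v101 * fx) * (1 - fy) * fz +
    (v011 * (1 - fx) + v111 * fx) * fy * fz
}

#' Inverse-class-frequency sample weights
#'
#' Weight proportional to `1 / class frequency`, normalized so the total
#' weight equals the sample count; the weighted mass of the minority
#' class then equals that of the majority class.
#'
#' @param labels numeric 0/1 labels (both classes present).
#' @return positive numeric weights, same length.
#' @export
sample_weights <- function(labels) {
  labels <- as.numeric(labels)
  n <- length(labels)
  n1 <- sum(labels == 1)
  n0 <- n - n1
  if (n0 == 0L || n1 == 0L) stop("both classes must be present")
  w <- ifelse(labels == 1, n / (2 * n1), n / (2 * n0))
  w
}

#' Build a subject-wise split PoC dataset from a phantom cohort
#'
#' Z-maps each case, partitions and labels PoCs, tags each PoC with its
#' subject, and assigns whole subjects to train/validation/test splits in
#' the given proportions (stratified by patient/control, seeded).
#' Subject-disjoint splitting avoids leakage of a subject's cubes across
#' splits. Optionally adds augmented copies of positive training PoCs to
#' soften class imbalance (weighting handles the rest).
#'
#' @param cohort list of `phantom_case` from [generate_cohort()].
#' @param n,stride cube size and stride for [partition_pocs()].
#' @param split train/val/test proportions (sums to 1).
#' @param seed RNG seed for split assignment and augmentation.
#' @param augment_positives integer: number of augmented copies of each
#'   positive training PoC to add (0 = none).
#' @param min_frac label threshold for [label_pocs()].
#' @return a `poc_dataset`: list with `pocs`, per-PoC `split`
#'   (`"train"/"val"/"test"`), `labels`, `subjects`, and `weights`
#'   (inverse-frequency weights over the training split).
#' @export
poc_dataset <- function(cohort, n = 16L, stride = max(1L, n %/% 2L),
                        split = c(train = 0.6, val = 0.2, test = 0.2),
                        seed = 1L, augment_positives = 0L,
                        min_frac = 0.005) {
  stopifnot(length(cohort) >= 2L, abs(sum(split) - 1) < 1e-8)
  subj_label <- vapply(cohort, function(cs) {
    if (any(cs$focus_mask)) "patient" else "control"
  }, character(1))
  split_of <- with_seed(seed, {
    out <- character(length(cohort))
    for (cls in unique(subj_label)) {
      idx <- sample(which(subj_label == cls))
      ns <- length(idx)
      n_tr <- round(split[1] * ns)
      n_va <- max(1L, round(split[2] * ns))
      n_tr <- max(1L, min(n_tr, ns - n_va))
      tags <- rep("test", ns)
      tags[seq_len(n_tr)] <- "train"
      if (n_tr + n_va <= ns) tags[n_tr + seq_len(n_va)] <- "val"
      out[idx] <- tags
      out
    }
    out
  })
  pocs <- list()
  splits <- character(0)
  for (i in seq_along(cohort)) {
    cs <- cohort[[i]]
    zm <- to_zmap(cs$volume)
    pp <- partition_pocs(zm, n = n, stride = stride)
    pp <- label_pocs(pp, cs$focus_mask, min_frac = min_frac)
    pp <- lapply(pp, function(p) {
      p$subject <- paste0("S", i)
      p
    })
    pocs <- c(pocs, pp)
    splits <- c(splits, rep(split_of[i], length(pp)))
  }
  labels <- vapply(pocs, `[[`, numeric(1), "label")
  if (augment_positives > 0L) {
    aug_seeds <- derive_seeds(seed + 1L, sum(labels == 1 & splits == "train") *
                                augment_positives + 1L)
    k <- 0L
    for (j in which(labels == 1 & splits == "train")) {
      for (r in seq_len(augment_positives)) {
        k <- k + 1L
        pocs[[length(pocs) + 1L]] <- with_seed(aug_seeds[k],
                                               augment_poc(pocs[[j]]))
        splits <- c(splits, "train")
        labels <- c(labels, 1)
      }
    }
  }
  tr <- splits == "train"
  weights <- rep(NA_real_, length(pocs))
  if (length(unique(labels[tr])) == 2L) {
    weights[tr] <- sample_weights(labels[tr])
  } else {
    weights[tr] <- 1
  }
  structure(list(pocs = pocs, split = splits, labels = labels,
                 subjects = vapply(pocs, `[[`, character(1), "subject"),
                 weights = weights, n = n, stride = stride, seed = seed),
            class = "poc_dataset")
}

#' @export
print.poc_dataset <- function(x, ...) {
  tab <- table(split = x$split, label = x$labels)
  cat(sprintf("<poc_dataset> %d PoCs (%d^3), stride %d\n",
              length(x$pocs), x$n, x$stride))
  print(tab)
  invisible(x)
}
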
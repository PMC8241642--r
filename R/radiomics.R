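#' Quantize a masked ROI into G gray levels
#'
#' Equal-width binning between the in-ROI minimum and maximum, half-open
#' bins with the top bin inclusive of the maximum. A constant ROI maps
#' entirely to level 1.
#'
#' @param data 3D numeric array.
#' @param mask logical array of the same shape (nonempty).
#' @param G number of gray levels (>= 2; default 32, a common radiomics
#'   discretization).
#' @return a `quantized_roi`: list with `labels` (integer array, 0 outside
#'   the ROI, 1..G inside) and `G`.
#' @export
quantize_roi <- function(data, mask, G = 32L) {
  stopifnot(length(dim(data)) == 3L, G >= 2L)
  mask <- array(as.logical(mask), dim(data))
  if (!any(mask)) stop("ROI is empty")
  v <- data[mask]
  lab <- array(0L, dim(data))
  rng <- range(v)
  if (rng[2] <= rng[1]) {
    lab[mask] <- 1L
  } else {
    width <- (rng[2] - rng[1]) / G
    lab[mask] <- pmin(G, as.integer(floor((v - rng[1]) / width)) + 1L)
  }
  structure(list(labels = lab, G = as.integer(G)), class = "quantized_roi")
}

#' First-order intensity features
#'
#' Returns mean, variance, skewness, kurtosis, energy and entropy of the
#' ROI intensities. Moment conventions: population (divide-by-n) variance;
#' skewness `m3 / sigma^3` and *excess* kurtosis `m4 / sigma^4 - 3`
#' (both defined as 0 for a constant ROI); energy is the sum of squared
#' intensities; entropy is the natural-log Shannon entropy of the
#' `G`-bin equal-width histogram.
#'
#' @param values numeric vector of ROI intensities (length >= 2).
#' @param G histogram bins for the entropy feature.
#' @return named numeric length 6.
#' @export
intensity_features <- function(values, G = 32L) {
  n <- length(values)
  if (n < 2L) stop("ROI must contain at least 2 voxels")
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  sigma <- sqrt(m2)
  skew <- if (sigma > 0) mean((values - mu)^3) / sigma^3 else 0
  kurt <- if (sigma > 0) mean((values - mu)^4) / sigma^4 - 3 else 0
  c(mean = mu, variance = m2, skewness = skew, kurtosis = kurt,
    energy = sum(values^2), entropy = hist_entropy(values, G))
}

# Natural-log entropy of the G-bin equal-width histogram.
hist_entropy <- function(values, G = 32L) {
  p <- hist_probs(values, G)
  p <- p[p > 0]
  -sum(p * log(p))
}

hist_probs <- function(values, G = 32L) {
  rng <- range(values)
  if (rng[2] <= rng[1]) return(1)
  width <- (rng[2] - rng[1]) / G
  idx <- pmin(G, floor((values - rng[1]) / width) + 1)
  tabulate(idx, G) / length(values)
}

#' Histogram (robust first-order) features
#'
#' Ten distribution-shape features: the 10th/25th/50th/75th/90th
#' percentiles, interquartile range, range, median absolute deviation
#' (unscaled), mean absolute deviation, and histogram uniformity
#' (sum of squared `G`-bin probabilities).
#'
#' @inheritParams intensity_features
#' @return named numeric length 10.
#' @export
histogram_features <- function(values, G = 32L) {
  q <- quantile(values, c(0.10, 0.25, 0.50, 0.75, 0.90),
                names = FALSE, type = 7)
  p <- hist_probs(values, G)
  c(p10 = q[1], p25 = q[2], p50 = q[3], p75 = q[4], p90 = q[5],
    iqr = q[4] - q[2], range = diff(range(values)),
    mad_median = median(abs(values - q[3])),
    mad_mean = mean(abs(values - mean(values))),
    uniformity = sum(p^2))
}

# The 13 unique 3D direction offsets at Chebyshev distance 1.
glcm_offsets <- function() {
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  # keep one of each +/- pair: lexicographically positive
  keep <- offs$dz > 0 | (offs$dz == 0 & offs$dy > 0) |
    (offs$dz == 0 & offs$dy == 0 & offs$dx > 0)
  as.matrix(offs[keep, ])
}

# Pairs of co-occurring labels for one offset (both voxels in ROI).
shift_pairs <- function(lab, off) {
  d <- dim(lab)
  sx <- seq_len(d[1] - abs(off[1])); tx <- sx + abs(off[1])
  if (off[1] < 0) { tmp <- sx; sx <- tx; tx <- tmp }
  sy <- seq_len(d[2] - abs(off[2])); ty <- sy + abs(off[2])
  if (off[2] < 0) { tmp <- sy; sy <- ty; ty <- tmp }
  sz <- seq_len(d[3] - abs(off[3])); tz <- sz + abs(off[3])
  if (off[3] < 0) { tmp <- sz; sz <- tz; tz <- tmp }
  a <- lab[sx, sy, sz]
  b <- lab[tx, ty, tz]
  ok <- a > 0L & b > 0L
  cbind(a[ok], b[ok])
}

# Symmetric normalized GLCM over the 13 unique directions at distance 1.
glcm_matrix <- function(q) {
  G <- q$G
  counts <- matrix(0, G, G)
  for (i in seq_len(nrow(glcm_offsets()))) {
    pr <- shift_pairs(q$labels, glcm_offsets()[i, ])
    if (nrow(pr) == 0L) next
    t1 <- tabulate((pr[, 2] - 1L) * G + pr[, 1], G * G)
    counts <- counts + matrix(t1, G, G)
  }
  counts <- counts + t(counts)  # symmetric accumulation (both directions)
  s <- sum(counts)
  if (s == 0) stop("ROI has no voxel pairs (single voxel?)")
  counts / s
}

#' Gray-level co-occurrence matrix (GLCM) features
#'
#' Co-occurrences are accumulated symmetrically over all 13 unique 3D
#' direction offsets at distance 1 into a single normalized matrix
#' (direction-symmetric accumulation makes every statistic invariant to
#' mirroring of the ROI). Ten statistics are returned: contrast,
#' correlation, energy (angular second moment), homogeneity (inverse
#' difference moment), entropy (natural log), gray-level variance,
#' dissimilarity, cluster shade, cluster prominence and maximum
#' probability. A constant ROI has correlation defined as 1.
#'
#' @param q a [quantize_roi()] result.
#' @return named numeric length 10.
#' @export
glcm_features <- function(q) {
  P <- glcm_matrix(q)
  G <- nrow(P)
  i <- matrix(seq_len(G), G, G)
  j <- t(i)
  pi_m <- rowSums(P)
  mu <- sum(seq_len(G) * pi_m)
  varg <- sum((seq_len(G) - mu)^2 * pi_m)
  pr <- P[P > 0]
  corr <- if (varg > 0) sum((i - mu) * (j - mu) * P) / varg else 1
  c(contrast = sum((i - j)^2 * P),
    correlation = corr,
    energy = sum(P^2),
    homogeneity = sum(P / (1 + (i - j)^2)),
    entropy = -sum(pr * log(pr)),
    variance = varg,
    dissimilarity = sum(abs(i - j) * P),
    cluster_shade = sum((i + j - 2 * mu)^3 * P),
    cluster_prominence = sum((i + j - 2 * mu)^4 * P),
    max_prob = max(P))
}

# 26-neighborhood sums of values and counts of in-ROI neighbours.
neighbor_stats <- function(lab) {
  d <- dim(lab)
  inroi <- lab > 0L
  vals <- array(0, d)
  vals[inroi] <- lab[inroi]
  nsum <- array(0, d)
  ncnt <- array(0L, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    sx <- seq_len(d[1] - abs(dx)); tx <- sx + abs(dx)
    if (dx < 0) { tmp <- sx; sx <- tx; tx <- tmp }
    sy <- seq_len(d[2] - abs(dy)); ty <- sy + abs(dy)
    if (dy < 0) { tmp <- sy; sy <- ty; ty <- tmp }
    sz <- seq_len(d[3] - abs(dz)); tz <- sz + abs(dz)
    if (dz < 0) { tmp <- sz; sz <- tz; tz <- tmp }
    nsum[tx, ty, tz] <- nsum[tx, ty, tz] + vals[sx, sy, sz]
    ncnt[tx, ty, tz] <- ncnt[tx, ty, tz] + inroi[sx, sy, sz]
  }
  list(nsum = nsum, ncnt = ncnt)
}

#' Neighborhood gray-tone difference matrix (NGTDM) features
#'
#' Amadasun-King coarseness, contrast, busyness, complexity and strength
#' with a 26-neighborhood. The neighborhood average uses the available
#' in-ROI neighbors; voxels with no in-ROI neighbor are excluded.
#'
#' @param q a [quantize_roi()] result.
#' @return named numeric length 5.
#' @export
ngtdm_features <- function(q) {
  ns <- neighbor_stats(q$labels)
  ok <- q$labels > 0L & ns$ncnt > 0L
  if (!any(ok)) stop("ROI has no voxels with in-ROI neighbors")
  lv <- q$labels[ok]
  A <- ns$nsum[ok] / ns$ncnt[ok]
  G <- q$G
  N <- length(lv)
  n_i <- tabulate(lv, G)
  p_i <- n_i / N
  s_i <- vapply(seq_len(G), function(g) sum(abs(g - A[lv == g])), numeric(1))
  act <- which(p_i > 0)
  Ng <- length(act)
  coarseness <- if (sum(p_i * s_i) > 0) 1 / sum(p_i * s_i) else 1e6
  contrast <- 0
  if (Ng > 1) {
    pij <- outer(p_i[act], p_i[act])
    dij2 <- outer(act, act, function(a, b) (a - b)^2)
    contrast <- sum(pij * dij2) / (Ng * (Ng - 1)) * sum(s_i) / N
  }
  busy_den <- sum(abs(outer(act * p_i[act], act * p_i[act], "-")))
  busyness <- if (busy_den > 0) sum(p_i * s_i) / busy_den else 0
  complexity <- 0
  strength <- 0
  if (Ng > 1) {
    pa <- p_i[act]; sa <- s_i[act]
    psum <- outer(pa, pa, "+")
    dabs <- abs(outer(act, act, "-"))
    complexity <- sum(dabs * (outer(pa * sa, pa * sa, "+")) / psum) / N
    if (sum(s_i) > 0) {
      strength <- sum(psum * dabs^2) / sum(s_i)
    }
  }
  c(coarseness = coarseness, contrast = contrast, busyness = busyness,
    complexity = complexity, strength = strength)
}

# Zone table: 26-connected components of equal gray level within the ROI.
zone_table <- function(q) {
  lv <- integer(0)
  sz <- integer(0)
  for (g in sort(unique(q$labels[q$labels > 0L]))) {
    lab <- .cc3d_label(array(q$labels == g, dim(q$labels)), 26L)
    if (max(lab) == 0L) next
    sizes <- tabulate(lab[lab > 0L])
    lv <- c(lv, rep(g, length(sizes)))
    sz <- c(sz, sizes)
  }
  data.frame(level = lv, size = sz)
}

#' Gray-level zone size matrix (GLZSM) features
#'
#' Zones are 26-connected components of equal gray level. Eleven emphasis
#' statistics are returned: small/large zone emphasis (SZE, LZE),
#' gray-level and zone-size non-uniformity (GLN, ZSN), zone percentage
#' (ZP), low/high gray-level zone emphasis (LGZE, HGZE), and the four
#' joint emphases LZLGE, LZHGE, SZLGE, SZHGE.
#'
#' @param q a [quantize_roi()] result.
#' @return named numeric length 11.
#' @export
glzsm_features <- function(q) {
  zt <- zone_table(q)
  Z <- nrow(zt)
  if (Z == 0L) stop("ROI is empty")
  N <- sum(q$labels > 0L)
  s <- zt$size
  g <- zt$level
  c(SZE = mean(1 / s^2),
    LZE = mean(s^2),
    GLN = sum(tabulate(g)^2) / Z,
    ZSN = sum(tabulate(s)^2) / Z,
    ZP = Z / N,
    LGZE = mean(1 / g^2),
    HGZE = mean(g^2),
    LZLGE = mean(s^2 / g^2),
    LZHGE = mean(s^2 * g^2),
    SZLGE = mean(1 / (s^2 * g^2)),
    SZHGE = mean(g^2 / s^2))
}

#' All 36 texture features of a quantized ROI
#'
#' Concatenates [histogram_features()] (computed on the raw in-mask
#' intensities), [glcm_features()], [ngtdm_features()] and
#' [glzsm_features()].
#'
#' @param data 3D numeric array.
#' @param mask logical array (the ROI).
#' @param G gray levels for quantization.
#' @return named numeric length 36.
#' @export
texture_features <- function(data, mask, G = 32L) {
  q <- quantize_roi(data, mask, G)
  v <- data[array(as.logical(mask), dim(data))]
  out <- c(hist = histogram_features(v, G),
           glcm = glcm_features(q),
           ngtdm = ngtdm_features(q),
           glzsm = glzsm_features(q))
  names(out) <- sub("^(hist|glcm|ngtdm|glzsm)\\.", "\\1.", names(out))
  out
}
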
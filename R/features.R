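#' The frozen 386-entry feature registry
#'
#' Names, in fixed package-wide order, of the 386 features produced by
#' [extract_all()]: 6 first-order intensity features, 36 texture features
#' (10 histogram + 10 GLCM + 5 NGTDM + 11 GLZSM), and 344 multiscale
#' wavelet features (6 intensity + 36 texture + 1 relative subband energy
#' = 43 per Coiflet-1 subband, times 8 subbands `dec1`..`dec8`).
#'
#' @return character vector of length 386 with attribute `blocks`, an
#'   integer vector giving the block sizes
#'   `c(intensity = 6, texture = 36, wavelet = 344)`.
#' @export
feature_registry <- function() {
  int6 <- c("mean", "variance", "skewness", "kurtosis", "energy", "entropy")
  hist10 <- c("p10", "p25", "p50", "p75", "p90", "iqr", "range",
              "mad_median", "mad_mean", "uniformity")
  glcm10 <- c("contrast", "correlation", "energy", "homogeneity", "entropy",
              "variance", "dissimilarity", "cluster_shade",
              "cluster_prominence", "max_prob")
  ngtdm5 <- c("coarseness", "contrast", "busyness", "complexity", "strength")
  glzsm11 <- c("SZE", "LZE", "GLN", "ZSN", "ZP", "LGZE", "HGZE",
               "LZLGE", "LZHGE", "SZLGE", "SZHGE")
  tex36 <- c(paste0("hist.", hist10), paste0("glcm.", glcm10),
             paste0("ngtdm.", ngtdm5), paste0("glzsm.", glzsm11))
  wav <- unlist(lapply(1:8, function(s) {
    paste0("wav.dec", s, ".",
           c(paste0("int.", int6), tex36, "relative_energy"))
  }))
  out <- c(paste0("int.", int6), tex36, wav)
  attr(out, "blocks") <- c(intensity = 6L, texture = 36L, wavelet = 344L)
  out
}

# Bounding box (list of index ranges) of a logical array.
bounding_box <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  lapply(1:3, function(ax) seq.int(min(idx[, ax]), max(idx[, ax])))
}

# Canonicalize a (data, mask) block along the left-right (first) axis:
# flip iff the flipped block is lexicographically smaller. Mirrored ROI
# contents therefore map to one canonical orientation, which makes the
# wavelet block of the feature vector mirror-invariant.
canonical_lr <- function(sub, submask) {
  key <- c(as.numeric(submask), as.numeric(sub))
  subf <- sub[seq.int(dim(sub)[1], 1L), , , drop = FALSE]
  maskf <- submask[seq.int(dim(submask)[1], 1L), , , drop = FALSE]
  keyf <- c(as.numeric(maskf), as.numeric(subf))
  cmp <- keyf - key
  nz <- which(cmp != 0)
  if (length(nz) > 0L && cmp[nz[1]] < 0) {
    list(sub = subf, mask = maskf)
  } else {
    list(sub = sub, mask = submask)
  }
}

# Pad a block (and mask) with zeros at the end of odd axes.
pad_even <- function(sub, submask) {
  d <- dim(sub)
  dn <- d + d %% 2L
  if (all(dn == d)) return(list(sub = sub, mask = submask))
  out <- array(0, dn)
  outm <- array(FALSE, dn)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- sub
  outm[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- submask
  list(sub = out, mask = outm)
}

# 2x downsampled mask: TRUE where any voxel of the 2x2x2 block is TRUE.
coarsen_mask <- function(mask) {
  d <- dim(mask)
  h <- d %/% 2L
  m <- array(mask, c(2L, h[1], 2L, h[2], 2L, h[3]))
  array(apply(m, c(2, 4, 6), any), h)
}

#' The 344 multiscale wavelet features
#'
#' The ROI bounding box is extracted from the volume, non-ROI voxels are
#' zeroed, the block is flipped into a canonical left-right orientation
#' (so mirrored ROIs give identical features) and zero-padded to even
#' extents, then decomposed with a single-level 3D Coiflet-1 DWT
#' ([dwt3_coif1()]). For each of the 8 subbands, the 6 intensity and 36
#' texture features are computed on the coefficients under the
#' 2x-coarsened ROI mask, plus one relative subband energy (subband energy
#' over the summed energy of all 8 subbands), giving 43 x 8 = 344 values.
#'
#' @param data 3D numeric array (e.g. a Z-map).
#' @param mask logical ROI (bounding box >= 6 voxels per axis).
#' @param G gray levels for subband texture quantization.
#' @return named numeric length 344.
#' @export
wavelet_features <- function(data, mask, G = 32L) {
  mask <- array(as.logical(mask), dim(data))
  if (!any(mask)) stop("ROI is empty")
  bb <- bounding_box(mask)
  sub <- data[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
  submask <- mask[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
  if (any(dim(sub) < 6L)) {
    stop("ROI bounding box must be >= 6 voxels per axis for the coif1 filter")
  }
  sub[!submask] <- 0
  cn <- canonical_lr(sub, submask)
  pd <- pad_even(cn$sub, cn$mask)
  bands <- dwt3_coif1(pd$sub)
  cmask <- coarsen_mask(pd$mask)
  energies <- vapply(bands, function(b) sum(b^2), numeric(1))
  etot <- sum(energies)
  out <- numeric(0)
  for (s in 1:8) {
    b <- bands[[s]]
    cv <- b[cmask]
    f <- c(intensity_features(cv, G), texture_features(b, cmask, G),
           relative_energy = if (etot > 0) energies[[s]] / etot else 0)
    out <- c(out, f)
  }
  reg <- feature_registry()
  names(out) <- reg[43:386]
  out
}

#' Extract the full 386-dimensional radiomics feature vector
#'
#' Concatenates, in frozen registry order ([feature_registry()]), the 6
#' intensity features, the 36 texture features and the 344 wavelet
#' features of a masked region of a Z-map. All features are invariant to
#' translation of the ROI and to left-right mirroring, which makes the
#' left and right hemisphere vectors directly comparable.
#'
#' @param zmap a [to_zmap()] result (or any `brain_volume`).
#' @param roi logical array (within the brain mask).
#' @param G gray levels for texture quantization (default 32).
#' @return named numeric vector of length 386 (class `feature_vector`).
#' @export
extract_all <- function(zmap, roi, G = 32L) {
  data <- if (inherits(zmap, "brain_volume")) zmap$data else zmap
  roi <- array(as.logical(roi), dim(data))
  if (!any(roi)) stop("ROI is empty")
  v <- data[roi]
  out <- c(intensity_features(v, G),
           texture_features(data, roi, G),
           wavelet_features(data, roi, G))
  reg <- feature_registry()
  names(out) <- reg
  stopifnot(length(out) == 386L)
  class(out) <- c("feature_vector", "numeric")
  out
}

#' @export
print.feature_vector <- function(x, ...) {
  cat("<feature_vector> 386 features (6 intensity | 36 texture | 344 wavelet)\n")
  print(utils::head(unclass(x)))
  invisible(x)
}
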
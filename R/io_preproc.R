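#' Construct a brain volume
#'
#' A `brain_volume` bundles a 3D scalar image with its voxel spacing and a
#' binary brain mask. It is the unit every downstream stage of the package
#' consumes. Volumes are assumed to be spatially normalized to a left-right
#' symmetric template: the first voxel axis is the left-right axis, and the
#' mirror plane is the mid-grid plane.
#'
#' @param data 3D numeric array of intensities (all finite).
#' @param spacing numeric length-3, voxel size in mm per axis.
#' @param mask logical 3D array of the same shape (the brain mask), or
#'   `NULL` to compute one with [compute_brain_mask()].
#' @return An object of class `brain_volume`: a list with elements `data`,
#'   `spacing` and `mask`.
#' @export
brain_volume <- function(data, spacing = c(1, 1, 1), mask = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("expected 3D volume, got ", length(dim(data)), " dimensions")
  }
  nbad <- sum(!is.finite(data))
  if (nbad > 0L) {
    stop("volume contains ", nbad, " non-finite voxels")
  }
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  if (is.null(mask)) {
    mask <- compute_brain_mask(data)
  }
  mask <- array(as.logical(mask), dim(data))
  if (!identical(dim(mask), dim(data))) {
    stop("mask shape does not match data shape")
  }
  if (!any(mask)) stop("brain mask is empty")
  structure(list(data = data, spacing = spacing, mask = mask),
            class = "brain_volume")
}

#' @export
print.brain_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels @ %s mm, %d in brain mask\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, trim = TRUE), collapse = "x"),
              sum(x$mask)))
  invisible(x)
}

#' Default brain mask by intensity thresholding
#'
#' Voxels above 20% of the 99th-percentile intensity, restricted to the
#' largest 26-connected component. Deterministic and atlas-free; intended
#' for template-space PET where background is near zero.
#'
#' @param data 3D numeric array.
#' @param frac threshold as a fraction of the 99th percentile.
#' @return logical array of the same shape.
#' @export
compute_brain_mask <- function(data, frac = 0.2) {
  thr <- frac * quantile(data, 0.99, names = FALSE, type = 7)
  m <- data > thr
  if (!any(m)) return(m)
  largest_component(m, connectivity = 26L)
}

# Largest connected component of a logical 3D array.
largest_component <- function(mask, connectivity = 26L) {
  lab <- .cc3d_label(mask, as.integer(connectivity))
  if (max(lab) <= 1L) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  array(lab == which.max(sizes), dim(mask))
}

#' Read a NIfTI volume
#'
#' Reads a 3D NIfTI image into a [brain_volume()]. The brain mask is read
#' from `mask_path` when given, otherwise computed by thresholding
#' ([compute_brain_mask()]).
#'
#' @param path path to a `.nii`/`.nii.gz` file.
#' @param mask_path optional path to a companion binary mask NIfTI.
#' @return a `brain_volume`.
#' @export
read_volume <- function(path, mask_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stop("expected 3D volume, got ", length(d), " dimensions")
  }
  data <- array(as.numeric(img), d)
  nbad <- sum(!is.finite(data))
  if (nbad > 0L) stop("volume contains ", nbad, " non-finite voxels")
  spacing <- abs(RNifti::pixdim(img))[seq_len(3)]
  mask <- NULL
  if (!is.null(mask_path)) {
    mimg <- RNifti::readNifti(mask_path)
    if (!identical(dim(mimg), d)) stop("mask shape does not match volume")
    mask <- array(as.numeric(mimg) > 0.5, d)
  }
  brain_volume(data, spacing = spacing, mask = mask)
}

#' Write a volume or plain array as NIfTI
#'
#' @param x a `brain_volume`, `zmap`, or 3D array.
#' @param path output `.nii`/`.nii.gz` path.
#' @param spacing voxel spacing (ignored when `x` carries one).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, spacing = c(1, 1, 1)) {
  if (inherits(x, "brain_volume")) {
    spacing <- x$spacing
    x <- x$data
  }
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Standardize a volume to a Z-map
#'
#' Transforms intensities so that cross-subject comparison of uptake is
#' possible without dose/weight calibration. The default standardizes
#' within the brain mask to mean 0 and (population) SD 1; voxels outside
#' the mask are set to 0. An alternative `"arctanh"` method applies
#' Fisher's z (arctanh) to intensities min-max rescaled to (-1, 1) within
#' the mask, then standardizes, for users who read the Z-map transform as
#' a literal Fisher transformation.
#'
#' @param vol a [brain_volume()].
#' @param method `"standardize"` (default) or `"arctanh"`.
#' @return an object of class `zmap` (inherits `brain_volume`).
#' @export
to_zmap <- function(vol, method = c("standardize", "arctanh")) {
  method <- match.arg(method)
  stopifnot(inherits(vol, "brain_volume"))
  v <- vol$data[vol$mask]
  if (method == "arctanh") {
    rng <- range(v)
    if (rng[2] <= rng[1]) stop("degenerate constant image within mask")
    u <- (v - rng[1]) / (rng[2] - rng[1]) * 1.96 - 0.98  # into (-1, 1)
    v <- atanh(u)
  }
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))
  if (sigma == 0) stop("degenerate constant image within mask (zero variance)")
  out <- array(0, dim(vol$data))
  out[vol$mask] <- (v - mu) / sigma
  structure(list(data = out, spacing = vol$spacing, mask = vol$mask),
            class = c("zmap", "brain_volume"))
}

#' Split a volume into hemisphere halves with mirrored alignment
#'
#' Splits along the left-right (first) voxel axis at the mid-grid plane and
#' flips the right half so that homologous voxels share array indices in
#' the two outputs. An odd left-right extent is padded with one zero slab
#' on the right end before splitting.
#'
#' @param x a `brain_volume`/`zmap`, or a 3D array.
#' @return list with elements `left` and `right` (right half mirrored into
#'   left orientation), plus `padded` (logical).
#' @export
split_mirror <- function(x) {
  a <- if (inherits(x, "brain_volume")) x$data else x
  stopifnot(length(dim(a)) == 3L)
  padded <- FALSE
  nx <- dim(a)[1]
  if (nx %% 2L == 1L) {
    a <- pad_lr(a)
    nx <- nx + 1L
    padded <- TRUE
  }
  half <- nx %/% 2L
  left <- a[seq_len(half), , , drop = FALSE]
  right <- a[seq.int(nx, half + 1L), , , drop = FALSE]
  list(left = left, right = right, padded = padded)
}

# Pad one zero (or FALSE) slab on the right end of the left-right axis.
pad_lr <- function(a) {
  d <- dim(a)
  out <- array(if (is.logical(a)) FALSE else 0, c(d[1] + 1L, d[2], d[3]))
  out[seq_len(d[1]), , ] <- a
  out
}

#' Flip an array or volume along the left-right axis
#'
#' @param x 3D array or `brain_volume`.
#' @return same type as `x`, mirrored about the mid-grid plane.
#' @export
flip_lr <- function(x) {
  if (inherits(x, "brain_volume")) {
    x$data <- flip_lr(x$data)
    x$mask <- flip_lr(x$mask)
    return(x)
  }
  x[seq.int(dim(x)[1], 1L), , , drop = FALSE]
}
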
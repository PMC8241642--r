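#' Standardized uptake value ratio (SUVR)
#'
#' Mean intensity within `roi` divided by the mean within a reference
#' region (default: the whole brain mask). Computed on raw uptake volumes,
#' not Z-maps (a Z-map has zero within-brain mean by construction).
#'
#' @param vol a [brain_volume()].
#' @param roi logical array, same shape as the volume.
#' @param reference optional logical array; defaults to `vol$mask`.
#' @return a single number.
#' @export
suvr <- function(vol, roi, reference = NULL) {
  stopifnot(inherits(vol, "brain_volume"))
  roi <- array(as.logical(roi), dim(vol$data))
  if (!any(roi)) stop("ROI is empty")
  ref <- if (is.null(reference)) vol$mask else array(as.logical(reference), dim(vol$data))
  if (!any(ref)) stop("reference region is empty")
  mref <- mean(vol$data[ref])
  if (mref == 0) stop("reference region mean is zero")
  mean(vol$data[roi]) / mref
}

#' Asymmetric index (AI)
#'
#' The normalized interhemispheric difference
#' `AI = 2 * (SUVR_ipsi - SUVR_contra) / (SUVR_ipsi + SUVR_contra)`.
#' Negative values mean the ipsilateral (focus-side) region takes up less
#' tracer than its mirrored counterpart (hypometabolism); positive values
#' mean hypermetabolism. Bounded in [-2, 2] for nonnegative inputs.
#'
#' @param suvr_ipsi,suvr_contra SUVR of the focus-side region and of its
#'   mirrored contralateral region.
#' @return a single number.
#' @export
asym_index <- function(suvr_ipsi, suvr_contra) {
  s <- suvr_ipsi + suvr_contra
  if (!is.finite(s) || s <= 0) stop("nonpositive SUVR denominator")
  2 * (suvr_ipsi - suvr_contra) / s
}

#' Per-slice asymmetric-index profile over a focus mask
#'
#' For every axial slice (third voxel axis by default) intersecting the
#' mask, the AI is computed between the in-slice mask voxels and their
#' mirrored contralateral voxels (reflection about the mid-grid plane of
#' the left-right axis). Slices not touching the mask are absent from the
#' profile. The SUVR reference is the whole brain mask.
#'
#' @param vol a [brain_volume()] of raw uptake.
#' @param mask logical focus mask (same shape), nonempty. The mask should
#'   be unilateral: a mask equal to its own mirror image yields AI = 0 by
#'   construction (see [lateralize_focus()]).
#' @param axis slice axis (1, 2 or 3; default 3 = axial).
#' @return an `ai_profile` data frame with columns `slice`, `ai`, `n_vox`.
#' @export
ai_profile <- function(vol, mask, axis = 3L) {
  stopifnot(inherits(vol, "brain_volume"))
  d <- dim(vol$data)
  mask <- array(as.logical(mask), d)
  if (!any(mask)) stop("focus mask is empty")
  mref <- mean(vol$data[vol$mask])
  if (mref == 0) stop("reference region mean is zero")
  mirror <- flip_lr(mask)
  slices <- sort(unique(arrayInd(which(mask), d)[, axis]))
  ai <- vapply(slices, function(k) {
    sl_ipsi <- slice_index(d, axis, k) & mask
    sl_contra <- slice_index(d, axis, k) & mirror
    asym_index(mean(vol$data[sl_ipsi]) / mref,
               mean(vol$data[sl_contra]) / mref)
  }, numeric(1))
  structure(data.frame(slice = slices, ai = ai,
                       n_vox = vapply(slices, function(k) {
                         sum(slice_index(d, axis, k) & mask)
                       }, integer(1))),
            class = c("ai_profile", "data.frame"), axis = axis)
}

# Logical array selecting slice k along `axis`.
slice_index <- function(d, axis, k) {
  out <- array(FALSE, d)
  if (axis == 1L) out[k, , ] <- TRUE
  if (axis == 2L) out[, k, ] <- TRUE
  if (axis == 3L) out[, , k] <- TRUE
  out
}

#' Grade a focus into one of four metabolic abnormality levels
#'
#' A focus is `severe` if the absolute AI exceeds `threshold` on at least
#' `consecutive` consecutive slices of the profile, otherwise `mild`
#' (strict `>` at the threshold). Polarity (hypo- vs hypermetabolism) is
#' the sign of the mean AI over the profile; an exactly zero mean falls
#' back to the sign of the largest-|AI| slice (first such slice on ties).
#'
#' @param profile an [ai_profile()].
#' @param threshold absolute-AI threshold (default 0.15).
#' @param consecutive required run length of supra-threshold slices
#'   (default 3).
#' @return a `metabolic_grade` list with elements `severity`
#'   (`"severe"`/`"mild"`), `polarity` (`"hypo"`/`"hyper"`), `level` (one
#'   of the four combined labels) and `runs` (slice runs exceeding the
#'   threshold).
#' @export
grade_metabolic <- function(profile, threshold = 0.15, consecutive = 3L) {
  stopifnot(inherits(profile, "ai_profile"), nrow(profile) >= 1L)
  ai <- profile$ai
  over <- abs(ai) > threshold
  r <- rle(over)
  severe <- any(r$values & r$lengths >= consecutive)
  m <- mean(ai)
  if (m == 0) m <- ai[which.max(abs(ai))]
  polarity <- if (m < 0) "hypo" else "hyper"
  severity <- if (severe) "severe" else "mild"
  runs <- NULL
  if (any(r$values)) {
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    runs <- data.frame(start = profile$slice[starts[keep]],
                       end = profile$slice[ends[keep]],
                       length = r$lengths[keep])
  }
  structure(list(severity = severity, polarity = polarity,
                 level = paste(severity, paste0(polarity, "metabolism")),
                 runs = runs, threshold = threshold,
                 consecutive = as.integer(consecutive)),
            class = "metabolic_grade")
}

#' @export
print.metabolic_grade <- function(x, ...) {
  cat(sprintf("<metabolic_grade> %s (|AI| > %g on >= %d consecutive slices: %s)\n",
              x$level, x$threshold, x$consecutive,
              if (x$severity == "severe") "yes" else "no"))
  invisible(x)
}
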
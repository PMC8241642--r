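# Coiflet-1 analysis filters (orthonormal, 6 taps).
coif1_lo <- c(-0.015655728135791993, -0.07273261951252645,
              0.38486484686485778, 0.85257202021160039,
              0.33789766245748182, -0.07273261951252645)
coif1_hi <- c(0.07273261951252645, 0.33789766245748182,
              -0.85257202021160039, 0.38486484686485778,
              0.07273261951252645, -0.015655728135791993)

# Periodized single-level 1D DWT along axis `ax` of a 3D array with even
# extent. Returns list(lo, hi), each of half extent along `ax`. The
# periodized transform is orthonormal, so energy is conserved exactly.
dwt_axis <- function(a, ax) {
  d <- dim(a)
  n <- d[ax]
  stopifnot(n %% 2L == 0L)
  perm <- c(ax, setdiff(1:3, ax))
  m <- matrix(aperm(a, perm), nrow = n)
  half <- n %/% 2L
  lo <- matrix(0, half, ncol(m))
  hi <- matrix(0, half, ncol(m))
  base <- 2L * (seq_len(half) - 1L)
  for (t in seq_along(coif1_lo)) {
    src <- (base + (t - 1L)) %% n + 1L
    lo <- lo + coif1_lo[t] * m[src, , drop = FALSE]
    hi <- hi + coif1_hi[t] * m[src, , drop = FALSE]
  }
  dn <- d
  dn[ax] <- half
  back <- order(perm)
  list(lo = aperm(array(lo, dn[perm]), back),
       hi = aperm(array(hi, dn[perm]), back))
}

#' Single-level 3D Coiflet-1 wavelet decomposition
#'
#' Separable periodized DWT along all three axes of an even-dimensioned
#' 3D array. Returns the 8 subbands in a fixed order: subband `dec(s)`
#' applies the highpass filter along axis `ax` iff bit `ax` of `s - 1` is
#' set, so `dec1 = LLL` (approximation), `dec2 = HLL`, `dec3 = LHL`,
#' `dec4 = HHL`, `dec5 = LLH`, ..., `dec8 = HHH`. The transform is
#' orthonormal: the summed energy of the 8 subbands equals the energy of
#' the input.
#'
#' @param a 3D numeric array with even extents (each >= 6, the filter
#'   length).
#' @return named list of 8 arrays (`dec1` ... `dec8`), each of half the
#'   input extent per axis.
#' @export
dwt3_coif1 <- function(a) {
  d <- dim(a)
  stopifnot(length(d) == 3L)
  if (any(d %% 2L != 0L)) stop("array extents must be even")
  if (any(d < 6L)) stop("array extents must be >= the filter length (6)")
  s1 <- dwt_axis(a, 1L)
  out <- vector("list", 8L)
  for (bx in 0:1) {
    x <- if (bx == 0) s1$lo else s1$hi
    s2 <- dwt_axis(x, 2L)
    for (by in 0:1) {
      y <- if (by == 0) s2$lo else s2$hi
      s3 <- dwt_axis(y, 3L)
      for (bz in 0:1) {
        out[[1L + bx + 2L * by + 4L * bz]] <- if (bz == 0) s3$lo else s3$hi
      }
    }
  }
  names(out) <- paste0("dec", 1:8)
  out
}
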
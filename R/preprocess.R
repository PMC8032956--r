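#' Slice-timing correction by frequency-domain phase shift
#'
#' Each slice's time courses are resampled to the reference slice's
#' acquisition phase. Slice k in acquisition position q is acquired at
#' `t + q * TR / nz`; its courses are shifted by `delta = (q_ref - q) *
#' TR / nz` via a Fourier phase ramp, after removal (and restoration) of a
#' per-voxel linear trend to limit wrap-around leakage.
#'
#' @param series A [bold_series()].
#' @param slice_order Permutation of `1..nz`: `slice_order[q]` is the slice
#'   acquired q-th. Default ascending sequential.
#' @param ref_slice Reference slice index (default middle slice).
#' @return The corrected [bold_series()].
#' @export
slice_timing_correct <- function(series, slice_order = NULL, ref_slice = NULL) {
  stopifnot(inherits(series, "bold_series"))
  nz <- series$grid$dim[3]
  nt <- series$n_frames
  if (is.null(slice_order)) slice_order <- seq_len(nz)
  if (!identical(sort(as.integer(slice_order)), seq_len(nz)))
    stop("slice_order must be a permutation of 1..", nz)
  if (is.null(ref_slice)) ref_slice <- slice_order[(nz + 1L) %/% 2L]
  if (!ref_slice %in% seq_len(nz)) stop("ref_slice out of range")
  acq_pos <- match(seq_len(nz), slice_order)        # 1-based position in order
  dt_slice <- series$tr_vol / nz
  tvec <- seq_len(nt) - 1
  freqs <- tvec / nt                                 # cycles per frame
  freqs[freqs > 0.5] <- freqs[freqs > 0.5] - 1
  out <- series$data
  for (z in seq_len(nz)) {
    delta <- (acq_pos[ref_slice] - acq_pos[z]) * dt_slice / series$tr_vol
    if (delta == 0) next
    ramp <- exp(2i * pi * freqs * delta)
    if (nt %% 2 == 0) ramp[nt / 2 + 1] <- Re(ramp[nt / 2 + 1])
    sl <- matrix(series$data[, , z, ], ncol = nt)
    # remove a linear trend per voxel, shift, restore it at shifted times
    a <- (sl[, nt] - sl[, 1]) / (nt - 1)
    trend <- outer(a, tvec)
    det <- sl - trend
    shifted <- t(Re(stats::mvfft(stats::mvfft(t(det)) * ramp,
                                 inverse = TRUE))) / nt
    out[, , z, ] <- shifted + trend + a * delta
  }
  bold_series(out, series$grid, series$tr_vol)
}

# 1D Gaussian convolution along one axis of a 4D array (zero-padded,
# normalized kernel; identity when sigma_vox == 0).
gauss_conv_axis <- function(arr, sigma_vox, axis) {
  if (sigma_vox <= 0) return(arr)
  half <- max(1L, ceiling(4 * sigma_vox))
  k <- stats::dnorm(-half:half, sd = sigma_vox)
  k <- k / sum(k)
  d <- dim(arr)
  perm <- c(axis, setdiff(1:4, axis))
  x <- aperm(arr, perm)
  dn <- dim(x)
  m <- matrix(x, nrow = dn[1])
  n <- dn[1]
  out <- matrix(0, n, ncol(m))
  for (o in -half:half) {
    w <- k[o + half + 1]
    src <- (1:n) - o
    ok <- src >= 1 & src <= n
    out[ok, ] <- out[ok, ] + w * m[src[ok], ]
  }
  aperm(array(out, dim = dn), order(perm))
}

#' Spatial Gaussian smoothing
#'
#' Per-frame separable Gaussian convolution with per-axis FWHM in mm;
#' `sigma = FWHM / (2 sqrt(2 ln 2)) / voxel size`, truncated at 4 sigma.
#'
#' @param series A [bold_series()].
#' @param fwhm Length-3 FWHM in mm (default `c(0.36, 0.36, 1.0)`, i.e. one
#'   in-plane voxel at 360 um resolution).
#' @return The smoothed [bold_series()].
#' @export
smooth_series <- function(series, fwhm = c(0.36, 0.36, 1.0)) {
  stopifnot(inherits(series, "bold_series"))
  if (length(fwhm) == 1) fwhm <- rep(fwhm, 3)
  if (any(fwhm < 0)) stop("FWHM must be >= 0")
  sigma_vox <- fwhm / (2 * sqrt(2 * log(2))) / series$grid$voxdim
  out <- series$data
  for (ax in 1:3) out <- gauss_conv_axis(out, sigma_vox[ax], ax)
  bold_series(out, series$grid, series$tr_vol)
}

#' High-pass temporal filtering
#'
#' Removes all fluctuations below the cutoff: each voxel course is
#' orthogonally projected off the span of an intercept, a linear drift and
#' the Fourier sine/cosine pairs at frequencies `k / (T * TR)` below the
#' cutoff, then the temporal mean is re-added. Being a projection, the
#' filter is exactly idempotent.
#'
#' @param series A [bold_series()].
#' @param cutoff Cutoff frequency in Hz, in `(0, Nyquist)`. Default 0.01.
#' @return The filtered [bold_series()].
#' @export
highpass <- function(series, cutoff = 0.01) {
  stopifnot(inherits(series, "bold_series"))
  nt <- series$n_frames
  nyq <- 1 / (2 * series$tr_vol)
  if (cutoff <= 0 || cutoff >= nyq)
    stop("cutoff must lie in (0, Nyquist = ", signif(nyq, 4), ")")
  tvec <- seq_len(nt)
  kmax <- floor(cutoff * nt * series$tr_vol)
  X <- cbind(1, tvec - mean(tvec))
  if (kmax >= 1) {
    for (k in seq_len(kmax)) {
      X <- cbind(X, sin(2 * pi * k * tvec / nt), cos(2 * pi * k * tvec / nt))
    }
  }
  q <- qr.Q(qr(X))
  flat <- matrix(series$data, ncol = nt)
  mu <- rowMeans(flat)
  low <- (flat %*% q) %*% t(q)
  out <- flat - low + mu
  bold_series(array(out, dim = dim(series$data)), series$grid, series$tr_vol)
}
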
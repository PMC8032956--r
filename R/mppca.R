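# Eigen-partition of one patch matrix into signal + Marchenko-Pastur noise.
#
# X: M voxels x N frames, rows already centred. The covariance is formed
# over the smaller dimension C = min(M, N) so that for pure Gaussian noise
# the mean trailing eigenvalue is a consistent estimate of sigma^2. For
# candidate signal rank p (smallest first), sigma2(p) = mean of the C - p
# trailing eigenvalues; p is accepted when the trailing spread fits inside
# the MP support width: lambda_{p+1} - lambda_C <= 4 * sigma2(p) *
# sqrt((C - p) / R), with R = max(M, N) the sample count.
mp_partition <- function(eig, n_rows, n_cols) {
  C <- length(eig)
  R <- max(n_rows, n_cols)
  for (p in 0:(C - 1)) {
    tail_eigs <- eig[(p + 1):C]
    sigma2 <- mean(tail_eigs)
    if (eig[p + 1] - eig[C] <= 4 * sigma2 * sqrt((C - p) / R))
      return(list(rank = p, sigma2 = sigma2))
  }
  list(rank = C - 1L, sigma2 = max(eig[C], 0))
}

# Denoise one patch: rows = voxels, cols = frames. Returns the full
# reconstructed patch plus sigma and retained rank.
mppca_patch <- function(X) {
  M <- nrow(X); N <- ncol(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  if (M <= N) {
    cv <- tcrossprod(Xc) / N                 # M x M voxel covariance
    ev <- eigen(cv, symmetric = TRUE)
    part <- mp_partition(pmax(ev$values, 0), M, N)
    p <- part$rank
    rec <- if (p == 0) matrix(0, M, N) else {
      V <- ev$vectors[, seq_len(p), drop = FALSE]
      V %*% crossprod(V, Xc)
    }
  } else {
    cv <- crossprod(Xc) / M                  # N x N frame covariance
    ev <- eigen(cv, symmetric = TRUE)
    part <- mp_partition(pmax(ev$values, 0), N, M)
    p <- part$rank
    rec <- if (p == 0) matrix(0, M, N) else {
      V <- ev$vectors[, seq_len(p), drop = FALSE]
      (Xc %*% V) %*% t(V)
    }
  }
  list(denoised = rec + mu, sigma = sqrt(max(part$sigma2, 0)),
       rank = part$rank)
}

#' MP-PCA denoising of a 4D BOLD series
#'
#' Sliding-kernel Marchenko-Pastur PCA: around every in-mask voxel a
#' `kernel^3` patch (clipped at volume boundaries and intersected with the
#' mask) forms a voxels x frames matrix whose eigen-spectrum is split into
#' retained signal components and discarded MP-distributed noise; only the
#' centre voxel's reconstructed course is written to the output. The noise
#' level and retained rank are recorded per voxel, and
#' `denoised + residuals == original` exactly.
#'
#' @param series A [bold_series()].
#' @param mask A [brain_mask()] on the same grid.
#' @param kernel Odd kernel width in voxels (default 5).
#' @return An object of class `denoise_result`: `denoised`
#'   ([bold_series()]), `sigma_map`, `rank_map`, `residuals` (4D array),
#'   and `skipped` (count of passthrough voxels with too-small patches).
#' @export
mppca_denoise <- function(series, mask, kernel = 5L) {
  stopifnot(inherits(series, "bold_series"), inherits(mask, "brain_mask"))
  if (!grids_equal(series$grid, mask$grid)) stop("series and mask grids differ")
  kernel <- as.integer(kernel)
  if (kernel %% 2L == 0L || kernel < 3L) stop("kernel must be odd and >= 3")
  d <- series$grid$dim
  nt <- series$n_frames
  flat <- matrix(series$data, ncol = nt)
  mask_arr <- mask$voxels
  out <- flat
  sigma_map <- array(NA_real_, dim = d)
  rank_map <- array(NA_integer_, dim = d)
  half <- kernel %/% 2L
  idx <- which(mask_arr)
  co <- arrayInd(idx, d)
  min_patch <- 2L * kernel
  skipped <- 0L
  for (v in seq_along(idx)) {
    xr <- max(1L, co[v, 1] - half):min(d[1], co[v, 1] + half)
    yr <- max(1L, co[v, 2] - half):min(d[2], co[v, 2] + half)
    zr <- max(1L, co[v, 3] - half):min(d[3], co[v, 3] + half)
    sub <- mask_arr[xr, yr, zr, drop = FALSE]
    if (sum(sub) < min_patch) { skipped <- skipped + 1L; next }
    pij <- arrayInd(which(sub), dim(sub))
    pidx <- (xr[pij[, 1]]) + (yr[pij[, 2]] - 1L) * d[1] +
      (zr[pij[, 3]] - 1L) * d[1] * d[2]
    centre <- which(pidx == idx[v])
    fit <- mppca_patch(flat[pidx, , drop = FALSE])
    out[idx[v], ] <- fit$denoised[centre, ]
    sigma_map[idx[v]] <- fit$sigma
    rank_map[idx[v]] <- fit$rank
  }
  denoised <- bold_series(array(out, dim = c(d, nt)), series$grid,
                          series$tr_vol)
  structure(list(denoised = denoised, sigma_map = sigma_map,
                 rank_map = rank_map,
                 residuals = series$data - denoised$data,
                 skipped = skipped),
            class = "denoise_result")
}

#' Residual-normality QC for MP-PCA denoising
#'
#' Gaussian residuals have a log-density linear in the squared standardized
#' residual: `ln P = c - r^2 / 2`. The standardized in-mask residuals are
#' histogrammed, `ln` of the bin probability density is regressed on the
#' squared bin centre, and the fit's slope and coefficient of determination
#' are reported; the QC passes when R^2 meets the threshold.
#'
#' @param residuals 4D residual array (original - denoised).
#' @param mask A [brain_mask()].
#' @param n_bins Number of histogram bins (default 60).
#' @param r2_threshold Pass threshold on the coefficient of determination.
#' @param min_count Bins with fewer samples are excluded from the fit.
#' @return An object of class `normality_qc`: `r2_centers` (squared bin
#'   centres), `log_p`, `slope`, `intercept`, `r_squared`, `pass`.
#' @export
residual_normality <- function(residuals, mask, n_bins = 60,
                               r2_threshold = 0.98, min_count = 10) {
  stopifnot(inherits(mask, "brain_mask"))
  flat <- matrix(residuals, ncol = dim(residuals)[4])
  r <- as.numeric(flat[which(mask$voxels), ])
  if (length(r) < 1000) stop("need >= 1000 in-mask residual samples")
  s <- stats::sd(r)
  if (s == 0) stop("residuals are degenerate (all equal)")
  r <- (r - mean(r)) / s
  br <- seq(min(r), max(r), length.out = n_bins + 1)
  h <- graphics::hist(r, breaks = br, plot = FALSE)
  keep <- h$counts >= min_count
  x <- h$mids[keep]^2
  y <- log(h$density[keep])
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  structure(list(r2_centers = x, log_p = y,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, pass = r2 >= r2_threshold,
                 n_samples = length(r)),
            class = "normality_qc")
}

#' Temporal signal-to-noise ratio map
#'
#' Voxelwise temporal mean divided by temporal standard deviation.
#' Zero-variance voxels are flagged `NA` (undefined), never silently zeroed.
#'
#' @param series A [bold_series()].
#' @param mask A [brain_mask()].
#' @return An object of class `tsnr_map`: `map` (3D, NA outside the mask
#'   and at undefined voxels), `mean_tsnr` (over defined in-mask voxels),
#'   `n_undefined`.
#' @export
tsnr <- function(series, mask) {
  stopifnot(inherits(series, "bold_series"), inherits(mask, "brain_mask"))
  if (series$n_frames < 2) stop("need >= 2 frames")
  flat <- mask_matrix(series, mask)
  mu <- rowMeans(flat)
  sdv <- apply(flat, 1, stats::sd)
  val <- ifelse(sdv > 0, mu / sdv, NA_real_)
  map <- array(NA_real_, dim = series$grid$dim)
  map[attr(flat, "voxel_index")] <- val
  structure(list(map = map, mean_tsnr = mean(val, na.rm = TRUE),
                 n_undefined = sum(is.na(val))),
            class = "tsnr_map")
}
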
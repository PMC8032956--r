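#' ROI-averaged time series
#'
#' Row i is the mean course over voxels carrying ROI i's label (optionally
#' intersected with a brain mask); ROIs with no covered voxel are dropped
#' with a warning, mirroring the exclusion of regions without sufficient
#' signal.
#'
#' @param series A [bold_series()].
#' @param labels A [label_volume()] on the same grid.
#' @param mask Optional [brain_mask()] restricting the voxels used.
#' @return An object of class `roi_timeseries`: `ts` (n_roi x n_frames),
#'   `table` (ROI metadata of retained ROIs), `dropped` (ids).
#' @export
extract_roi_timeseries <- function(series, labels, mask = NULL) {
  stopifnot(inherits(series, "bold_series"), inherits(labels, "label_volume"))
  if (!grids_equal(series$grid, labels$grid))
    stop("series and label grids differ")
  lab <- labels$labels
  if (!is.null(mask)) {
    if (!grids_equal(series$grid, mask$grid)) stop("mask grid differs")
    lab <- lab * mask$voxels
  }
  flat <- matrix(series$data, ncol = series$n_frames)
  ids <- labels$table$id
  counts <- vapply(ids, function(i) sum(lab == i), integer(1))
  dropped <- ids[counts == 0]
  if (length(dropped))
    warning("dropping ROIs with no in-mask voxels: ",
            paste(dropped, collapse = ", "))
  keep <- ids[counts > 0]
  ts <- roi_mean_courses(flat, lab, keep)
  tab <- labels$table[match(keep, labels$table$id), , drop = FALSE]
  rownames(ts) <- tab$name
  structure(list(ts = ts, table = tab, dropped = dropped,
                 tr_vol = series$tr_vol),
            class = "roi_timeseries")
}

#' Global signal
#'
#' Frame-wise mean over all in-mask voxels.
#'
#' @param series A [bold_series()].
#' @param mask A [brain_mask()].
#' @return Numeric vector of length `n_frames`.
#' @export
global_signal <- function(series, mask) {
  stopifnot(inherits(series, "bold_series"), inherits(mask, "brain_mask"))
  if (!grids_equal(series$grid, mask$grid)) stop("series and mask grids differ")
  colMeans(mask_matrix(series, mask))
}

fc_matrix <- function(m, kind, space, roi_names, undefined = NULL) {
  dimnames(m) <- list(roi_names, roi_names)
  structure(list(m = m, kind = kind, space = space,
                 roi_names = roi_names, undefined = undefined),
            class = "fc_matrix")
}

#' Full-correlation FC matrix
#'
#' Pairwise product-moment correlations of the ROI courses.
#'
#' @param ts A [extract_roi_timeseries()] result.
#' @return An `fc_matrix` (kind `full`, space `r`).
#' @export
fc_full <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  if (ncol(ts$ts) < 3) stop("need >= 3 frames")
  sds <- apply(ts$ts, 1, stats::sd)
  if (any(sds == 0))
    stop("constant ROI course: ", paste(ts$table$name[sds == 0], collapse = ", "))
  fc_matrix(stats::cor(t(ts$ts)), "full", "r", ts$table$name)
}

#' Partial-correlation FC matrix with global-signal adjustment
#'
#' Each ROI course is regressed on the global signal (plus intercept) and
#' correlations are computed between the residuals; this equals the
#' first-order partial correlation controlling for the global signal.
#' ROI courses that are (numerically) collinear with the global signal
#' yield undefined edges, flagged `NA`.
#'
#' @param ts A [extract_roi_timeseries()] result.
#' @param gs Global-signal course (same length, nonconstant).
#' @return An `fc_matrix` (kind `partial_gsr`, space `r`).
#' @export
fc_partial_gsr <- function(ts, gs) {
  stopifnot(inherits(ts, "roi_timeseries"))
  if (length(gs) != ncol(ts$ts)) stop("global signal length mismatch")
  if (stats::sd(gs) == 0) stop("global signal is constant")
  g <- gs - mean(gs)
  X <- t(ts$ts)
  Xc <- sweep(X, 2, colMeans(X))
  beta <- as.numeric(crossprod(g, Xc)) / sum(g^2)
  res <- Xc - outer(g, beta)
  sds <- apply(res, 2, stats::sd)
  tiny <- sds < 1e-10 * apply(Xc, 2, stats::sd)
  m <- suppressWarnings(stats::cor(res))
  if (any(tiny)) {
    m[tiny, ] <- NA
    m[, tiny] <- NA
  }
  diag(m) <- 1
  fc_matrix(m, "partial_gsr", "r", ts$table$name,
            undefined = which(tiny))
}

#' Fisher z-transform of an FC matrix
#'
#' Off-diagonal `z = atanh(r)` with `|r|` clipped to `1 - 1e-7` first; the
#' diagonal is set to 0 by convention.
#'
#' @param fc An `fc_matrix` in r-space.
#' @return The `fc_matrix` in z-space; attribute `n_clipped` counts
#'   clipped entries.
#' @export
fisher_z <- function(fc) {
  stopifnot(inherits(fc, "fc_matrix"))
  if (fc$space != "r") stop("input must be in r-space")
  r <- fc$m
  clip <- 1 - 1e-7
  n_clipped <- sum(abs(r[upper.tri(r)]) > clip, na.rm = TRUE) * 2
  r <- pmin(pmax(r, -clip), clip)
  z <- atanh(r)
  diag(z) <- 0
  out <- fc_matrix(z, fc$kind, "z", fc$roi_names, undefined = fc$undefined)
  out$n_clipped <- n_clipped
  out
}

#' Within-group variability of Fisher-z FC matrices
#'
#' Per-edge sample standard deviation (n - 1 denominator) across subjects,
#' summarized as the mean over off-diagonal upper-triangle edges; edges
#' undefined (`NA`) in any subject are excluded from the summary with a
#' count.
#'
#' @param z_list List of z-space matrices (identical ROI sets, >= 2).
#' @return An object of class `group_variability`: `edge_sd` (matrix),
#'   `summary` (scalar), `n_excluded`.
#' @export
within_group_variability <- function(z_list) {
  if (length(z_list) < 2) stop("need >= 2 matrices")
  mats <- lapply(z_list, function(x) if (inherits(x, "fc_matrix")) x$m else x)
  p <- nrow(mats[[1]])
  nm <- rownames(mats[[1]])
  for (m in mats) {
    if (!all(dim(m) == p)) stop("matrices must share one ROI set")
    if (!is.null(nm) && !is.null(rownames(m)) && !identical(rownames(m), nm))
      stop("matrices must share one ROI set (names differ)")
  }
  arr <- simplify2array(mats)
  edge_sd <- apply(arr, c(1, 2), stats::sd)
  ut <- upper.tri(edge_sd)
  vals <- edge_sd[ut]
  structure(list(edge_sd = edge_sd,
                 summary = mean(vals, na.rm = TRUE),
                 n_excluded = sum(is.na(vals))),
            class = "group_variability")
}
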
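#' Voxel grid geometry
#'
#' A `volume_grid` records the voxel counts, voxel sizes (mm) and the 4x4
#' voxel-to-world affine (RAS convention, 0-based voxel indices) shared by
#' all volumes of a session.
#'
#' @param nx,ny,nz Voxel counts along each axis (>= 1).
#' @param dx,dy,dz Voxel sizes in mm (> 0).
#' @param affine 4x4 voxel-to-world matrix; defaults to a diagonal scaling
#'   by the voxel sizes.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(nx, ny, nz, dx = 1, dy = 1, dz = 1, affine = NULL) {
  counts <- c(nx, ny, nz)
  sizes <- c(dx, dy, dz)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("voxel counts must be integers >= 1")
  if (any(sizes <= 0)) stop("voxel sizes must be > 0")
  if (is.null(affine)) affine <- diag(c(sizes, 1))
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4))) stop("affine must be 4x4")
  if (abs(det(affine)) < .Machine$double.eps) stop("affine must be invertible")
  structure(list(dim = as.integer(counts), voxdim = sizes, affine = affine),
            class = "volume_grid")
}

grids_equal <- function(a, b, tol = 1e-6) {
  all(a$dim == b$dim) && all(abs(a$voxdim - b$voxdim) < tol)
}

#' 4D BOLD time series
#'
#' @param data 4D numeric array (x, y, z, t); all values finite.
#' @param grid A [volume_grid()] consistent with the first three dimensions.
#' @param tr_vol Volume sampling interval in seconds (> 0).
#' @return An object of class `bold_series` with fields `data`, `grid`,
#'   `tr_vol`, `n_frames`.
#' @export
bold_series <- function(data, grid, tr_vol) {
  d <- dim(data)
  if (length(d) != 4L) stop("bold series data must be 4D (x, y, z, t)")
  if (!all(d[1:3] == grid$dim)) stop("data spatial dimensions do not match grid")
  if (!is.numeric(tr_vol) || length(tr_vol) != 1L || !is.finite(tr_vol) || tr_vol <= 0)
    stop("tr_vol must be a positive scalar (seconds)")
  if (!all(is.finite(data))) stop("bold series contains non-finite values")
  structure(list(data = data, grid = grid, tr_vol = tr_vol,
                 n_frames = as.integer(d[4])),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("<bold_series> %dx%dx%d voxels, %d frames, TR_vol %.3g s\n",
              x$grid$dim[1], x$grid$dim[2], x$grid$dim[3], x$n_frames, x$tr_vol))
  invisible(x)
}

#' Brain mask
#'
#' @param voxels Logical 3D array; at least one `TRUE` voxel.
#' @param grid The [volume_grid()] of the series the mask belongs to.
#' @return An object of class `brain_mask`.
#' @export
brain_mask <- function(voxels, grid) {
  voxels <- array(as.logical(voxels), dim = dim(voxels))
  if (length(dim(voxels)) != 3L) stop("mask must be 3D")
  if (!all(dim(voxels) == grid$dim)) stop("mask dimensions do not match grid")
  if (!any(voxels)) stop("mask must contain at least one voxel")
  structure(list(voxels = voxels, grid = grid), class = "brain_mask")
}

#' ROI label volume
#'
#' Integer-labelled parcellation (0 = background) plus a lookup table.
#'
#' @param labels Integer 3D array; 0 marks background.
#' @param grid The [volume_grid()].
#' @param table `data.frame` with columns `id`, `name`, `hemisphere`; must
#'   cover every nonzero label in the volume, ids unique.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, grid, table) {
  if (length(dim(labels)) != 3L) stop("label volume must be 3D")
  if (!all(dim(labels) == grid$dim)) stop("label dimensions do not match grid")
  if (any(abs(labels - round(labels)) > 0)) stop("labels must be integer-valued")
  labels <- array(as.integer(labels), dim = dim(labels))
  table <- as.data.frame(table)
  need <- c("id", "name", "hemisphere")
  if (!all(need %in% names(table)))
    stop("label table must have columns id, name, hemisphere")
  if (anyDuplicated(table$id)) stop("label ids must be unique")
  present <- sort(unique(labels[labels != 0L]))
  if (length(present) == 0L) stop("label volume contains no ROIs (all zero)")
  missing <- setdiff(present, table$id)
  if (length(missing))
    stop("labels present in volume but missing from table: ",
         paste(missing, collapse = ", "))
  structure(list(labels = labels, grid = grid,
                 table = table[table$id %in% present, , drop = FALSE]),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %d ROIs on %dx%dx%d grid\n",
              nrow(x$table), x$grid$dim[1], x$grid$dim[2], x$grid$dim[3]))
  invisible(x)
}

#' Subject scan metadata wrapper
#'
#' @param subject_id Subject identifier.
#' @param group Group label, `"CTL"` or `"STZ"`.
#' @param timepoint Timepoint in weeks.
#' @param run Run index (>= 1).
#' @param series The [bold_series()].
#' @return An object of class `subject_scan`.
#' @export
subject_scan <- function(subject_id, group = c("CTL", "STZ"), timepoint, run = 1L,
                         series) {
  group <- match.arg(group)
  if (run < 1) stop("run index must be >= 1")
  if (missing(timepoint) || !is.finite(timepoint)) stop("timepoint must be set")
  stopifnot(inherits(series, "bold_series"))
  structure(list(subject_id = as.character(subject_id), group = group,
                 timepoint = timepoint, run = as.integer(run), series = series),
            class = "subject_scan")
}

# Flatten the in-mask voxel courses into an n_voxel x n_frames matrix.
mask_matrix <- function(series, mask) {
  idx <- which(mask$voxels)
  nt <- series$n_frames
  m <- matrix(series$data, ncol = nt)[idx, , drop = FALSE]
  attr(m, "voxel_index") <- idx
  m
}

# Write an n_voxel x n_frames matrix back into a series-shaped 4D array.
unmask_matrix <- function(m, idx, dim4) {
  out <- array(0, dim = dim4)
  flat <- matrix(out, ncol = dim4[4])
  flat[idx, ] <- m
  array(flat, dim = dim4)
}
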
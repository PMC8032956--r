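#' Read a 4D BOLD series from a NIfTI-1 file
#'
#' The grid (dimensions, voxel sizes, affine) is taken from the header. The
#' volume sampling interval is taken from the header `pixdim[4]` when
#' positive, otherwise from the `tr_vol` argument.
#'
#' @param path Path to a 4D `.nii`/`.nii.gz` file.
#' @param tr_vol Fallback volume TR in seconds when the header carries none.
#' @return A [bold_series()].
#' @export
read_bold <- function(path, tr_vol = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected a 4D BOLD image, got ", length(d), "D: ", path)
  vox <- RNifti::pixdim(img)
  header_tr <- if (length(vox) >= 4) vox[4] else 0
  tr <- if (is.finite(header_tr) && header_tr > 0) header_tr else tr_vol
  if (is.null(tr))
    stop("header pixdim[4] is 0 and no tr_vol argument given")
  grid <- volume_grid(d[1], d[2], d[3], vox[1], vox[2], vox[3],
                      affine = unclass(RNifti::xform(img)))
  bold_series(array(as.numeric(img), dim = d), grid, tr)
}

#' Write a 4D BOLD series to NIfTI-1
#'
#' @param series A [bold_series()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_bold <- function(series, path) {
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(series$grid$voxdim, series$tr_vol)
  RNifti::qform(img) <- structure(series$grid$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a brain mask volume
#'
#' Nonzero voxels become mask members.
#'
#' @param path Path to a 3D NIfTI file.
#' @return A [brain_mask()].
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected a 3D mask image, got ", length(d), "D")
  vox <- RNifti::pixdim(img)
  grid <- volume_grid(d[1], d[2], d[3], vox[1], vox[2], vox[3],
                      affine = unclass(RNifti::xform(img)))
  brain_mask(array(img != 0, dim = d), grid)
}

#' Read an ROI label volume with its lookup table
#'
#' @param path Path to a 3D integer-valued NIfTI file in functional space.
#' @param table_path TSV with columns `id`, `name`, `hemisphere`.
#' @return A [label_volume()].
#' @export
read_labels <- function(path, table_path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!file.exists(table_path)) stop("file not found: ", table_path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected a 3D label image, got ", length(d), "D")
  vals <- as.numeric(img)
  if (any(abs(vals - round(vals)) > 1e-6))
    stop("label volume is not integer-valued")
  vox <- RNifti::pixdim(img)
  grid <- volume_grid(d[1], d[2], d[3], vox[1], vox[2], vox[3],
                      affine = unclass(RNifti::xform(img)))
  table <- utils::read.delim(table_path, stringsAsFactors = FALSE)
  label_volume(array(round(vals), dim = d), grid, table)
}

#' Write / read a named square matrix as TSV
#'
#' The TSV carries ROI names as both header row and first column; values
#' round-trip to better than 1e-12.
#'
#' @param m Square numeric matrix.
#' @param roi_names Character vector, one name per row/column.
#' @param path Output path.
#' @return `path` (write) or the named matrix (read).
#' @export
write_matrix_tsv <- function(m, roi_names, path) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  if (length(roi_names) != nrow(m)) stop("roi_names length must match matrix")
  df <- data.frame(roi = roi_names, m, check.names = FALSE)
  names(df) <- c("roi", roi_names)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(utils::read.delim(path, check.names = FALSE,
                                   stringsAsFactors = FALSE),
                 error = function(e) stop("malformed matrix TSV: ",
                                          conditionMessage(e)))
  if (ncol(df) < 2 || names(df)[1] != "roi")
    stop("malformed matrix TSV: expected 'roi' header column")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || nrow(m) != ncol(m))
    stop("malformed matrix TSV: non-numeric or non-square body")
  rownames(m) <- df$roi
  if (!identical(colnames(m), df$roi))
    stop("malformed matrix TSV: row and column names disagree")
  m
}

#' Read / write artifact-component label files
#'
#' On disk, component indices use the 1-based bracketed-list convention of
#' hand-label files (e.g. `[1, 4, 7]`). In R (1-based) they are used as-is.
#'
#' @param path Label file path.
#' @return Integer vector of component indices.
#' @export
read_label_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = " ")
  body <- regmatches(txt, regexpr("\\[[^]]*\\]", txt))
  if (length(body) == 0) stop("malformed label file (no bracketed list): ", path)
  inner <- gsub("\\[|\\]", "", body)
  if (!nzchar(trimws(inner))) return(integer(0))
  out <- suppressWarnings(as.integer(strsplit(inner, "[,\\s]+")[[1]]))
  out <- out[!is.na(out)]
  if (any(out < 1)) stop("component indices must be >= 1")
  sort(unique(out))
}

#' @rdname read_label_list
#' @param indices Integer vector of 1-based component indices.
#' @export
write_label_list <- function(indices, path) {
  writeLines(paste0("[", paste(sort(unique(as.integer(indices))),
                               collapse = ", "), "]"), path)
  invisible(path)
}
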
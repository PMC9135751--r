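#' Labeled 3D volume
#'
#' A minimal container for a 3D integer label grid plus voxel spacing in mm.
#' World coordinates follow the package convention: the voxel at 0-based index
#' `(i, j, k)` sits at `(i, j, k) * spacing` mm, with no affine rotation.
#'
#' @param data 3D integer array of labels (0 = background).
#' @param spacing Numeric length-3, voxel spacing in mm (x, y, z).
#' @param labels Optional named integer vector documenting the label
#'   dictionary, e.g. `c(cgm = 1, wm = 2)`.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, spacing, labels = NULL) {
  if (length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three positive voxel sizes in mm", call. = FALSE)
  }
  storage.mode(data) <- "integer"
  structure(
    list(data = data, spacing = spacing, labels = labels),
    class = "label_volume"
  )
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing, 4), collapse = " x "), " mm\n",
      sep = "")
  tab <- table(x$data)
  cat("  labels:", paste(names(tab), collapse = ", "), "\n")
  invisible(x)
}

#' Count voxels per label
#'
#' @param vol A [label_volume()].
#' @return A tibble with columns `label` and `n_voxels`.
#' @export
label_counts <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  tab <- table(vol$data)
  tibble::tibble(
    label = as.integer(names(tab)),
    n_voxels = as.integer(tab)
  )
}

# ---- minimal NIfTI-1 I/O -----------------------------------------------
# Single-file uncompressed .nii or gzipped .nii.gz, datatype int16 on write;
# uint8/int16/int32/float32/float64/uint16 on read. Only the pixdim spacing
# is interpreted (the package works in a scanner-axis-aligned frame).

nifti_con <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a label volume as NIfTI-1
#'
#' Writes a single-file NIfTI-1 volume (datatype int16) carrying the voxel
#' spacing in `pixdim` and a diagonal sform. Compressed output is selected by
#' a `.nii.gz` suffix.
#'
#' @param vol A [label_volume()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  d <- dim(vol$data)
  sp <- vol$spacing
  con <- nifti_con(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wc <- function(n) writeBin(raw(n), con)

  wi(348L, 4)                                   # sizeof_hdr
  wc(35)                                        # data_type, db_name, extents, session_error, regular
  wc(1)                                         # dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2)               # dim[8]
  wf(c(0, 0, 0))                                # intent_p1..3
  wi(0L, 2)                                     # intent_code
  wi(4L, 2)                                     # datatype = int16
  wi(16L, 2)                                    # bitpix
  wi(0L, 2)                                     # slice_start
  wf(c(1, sp, 0, 0, 0, 0))                      # pixdim[8] (qfac = 1)
  wf(352)                                       # vox_offset
  wf(1); wf(0)                                  # scl_slope, scl_inter
  wi(0L, 2); wc(1)                              # slice_end, slice_code
  writeBin(as.raw(2L), con)                     # xyzt_units = mm
  wf(c(0, 0, 0, 0))                             # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                              # glmax, glmin
  wc(80); wc(24)                                # descrip, aux_file
  wi(0L, 2); wi(1L, 2)                          # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0, 0, 0, 0))                       # quatern b,c,d + qoffset x,y,z
  wf(c(sp[1], 0, 0, 0))                         # srow_x
  wf(c(0, sp[2], 0, 0))                         # srow_y
  wf(c(0, 0, sp[3], 0))                         # srow_z
  wc(16)                                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  wc(4)                                         # extension flag
  writeBin(as.integer(vol$data), con, size = 2L, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume as a label volume
#'
#' Reads single-file NIfTI-1 (`.nii` / `.nii.gz`), either endianness, common
#' integer and float datatypes. Values are rounded to integers; the voxel
#' spacing is taken from `pixdim`.
#'
#' @param path Path to the volume.
#' @return A [label_volume()].
#' @export
read_nifti <- function(path) {
  con <- nifti_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header in ", path, call. = FALSE)
  rd <- function(what, n, size, endian, offset) {
    readBin(hdr[(offset + 1L):length(hdr)], what, n = n, size = size, endian = endian)
  }
  endian <- "little"
  if (rd("integer", 1, 4, endian, 0) != 348L) {
    endian <- "big"
    if (rd("integer", 1, 4, endian, 0) != 348L) {
      stop("not a NIfTI-1 file: ", path, call. = FALSE)
    }
  }
  dims <- rd("integer", 8, 2, endian, 40)
  ndim <- dims[1]
  if (ndim < 3L) stop("expected a 3D NIfTI volume", call. = FALSE)
  d <- dims[2:4]
  nvox <- prod(pmax(dims[2:(1 + ndim)], 1L))
  datatype <- rd("integer", 1, 2, endian, 70)
  pixdim <- rd("double", 8, 4, endian, 76)
  vox_offset <- rd("double", 1, 4, endian, 108)
  scl_slope <- rd("double", 1, 4, endian, 112)
  scl_inter <- rd("double", 1, 4, endian, 116)

  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  vals <- switch(
    as.character(datatype),
    "2"   = as.numeric(readBin(con, "integer", n = nvox, size = 1, signed = FALSE, endian = endian)),
    "4"   = as.numeric(readBin(con, "integer", n = nvox, size = 2, endian = endian)),
    "8"   = as.numeric(readBin(con, "integer", n = nvox, size = 4, endian = endian)),
    "16"  = readBin(con, "double", n = nvox, size = 4, endian = endian),
    "64"  = readBin(con, "double", n = nvox, size = 8, endian = endian),
    "512" = as.numeric(readBin(con, "integer", n = nvox, size = 2, signed = FALSE, endian = endian)),
    stop("unsupported NIfTI datatype: ", datatype, call. = FALSE)
  )
  if (length(vals) < prod(d)) stop("truncated NIfTI data in ", path, call. = FALSE)
  vals <- vals[seq_len(prod(d))]  # first 3D frame only
  if (isTRUE(scl_slope != 0) && (scl_slope != 1 || scl_inter != 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  label_volume(array(as.integer(round(vals)), dim = d), spacing = pixdim[2:4])
}
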
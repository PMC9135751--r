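#' In-plane resolution from field of view and acquisition matrix
#'
#' The acquired in-plane voxel size is the field of view divided by the
#' matrix size (e.g. a 320 mm field of view on a 256 matrix gives 1.25 mm).
#'
#' @param fov Field of view, mm.
#' @param matrix_size Acquisition matrix size (count).
#' @return In-plane resolution, mm.
#' @export
in_plane_resolution <- function(fov, matrix_size) {
  if (any(!is.finite(fov)) || any(fov <= 0)) {
    stop("fov must be positive", call. = FALSE)
  }
  if (any(!is.finite(matrix_size)) || any(matrix_size <= 0)) {
    stop("matrix_size must be positive", call. = FALSE)
  }
  fov / matrix_size
}

#' Voxel volume from spacing
#'
#' @param spacing Numeric length-3 voxel spacing, mm.
#' @return Voxel volume, mm^3.
#' @export
voxel_volume <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be three positive mm values", call. = FALSE)
  }
  prod(spacing)
}

#' Voxel-count tissue volumetry
#'
#' Counts voxels per tissue class and converts to volumes using the voxel
#' size (count x voxel volume), reported in cm^3. Pure label counting with no
#' partial-volume correction. Labels present in the volume but absent from
#' the tissue dictionary are ignored with a warning.
#'
#' @param seg A [label_volume()] segmentation.
#' @param tissues Named integer vector mapping tissue names to labels;
#'   defaults to [segmentation_labels()].
#' @param hemisphere_mask Optional logical array (same shape) restricting the
#'   count, e.g. one hemisphere; see [hemisphere_masks()].
#' @return Tibble with columns `tissue`, `n_voxels`, `volume_cm3`.
#' @export
tissue_volumes <- function(seg, tissues = segmentation_labels(),
                           hemisphere_mask = NULL) {
  stopifnot(inherits(seg, "label_volume"))
  if (is.null(seg$spacing)) stop("segmentation lacks spacing metadata", call. = FALSE)
  data <- seg$data
  if (!is.null(hemisphere_mask)) {
    stopifnot(identical(dim(hemisphere_mask), dim(data)))
    data <- data[hemisphere_mask]
  }
  vv <- voxel_volume(seg$spacing)
  present <- setdiff(unique(as.integer(data)), 0L)
  unknown <- setdiff(present, as.integer(tissues))
  if (length(unknown) > 0) {
    warning("ignoring labels absent from the tissue dictionary: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  counts <- unname(vapply(tissues, function(lab) sum(data == lab), integer(1)))
  tibble::tibble(
    tissue = names(tissues),
    n_voxels = counts,
    volume_cm3 = counts * vv / 1000
  )
}

#' Left/right hemisphere masks for a label volume
#'
#' The package convention splits hemispheres by the x coordinate about the
#' volume's mid-sagittal plane; voxels exactly on the plane belong to the
#' left hemisphere.
#'
#' @param vol A [label_volume()].
#' @param plane_x Mid-sagittal x in mm; defaults to the grid center.
#' @return List of logical arrays `left` and `right`.
#' @export
hemisphere_masks <- function(vol, plane_x = NULL) {
  stopifnot(inherits(vol, "label_volume"))
  d <- dim(vol$data)
  plane_x <- plane_x %||% ((d[1] - 1) * vol$spacing[1] / 2)
  x <- (seq_len(d[1]) - 1) * vol$spacing[1]
  left_line <- x <= plane_x
  left <- array(rep(left_line, times = d[2] * d[3]), dim = d)
  list(left = left, right = !left)
}
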
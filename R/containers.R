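#' Dynamic image series
#'
#' Container for a multi-slice free-breathing image time series.
#'
#' @param data 4D numeric array indexed `(row, col, slice, frame)`, in
#'   arbitrary signal units.
#' @param frame_rate acquisition frame rate in Hz.
#' @param voxel_size numeric triple, voxel size in mm (in-plane row, column,
#'   slice thickness).
#' @param registered logical; `TRUE` after motion compensation.
#' @param shifts `NULL`, or a `slice x frame x 2` array of applied `(dy, dx)`
#'   corrections in voxels.
#' @return object of class `dynamic_series`.
#' @export
dynamic_series <- function(data, frame_rate, voxel_size = c(3.3, 3.3, 12),
                           registered = FALSE, shifts = NULL) {
  if (length(dim(data)) != 4L)
    stop("series data must be a 4D array (row, col, slice, frame)")
  assert_positive(frame_rate, "frame_rate")
  if (!is.null(shifts) && !all(is.finite(shifts)))
    stop("registration shifts must be finite")
  structure(list(data = data, frame_rate = frame_rate,
                 voxel_size = voxel_size, registered = isTRUE(registered),
                 shifts = shifts),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "dynamic series: %d x %d grid, %d slices, %d frames at %.3g Hz (%s)\n",
    d[1], d[2], d[3], d[4], x$frame_rate,
    if (x$registered) "registered" else "unregistered"))
  invisible(x)
}

#' Side-labelled lung mask
#'
#' Voxel labels follow the convention 0 = background, 1 = right lung,
#' 2 = left lung, 3 = heart. Side labels are taken from the mask as given;
#' anatomical left/right is never inferred from image orientation.
#'
#' @param labels integer 3D array `(row, col, slice)` of labels.
#' @return object of class `lung_mask`.
#' @export
lung_mask <- function(labels) {
  if (length(dim(labels)) != 3L)
    stop("mask labels must be a 3D array (row, col, slice)")
  labels <- array(as.integer(labels), dim(labels))
  if (!all(labels %in% 0:3))
    stop("mask labels must be 0 (background), 1 (right), 2 (left) or 3 (heart)")
  structure(list(labels = labels), class = "lung_mask")
}

#' @export
print.lung_mask <- function(x, ...) {
  cat(sprintf(
    "lung mask: %s voxels right, %s left, %s heart on %d slices\n",
    sum(x$labels == 1L), sum(x$labels == 2L), sum(x$labels == 3L),
    dim(x$labels)[3]))
  invisible(x)
}

#' Logical lung selector from a mask
#'
#' @param mask a [lung_mask()].
#' @param side `"both"`, `"right"` or `"left"`.
#' @return logical 3D array selecting lung voxels.
#' @export
lung_voxels <- function(mask, side = c("both", "right", "left")) {
  side <- match.arg(side)
  switch(side,
         both = mask$labels == 1L | mask$labels == 2L,
         right = mask$labels == 1L,
         left = mask$labels == 2L)
}
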
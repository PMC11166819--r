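#' Temporal mean image of a series
#'
#' @param series a [dynamic_series()].
#' @return 3D array `(row, col, slice)` of per-voxel temporal means.
#' @export
series_mean_image <- function(series) {
  d <- dim(series$data)
  array(rowMeans(matrix(series$data, prod(d[1:3]), d[4])), d[1:3])
}

#' Select the mid-respiratory baseline frame
#'
#' Returns the index of the frame whose whole-lung mean intensity is
#' closest to the temporal median of the whole-lung mean intensity (the
#' mid-respiratory state); exact ties are broken toward the earliest
#' frame. Invariant under global intensity scaling.
#'
#' @param series a [dynamic_series()].
#' @param mask a [lung_mask()].
#' @return frame index (1-based).
#' @export
select_baseline_frame <- function(series, mask) {
  lung <- lung_voxels(mask)
  if (!any(lung)) stop("empty lung mask")
  d <- dim(series$data)
  if (d[4] < 3L) stop("need at least 3 frames to select a baseline")
  flat <- matrix(series$data, prod(d[1:3]), d[4])
  lung_mean <- colMeans(flat[which(lung), , drop = FALSE])
  med <- median(lung_mean)
  which.min(abs(lung_mean - med))
}

# Integer-shift estimate of frame vs reference by circular FFT
# cross-correlation (means removed). Returns c(dy, dx, ncc) where ncc is
# the normalized correlation at the peak.
xcorr_shift <- function(ref, frame) {
  a <- ref - mean(ref)
  b <- frame - mean(frame)
  cc <- Re(fft(Conj(fft(a)) * fft(b), inverse = TRUE))
  peak <- arrayInd(which.max(cc), dim(cc))
  wrap <- function(i, n) { d <- i - 1L; if (d > n / 2) d - n else d }
  dy <- wrap(peak[1], nrow(ref))
  dx <- wrap(peak[2], ncol(ref))
  # unnormalized inverse FFT scales the correlation by the voxel count
  denom <- sqrt(sum(a^2) * sum(b^2)) * length(a)
  ncc <- if (denom > 0) max(cc) / denom else 0
  c(dy, dx, ncc)
}

#' Translation-based motion compensation
#'
#' Registers every frame of every slice to the baseline frame by the
#' integer `(dy, dx)` translation maximizing the 2D cross-correlation.
#' Voxels exposed at the frame edge are filled by edge replication. A frame
#' whose correlation peak is weak (normalized correlation < `min_ncc`) is
#' left unshifted and flagged via a message; an estimated shift larger
#' than a quarter of the grid raises an error (registration failure).
#'
#' @param series a [dynamic_series()].
#' @param baseline baseline frame index (see [select_baseline_frame()]).
#' @param min_ncc confidence floor on the normalized correlation peak.
#' @return a registered [dynamic_series()] with the applied per-slice,
#'   per-frame corrections in `$shifts`.
#' @export
register_translation <- function(series, baseline, min_ncc = 0.3) {
  d <- dim(series$data)
  if (baseline < 1L || baseline > d[4]) stop("baseline frame out of range")
  max_shift <- min(d[1], d[2]) / 4
  out <- series$data
  shifts <- array(0L, c(d[3], d[4], 2L))
  for (s in seq_len(d[3])) {
    ref <- series$data[, , s, baseline]
    low_conf <- 0L
    for (k in seq_len(d[4])) {
      est <- xcorr_shift(ref, series$data[, , s, k])
      if (est[3] < min_ncc) {
        low_conf <- low_conf + 1L
        est[1:2] <- 0
      } else if (max(abs(est[1:2])) > max_shift) {
        stop(sprintf(
          "registration failure: estimated shift (%d, %d) exceeds grid/4 on slice %d",
          est[1], est[2], s))
      }
      shifts[s, k, ] <- as.integer(est[1:2])
      if (est[1] != 0 || est[2] != 0)
        out[, , s, k] <- shift_matrix(series$data[, , s, k],
                                      -est[1], -est[2], fill = "edge")
    }
    if (low_conf > 0L)
      message(sprintf(
        "slice %d: %d low-confidence frames left unshifted", s, low_conf))
  }
  dynamic_series(out, series$frame_rate, series$voxel_size,
                 registered = TRUE, shifts = shifts)
}

#' Fallback lung segmentation from a mean image
#'
#' Naive intensity-based stand-in for when no lung mask is supplied:
#' Otsu's threshold over non-background voxels separates the low-intensity
#' lung parenchyma from brighter soft tissue; after dropping components
#' smaller than `min_size`, the two largest 6-connected low-intensity
#' components are labelled right/left by the column position of their
#' centroids. No heart label is produced.
#'
#' @param mean_img 3D array `(row, col, slice)`, e.g. from
#'   [series_mean_image()].
#' @param min_size minimum component size in voxels.
#' @return a [lung_mask()].
#' @export
segment_lungs_fallback <- function(mean_img, min_size = 30) {
  if (length(dim(mean_img)) == 2L)
    mean_img <- array(mean_img, c(dim(mean_img), 1L))
  mx <- max(mean_img)
  if (!is.finite(mx) || mx <= 0)
    stop("blank mean image; supply a lung mask")
  pos <- mean_img > 0.05 * mx
  vals <- mean_img[pos] / mx
  if (length(vals) < 2 * min_size)
    stop("too little foreground to segment; supply a lung mask")
  thr <- EBImage::otsu(EBImage::Image(matrix(vals, ncol = 1))) * mx
  low <- pos & mean_img < thr
  lab <- label_components(low)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_size)
  if (length(keep) < 2L)
    stop("fewer than two lung-sized components found; supply a lung mask")
  top2 <- keep[order(sizes[keep], decreasing = TRUE)][1:2]
  cent_col <- vapply(top2, function(k) {
    mean(arrayInd(which(lab == k), dim(lab))[, 2])
  }, numeric(1))
  right <- top2[which.min(cent_col)]
  left <- top2[which.max(cent_col)]
  labels <- array(0L, dim(mean_img))
  labels[lab == right] <- 1L
  labels[lab == left] <- 2L
  lung_mask(labels)
}
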
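#' Compute fractional-ventilation and relative-perfusion maps
#'
#' Decomposes every lung voxel's time series with the matrix-pencil
#' method and reads off the amplitudes at the previously estimated
#' respiratory and cardiac frequencies (nearest component within
#' `freq_tol`). Fractional ventilation is the respiratory-frequency
#' amplitude relative to the voxel's temporal mean signal; perfusion is
#' the raw cardiac-frequency amplitude (the slice-relative defect rule is
#' invariant to its scaling).
#'
#' @param series a registered [dynamic_series()].
#' @param mask a [lung_mask()].
#' @param freqs a `cardinal_frequencies` object from
#'   [estimate_cardinal_frequencies()].
#' @param freq_tol component-matching half-width in Hz.
#' @param pencil_L,order,sv_tol,max_order pencil parameters, as in
#'   [matrix_pencil_decompose()].
#' @return object of class `functional_maps`: list with 3D arrays `fv`
#'   (unitless) and `q` (signal units), `NA` outside the lung, plus the
#'   frequencies used.
#' @export
compute_functional_maps <- function(series, mask, freqs, freq_tol = 0.1,
                                    pencil_L = NULL, order = NULL,
                                    sv_tol = 1e-3, max_order = 16) {
  stopifnot(inherits(series, "dynamic_series"), inherits(mask, "lung_mask"),
            inherits(freqs, "cardinal_frequencies"))
  if (!series$registered)
    stop("series must be motion-compensated before spectral mapping; ",
         "run register_translation() (or construct with registered = TRUE)")
  d <- dim(series$data)
  if (!identical(d[1:3], dim(mask$labels)))
    stop("mask grid does not match the series grid")
  lung_idx <- which(lung_voxels(mask))
  n <- d[4]
  if (is.null(pencil_L)) pencil_L <- floor(n / 3)
  flat <- matrix(series$data, prod(d[1:3]), n)
  vox <- t(flat[lung_idx, , drop = FALSE])  # N x nvox
  amps <- mp_band_amplitudes_cpp(vox, series$frame_rate,
                                 as.integer(pencil_L),
                                 if (is.null(order)) -1L else
                                   as.integer(order),
                                 sv_tol, as.integer(max_order),
                                 c(freqs$f_resp, freqs$f_card), freq_tol)
  mean_sig <- colMeans(vox)
  fv_v <- ifelse(mean_sig > 0, amps[, 1] / pmax(mean_sig, .Machine$double.eps),
                 0)
  n_bad <- sum(mean_sig <= 0)
  if (n_bad > 0)
    warning(sprintf(
      "%d lung voxels with non-positive mean signal set to fv = 0", n_bad))
  fv <- array(NA_real_, d[1:3]); fv[lung_idx] <- fv_v
  q <- array(NA_real_, d[1:3]); q[lung_idx] <- amps[, 2]
  structure(list(fv = fv, q = q, f_resp = freqs$f_resp,
                 f_card = freqs$f_card),
            class = "functional_maps")
}

#' @export
print.functional_maps <- function(x, ...) {
  v <- x$fv[!is.na(x$fv)]
  cat(sprintf(
    "functional maps over %d lung voxels: median FV %.4f, median Q %.4g\n",
    length(v), median(v), median(x$q[!is.na(x$q)])))
  invisible(x)
}

#' Slice-wise relative-median defect mask
#'
#' A lung voxel is defective when its map value falls strictly below
#' `threshold_factor` times the median of the map over the segmented lung
#' area of its own coronal slice (the local region of interest). The rule
#' is invariant to per-slice rescaling of the map. Slices without lung
#' voxels contribute nothing.
#'
#' @param map_values 3D array of map values (`NA` outside the lung).
#' @param mask a [lung_mask()].
#' @param threshold_factor fraction of the slice median (default 0.70).
#' @return logical 3D array; `TRUE` marks defect voxels (always `FALSE`
#'   outside the lung).
#' @export
defect_mask <- function(map_values, mask, threshold_factor = 0.70) {
  if (!is.numeric(threshold_factor) || length(threshold_factor) != 1L ||
      !is.finite(threshold_factor) || threshold_factor <= 0 ||
      threshold_factor > 1)
    stop("threshold_factor must lie in (0, 1]")
  stopifnot(inherits(mask, "lung_mask"))
  dm <- dim(mask$labels)
  if (!identical(dim(map_values), dm))
    stop("map grid does not match the mask grid")
  lung <- lung_voxels(mask)
  out <- array(FALSE, dm)
  for (s in seq_len(dm[3])) {
    sel <- lung[, , s]
    if (!any(sel)) next
    vals <- map_values[, , s][sel]
    m <- median(vals)
    dmask <- matrix(FALSE, dm[1], dm[2])
    dmask[sel] <- vals < threshold_factor * m
    out[, , s] <- dmask
  }
  out
}
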
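#' Matrix-pencil decomposition of a sampled signal
#'
#' Models a uniformly sampled real signal as a sum of exponentially damped
#' sinusoids, `y_n ~ sum_k c_k z_k^n`. Poles `z_k` are obtained from the
#' generalized pencil of the shifted right-singular-vector matrices of the
#' Hankel data matrix, truncated to the dominant singular values; complex
#' amplitudes follow by linear least squares against the pole Vandermonde
#' system. Conjugate pole pairs are merged into one real component
#' (amplitude `2|c|`; `|c|` for a real pole), and components are returned
#' sorted by frequency.
#'
#' @param y numeric vector, the sampled signal (length >= 8, all finite).
#' @param frame_rate sampling rate in Hz.
#' @param pencil_L pencil parameter; must lie in `[N/3, N/2]` (defaults to
#'   `floor(N/3)`).
#' @param order model order (number of retained singular values), or `NULL`
#'   to select automatically as the number of singular values at least
#'   `sv_tol` times the largest.
#' @param sv_tol relative singular-value cutoff for automatic order
#'   selection (default 0.001, low enough to retain cardiac modulations a
#'   few percent of the baseline signal).
#' @param max_order cap on the automatically selected order (default 16),
#'   bounding the number of noise poles admitted per voxel.
#' @return data frame with one row per component and columns `frequency`
#'   (Hz), `damping` (1/s), `amplitude` (signal units, amplitude at the
#'   first sample), `phase` (radians, cosine convention).
#' @examples
#' t <- (0:149) / 3.3
#' y <- 5 + 2 * sin(2 * pi * 0.33 * t)
#' matrix_pencil_decompose(y, frame_rate = 3.3)
#' @export
matrix_pencil_decompose <- function(y, frame_rate, pencil_L = NULL,
                                    order = NULL, sv_tol = 1e-3,
                                    max_order = 16) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 8L) stop("signal too short for the pencil decomposition (N < 8)")
  if (!all(is.finite(y))) stop("signal contains non-finite samples")
  assert_positive(frame_rate, "frame_rate")
  if (is.null(pencil_L)) pencil_L <- floor(n / 3)
  pencil_L <- as.integer(pencil_L)
  if (pencil_L < floor(n / 3) || pencil_L > ceiling(n / 2))
    stop(sprintf("pencil_L = %d outside [N/3, N/2] for N = %d", pencil_L, n))
  if (!is.null(order)) assert_count(order, "order")
  assert_positive(sv_tol, "sv_tol")
  assert_count(max_order, "max_order")
  m <- mp_decompose_cpp(y, frame_rate, pencil_L,
                        if (is.null(order)) -1L else as.integer(order),
                        sv_tol, as.integer(max_order))
  as.data.frame(m)
}

#' Amplitude of the spectral component nearest a target frequency
#'
#' @param components data frame as returned by
#'   [matrix_pencil_decompose()].
#' @param f0 target frequency in Hz.
#' @param tol matching half-width in Hz; components farther than `tol`
#'   from `f0` are ignored. An exact tie in distance is broken toward the
#'   lower frequency.
#' @return the matched component's amplitude, or 0 when no component lies
#'   within `f0 +/- tol`.
#' @export
component_amplitude_at <- function(components, f0, tol = 0.1) {
  assert_positive(tol, "tol")
  if (nrow(components) == 0L) return(0)
  d <- abs(components$frequency - f0)
  ok <- which(d <= tol)
  if (length(ok) == 0L) return(0)
  # components are sorted by frequency; which.min takes the first (lower
  # frequency) on an exact tie
  components$amplitude[ok[which.min(d[ok])]]
}

#' DFT amplitude at an exact bin (independent oracle)
#'
#' Single-bin discrete Fourier amplitude `2|DFT(y)[k]|/N` (or `|DFT(y)[0]|/N`
#' at DC) for a frequency aligned to a DFT bin. Used as an independent
#' cross-check of the pencil decomposition on bin-aligned tones.
#'
#' @param y numeric vector.
#' @param frame_rate sampling rate in Hz.
#' @param f0 target frequency in Hz; must equal `k * frame_rate / N` for an
#'   integer `k`.
#' @return amplitude in signal units.
#' @export
dft_amplitude_oracle <- function(y, frame_rate, f0) {
  n <- length(y)
  k <- f0 * n / frame_rate
  if (abs(k - round(k)) > 1e-9)
    stop(sprintf("f0 = %g Hz is not aligned to a DFT bin (k = %g)", f0, k))
  k <- round(k)
  if (k < 0 || k > n / 2) stop("f0 outside [0, frame_rate/2]")
  a <- Mod(fft(y)[k + 1L]) / n
  if (k == 0) a else 2 * a
}

#' Default respiratory and cardiac search bands
#'
#' Respiratory band `[0.1, 0.6)` Hz and cardiac band `[0.6, 3.0]` Hz cover
#' pediatric tidal-breathing and heart rates.
#' @return list with elements `resp` and `card`, each `c(lower, upper)` Hz.
#' @export
default_bands <- function() {
  list(resp = c(0.1, 0.6), card = c(0.6, 3.0))
}

reconstruct_components <- function(components, n, frame_rate) {
  t <- (seq_len(n) - 1) / frame_rate
  y <- numeric(n)
  for (i in seq_len(nrow(components))) {
    y <- y + components$amplitude[i] * exp(components$damping[i] * t) *
      cos(2 * pi * components$frequency[i] * t + components$phase[i])
  }
  y
}

band_peak <- function(components, band, upper_open = FALSE) {
  f <- components$frequency
  inb <- if (upper_open) f >= band[1] & f < band[2] else
    f >= band[1] & f <= band[2]
  if (!any(inb)) return(NULL)
  sub <- components[inb, , drop = FALSE]
  sub[which.max(sub$amplitude), , drop = FALSE]
}

#' Estimate the respiratory and cardiac frequencies of a series
#'
#' Decomposes the whole-lung mean time series (and the heart-region mean,
#' when the mask labels a heart region, for the cardiac band) and returns
#' the frequency of the largest-amplitude component inside each band.
#' A band with no component, or whose best component does not rise at
#' least 3-fold above the residual noise floor, raises an error naming
#' the band.
#'
#' @param series a registered [dynamic_series()].
#' @param mask a [lung_mask()].
#' @param bands list with `resp` and `card` band limits in Hz (default
#'   [default_bands()]).
#' @param pencil_L,order,sv_tol,max_order passed to
#'   [matrix_pencil_decompose()].
#' @return object of class `cardinal_frequencies`: list with `f_resp`,
#'   `f_card` (Hz) and the bands used.
#' @export
estimate_cardinal_frequencies <- function(series, mask,
                                          bands = default_bands(),
                                          pencil_L = NULL, order = NULL,
                                          sv_tol = 1e-3, max_order = 16) {
  stopifnot(inherits(series, "dynamic_series"), inherits(mask, "lung_mask"))
  if (bands$resp[2] > bands$card[1])
    stop("respiratory band upper limit must not exceed cardiac band lower limit")
  lung <- mask$labels == 1L | mask$labels == 2L
  if (!any(lung)) stop("empty lung mask")
  n_frames <- dim(series$data)[4]
  mean_series <- function(sel3d) {
    idx <- which(sel3d)
    flat <- matrix(series$data, ncol = n_frames)
    colMeans(flat[idx, , drop = FALSE])
  }

  pick <- function(y, band, band_name, upper_open = FALSE) {
    comps <- matrix_pencil_decompose(y, series$frame_rate, pencil_L, order,
                                     sv_tol, max_order)
    peak <- band_peak(comps, band, upper_open)
    if (is.null(peak))
      stop(sprintf("no spectral component found in the %s band [%g, %g] Hz",
                   band_name, band[1], band[2]))
    resid <- y - reconstruct_components(comps, length(y), series$frame_rate)
    floor_amp <- sd(resid) * sqrt(2 / length(y))
    if (peak$amplitude <= 3 * floor_amp)
      stop(sprintf(
        "no component above 3x the noise floor in the %s band [%g, %g] Hz",
        band_name, band[1], band[2]))
    peak$frequency
  }

  y_lung <- mean_series(lung)
  f_resp <- pick(y_lung, bands$resp, "respiratory", upper_open = TRUE)
  heart <- mask$labels == 3L
  y_card <- if (any(heart)) mean_series(heart) else y_lung
  f_card <- pick(y_card, bands$card, "cardiac")

  structure(list(f_resp = f_resp, f_card = f_card, bands = bands),
            class = "cardinal_frequencies")
}

#' @export
print.cardinal_frequencies <- function(x, ...) {
  cat(sprintf("cardinal frequencies: f_resp = %.4f Hz, f_card = %.4f Hz\n",
              x$f_resp, x$f_card))
  invisible(x)
}
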
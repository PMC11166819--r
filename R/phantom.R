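#' Phantom configuration
#'
#' Parameters of the synthetic free-breathing dynamic series generator.
#' Defaults emulate the acquisition this package targets: ~150 coronal
#' frames per slice at 3.3 frames/s (about 45 s of free breathing), 8-14
#' slices, 3.3 x 3.3 x 12 mm voxels, with periodic respiratory- and
#' cardiac-frequency intensity modulations of the lung parenchyma.
#'
#' @param n_slices number of coronal slices.
#' @param n_frames frames per slice.
#' @param frame_rate frames per second (Hz); must exceed `2 * f_card`.
#' @param grid in-plane grid size, `c(rows, cols)`.
#' @param voxel_size voxel size in mm.
#' @param f_resp,f_card respiratory and cardiac modulation frequencies (Hz);
#'   `f_resp < f_card`.
#' @param resp_amp_mean,card_amp_mean mean modulation amplitudes as a
#'   fraction of the baseline lung signal.
#' @param amp_cv coefficient of variation of the smooth spatial amplitude
#'   fields.
#' @param defect_side `"left"`, `"right"` or `"none"`.
#' @param defect_fraction fraction of affected-side lung voxels inside the
#'   planted defect.
#' @param defect_attenuation multiplicative amplitude factor inside defects.
#' @param decouple_vq logical; plant independent ventilation and perfusion
#'   defect blobs instead of co-located ones.
#' @param noise_sd additive Gaussian noise SD as a fraction of the baseline
#'   lung signal.
#' @param bulk_shift_amp amplitude (voxels) of a respiratory bulk
#'   translation planted along the row axis; shifts are rounded to integers.
#' @param seed integer seed; fixing it fixes every emitted voxel.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(n_slices = 10, n_frames = 150, frame_rate = 3.3,
                           grid = c(96, 96), voxel_size = c(3.3, 3.3, 12),
                           f_resp = 0.30, f_card = 1.25,
                           resp_amp_mean = 0.12, card_amp_mean = 0.03,
                           amp_cv = 0.25, defect_side = "none",
                           defect_fraction = 0, defect_attenuation = 0.4,
                           decouple_vq = FALSE, noise_sd = 0.02,
                           bulk_shift_amp = 0, seed = 1L) {
  n_slices <- assert_count(n_slices, "n_slices", min = 1L)
  n_frames <- assert_count(n_frames, "n_frames", min = 8L)
  assert_positive(frame_rate, "frame_rate")
  if (length(grid) != 2L || any(grid < 32))
    stop_config("grid", "needs at least 32 x 32 voxels to hold two lung ellipses")
  assert_positive(f_resp, "f_resp")
  assert_positive(f_card, "f_card")
  if (f_resp >= f_card) stop_config("f_resp", "must be below f_card")
  if (frame_rate <= 2 * f_card)
    stop_config("frame_rate", "must exceed 2 * f_card (sampling adequacy)")
  assert_fraction(resp_amp_mean, "resp_amp_mean")
  assert_fraction(card_amp_mean, "card_amp_mean")
  assert_fraction(amp_cv, "amp_cv")
  if (!defect_side %in% c("left", "right", "none"))
    stop_config("defect_side", "must be 'left', 'right' or 'none'")
  assert_fraction(defect_fraction, "defect_fraction")
  assert_fraction(defect_attenuation, "defect_attenuation")
  assert_fraction(noise_sd, "noise_sd")
  if (!is.numeric(bulk_shift_amp) || bulk_shift_amp < 0)
    stop_config("bulk_shift_amp", "must be a non-negative number of voxels")
  structure(list(n_slices = n_slices, n_frames = n_frames,
                 frame_rate = frame_rate, grid = as.integer(grid),
                 voxel_size = voxel_size, f_resp = f_resp, f_card = f_card,
                 resp_amp_mean = resp_amp_mean,
                 card_amp_mean = card_amp_mean, amp_cv = amp_cv,
                 defect_side = defect_side,
                 defect_fraction = defect_fraction,
                 defect_attenuation = defect_attenuation,
                 decouple_vq = isTRUE(decouple_vq), noise_sd = noise_sd,
                 bulk_shift_amp = bulk_shift_amp, seed = as.integer(seed)),
            class = "phantom_config")
}

in_ellipse <- function(nr, nc, cr, cc, rr, rc) {
  r <- matrix(seq_len(nr), nr, nc)
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ((r - cr) / rr)^2 + ((c - cc) / rc)^2 <= 1
}

# Two tapering lung ellipses with a cardiac notch in the left lung, a heart
# region between/over the lungs, and a surrounding body ellipse.
phantom_geometry <- function(nr, nc, ns) {
  labels <- array(0L, c(nr, nc, ns))
  body <- array(FALSE, c(nr, nc, ns))
  for (s in seq_len(ns)) {
    u <- (s - (ns + 1) / 2) / ((ns + 1) / 2)
    sc <- sqrt(1 - 0.65 * u^2)
    bd <- in_ellipse(nr, nc, nr / 2, nc / 2, 0.47 * nr, 0.44 * nc)
    right <- in_ellipse(nr, nc, 0.50 * nr, 0.31 * nc,
                        0.32 * nr * sc, 0.135 * nc * sc)
    left <- in_ellipse(nr, nc, 0.50 * nr, 0.69 * nc,
                       0.32 * nr * sc, 0.135 * nc * sc)
    heart <- in_ellipse(nr, nc, 0.60 * nr, 0.58 * nc,
                        0.16 * nr * sc, 0.12 * nc * sc)
    lab <- matrix(0L, nr, nc)
    lab[right & bd] <- 1L
    lab[left & bd] <- 2L
    lab[heart & bd] <- 3L  # carves the cardiac notch out of the left lung
    labels[, , s] <- lab
    body[, , s] <- bd
  }
  list(labels = labels, body = body)
}

# Smooth spatial random field over lung voxels with target mean and CV:
# per-slice Gaussian-blurred white noise, standardized over the lung and
# affinely rescaled; clipped at zero (amplitudes are non-negative).
smooth_amplitude_field <- function(lung, target_mean, cv, sigma = 4) {
  dm <- dim(lung)
  field <- array(0, dm)
  for (s in seq_len(dm[3])) {
    z <- matrix(rnorm(dm[1] * dm[2]), dm[1], dm[2])
    field[, , s] <- EBImage::gblur(z, sigma = sigma)
  }
  z <- field[lung]
  if (sd(z) == 0 || cv == 0) {
    a <- rep(target_mean, length(z))
  } else {
    a <- target_mean * (1 + cv * (z - mean(z)) / sd(z))
  }
  pmax(a, 0)
}

# Contiguous defect blob: the round(frac * n_side) lung voxels of the
# affected side nearest (in mm) to a randomly seeded voxel.
grow_defect <- function(side_idx, dims, voxel_size, frac) {
  n_take <- round(frac * length(side_idx))
  if (n_take == 0L) return(integer(0))
  coord <- arrayInd(side_idx, dims)
  seed_i <- sample.int(length(side_idx), 1L)
  d2 <- ((coord[, 1] - coord[seed_i, 1]) * voxel_size[1])^2 +
    ((coord[, 2] - coord[seed_i, 2]) * voxel_size[2])^2 +
    ((coord[, 3] - coord[seed_i, 3]) * voxel_size[3])^2
  side_idx[order(d2)[seq_len(n_take)]]
}

#' Generate a synthetic dynamic lung series
#'
#' Builds a multi-slice dynamic series in which every lung voxel `v`
#' carries the signal
#' `S_v(t) = S0 * (1 + a_v sin(2 pi f_resp t + phi) + b_v sin(2 pi f_card t + psi)) + noise`,
#' with per-voxel amplitudes `a_v`, `b_v` drawn from smooth spatial random
#' fields (mean `resp_amp_mean` / `card_amp_mean`, coefficient of variation
#' `amp_cv`), attenuated by `defect_attenuation` inside a planted contiguous
#' defect blob. A heart region outside the lung carries cardiac-only
#' modulation; surrounding body tissue is static; optional integer bulk
#' translation emulates residual respiratory motion. Output is
#' deterministic for a fixed seed.
#'
#' @param config a [phantom_config()].
#' @return list with elements `series` ([dynamic_series()]), `mask`
#'   ([lung_mask()]) and `truth` (ground truth: amplitude fields, defect
#'   masks, per-side planted defect fractions, frequencies, phases, planted
#'   per-frame shifts, baseline `S0`).
#' @export
generate_phantom_series <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(config$seed, {
    nr <- config$grid[1]; nc <- config$grid[2]
    ns <- config$n_slices; nt <- config$n_frames
    geo <- phantom_geometry(nr, nc, ns)
    labels <- geo$labels
    lung <- labels == 1L | labels == 2L
    heart <- labels == 3L
    lung_idx <- which(lung)

    a <- smooth_amplitude_field(lung, config$resp_amp_mean, config$amp_cv)
    b <- smooth_amplitude_field(lung, config$card_amp_mean, config$amp_cv)
    # phases are drawn before defect placement so a defect-free twin with
    # the same seed shares geometry, amplitude fields and phases
    phi <- runif(1, 0, 2 * pi)
    psi <- runif(1, 0, 2 * pi)

    defect_v <- integer(0); defect_q <- integer(0)
    if (config$defect_side != "none" && config$defect_fraction > 0) {
      side_lab <- if (config$defect_side == "left") 2L else 1L
      side_idx <- which(labels == side_lab)
      defect_v <- grow_defect(side_idx, dim(labels), config$voxel_size,
                              config$defect_fraction)
      defect_q <- if (config$decouple_vq)
        grow_defect(side_idx, dim(labels), config$voxel_size,
                    config$defect_fraction) else defect_v
      a[match(defect_v, lung_idx)] <- a[match(defect_v, lung_idx)] *
        config$defect_attenuation
      b[match(defect_q, lung_idx)] <- b[match(defect_q, lung_idx)] *
        config$defect_attenuation
    }

    s0 <- 100
    t <- (seq_len(nt) - 1) / config$frame_rate
    sin_resp <- sin(2 * pi * config$f_resp * t + phi)
    sin_card <- sin(2 * pi * config$f_card * t + psi)

    base <- array(0, c(nr, nc, ns))
    base[geo$body] <- 200
    base[heart] <- 180
    base[lung] <- s0
    heart_idx <- which(heart)

    shifts_true <- cbind(dy = as.integer(round(
      config$bulk_shift_amp * sin(2 * pi * config$f_resp * t))),
      dx = 0L)

    data <- array(0, c(nr, nc, ns, nt))
    nvox3 <- nr * nc * ns
    for (k in seq_len(nt)) {
      frame <- base
      frame[lung_idx] <- s0 * (1 + a * sin_resp[k] + b * sin_card[k])
      frame[heart_idx] <- 180 * (1 + 0.08 * sin_card[k])
      if (shifts_true[k, 1] != 0L || shifts_true[k, 2] != 0L) {
        for (s in seq_len(ns)) {
          frame[, , s] <- shift_matrix(frame[, , s], shifts_true[k, 1],
                                       shifts_true[k, 2], fill = "edge")
        }
      }
      if (config$noise_sd > 0)
        frame <- frame + rnorm(nvox3, sd = config$noise_sd * s0)
      data[, , , k] <- frame
    }

    defect_mask_v <- array(FALSE, dim(labels)); defect_mask_v[defect_v] <- TRUE
    defect_mask_q <- array(FALSE, dim(labels)); defect_mask_q[defect_q] <- TRUE
    frac_side <- function(dm) {
      c(right = sum(dm & labels == 1L) / max(1L, sum(labels == 1L)),
        left = sum(dm & labels == 2L) / max(1L, sum(labels == 2L)))
    }
    amp_field_a <- array(NA_real_, dim(labels)); amp_field_a[lung_idx] <- a
    amp_field_b <- array(NA_real_, dim(labels)); amp_field_b[lung_idx] <- b

    truth <- list(defect_mask_v = defect_mask_v,
                  defect_mask_q = defect_mask_q,
                  true_defect_fraction_by_side = list(
                    v = frac_side(defect_mask_v),
                    q = frac_side(defect_mask_q)),
                  f_resp = config$f_resp, f_card = config$f_card,
                  resp_amplitude = amp_field_a,
                  card_amplitude = amp_field_b,
                  phases = c(phi = phi, psi = psi),
                  shifts = shifts_true, s0 = s0)

    list(series = dynamic_series(data, config$frame_rate, config$voxel_size),
         mask = lung_mask(labels), truth = truth)
  })
}

#' Acquisition duration of a series
#'
#' Time from the first to the last frame, `(n_frames - 1) / frame_rate`,
#' in seconds.
#' @param series a [dynamic_series()].
#' @return seconds.
#' @export
series_duration <- function(series) {
  (dim(series$data)[4] - 1) / series$frame_rate
}
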
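as_lung_logical <- function(lung) {
  if (inherits(lung, "lung_mask")) lung_voxels(lung) else lung
}

check_defect_subset <- function(defect, lung) {
  if (!identical(dim(defect), dim(lung)))
    stop("defect and lung masks have different grids")
  if (any(defect & !lung))
    stop("defect mask contains voxels outside the lung mask")
}

#' Defect percentage
#'
#' Share of lung volume covered by a defect mask, across all slices:
#' `100 * |defect| / |lung|`.
#'
#' @param defect logical 3D defect mask (subset of the lung).
#' @param lung a [lung_mask()] or logical 3D lung selector.
#' @return percent of lung volume.
#' @export
defect_percentage <- function(defect, lung) {
  lung <- as_lung_logical(lung)
  if (!any(lung)) stop("empty lung mask")
  check_defect_subset(defect, lung)
  100 * sum(defect) / sum(lung)
}

#' Matched ventilation/perfusion defect percentage
#'
#' Share of lung volume defective in both ventilation and perfusion:
#' `100 * |v_defect AND q_defect| / |lung|`.
#'
#' @param v_defect,q_defect logical 3D defect masks.
#' @param lung a [lung_mask()] or logical 3D lung selector.
#' @return percent of lung volume.
#' @export
matched_defect_percentage <- function(v_defect, q_defect, lung) {
  lung <- as_lung_logical(lung)
  if (!any(lung)) stop("empty lung mask")
  check_defect_subset(v_defect, lung)
  check_defect_subset(q_defect, lung)
  100 * sum(v_defect & q_defect) / sum(lung)
}

side_names <- function(hernia_side) {
  if (hernia_side %in% c("left", "right")) c("affected", "non_affected")
  else c("left", "right")
}

side_labels_for <- function(hernia_side) {
  # label codes (1 = right, 2 = left) in the order of side_names()
  switch(hernia_side,
         left = c(2L, 1L),
         right = c(1L, 2L),
         c(2L, 1L))  # no hernia: report left, then right
}

#' Side-specific defect percentages
#'
#' Allocates defect voxels to the right or left lung and relates each
#' side's count to the voxel count of the whole lung, so the two side
#' values sum exactly to the whole-lung defect percentage. Sides are
#' relabelled affected/non-affected from the hernia side; with
#' `hernia_side = "none"` the sides are reported as left/right.
#'
#' @param defect logical 3D defect mask.
#' @param mask a side-labelled [lung_mask()] with both lung labels present.
#' @param hernia_side `"left"`, `"right"` or `"none"`.
#' @return named numeric vector of two percentages (whole-lung
#'   denominator).
#' @export
side_specific_percentages <- function(defect, mask, hernia_side = "none") {
  stopifnot(inherits(mask, "lung_mask"))
  if (!any(mask$labels == 1L) || !any(mask$labels == 2L))
    stop("mask must label both lung sides")
  lung <- lung_voxels(mask)
  check_defect_subset(defect, lung)
  n_lung <- sum(lung)
  labs <- side_labels_for(hernia_side)
  out <- vapply(labs, function(l) 100 * sum(defect & mask$labels == l) / n_lung,
                numeric(1))
  setNames(out, side_names(hernia_side))
}

disc_neighbour_count <- function(radius) {
  r <- floor(radius)
  n <- 0L
  for (dx in -r:r) n <- n + sum((dx^2 + (-r:r)^2) <= radius^2)
  n - 1L  # exclude the centre voxel
}

ddi_slice <- function(coords, radius, comp_size) {
  n <- nrow(coords)
  d2 <- as.matrix(dist(coords))^2
  neigh <- rowSums(d2 > 0 & d2 <= radius^2)
  rho <- neigh / disc_neighbour_count(radius)
  mean(rho * sqrt(comp_size))
}

#' Defect distribution index
#'
#' Clustering measure of a defect mask: for each in-plane defect voxel
#' `i`, the local defect density `rho_i` is the fraction of the radius-`R`
#' Euclidean disc (centre excluded) occupied by other defect voxels, and
#' `c_i` is the size of `i`'s 8-connected component on that slice. The
#' per-slice index is the mean of `rho_i * sqrt(c_i)`; the overall index
#' is the defect-count-weighted mean over slices. Zero when there are no
#' defect voxels; higher when defects are dense and aggregated.
#'
#' @param defect logical 3D defect mask.
#' @param lung a [lung_mask()] or logical 3D lung selector.
#' @param radius neighbourhood radius in voxels (default 3).
#' @return non-negative index (arbitrary units).
#' @export
defect_distribution_index <- function(defect, lung, radius = 3) {
  if (!is.numeric(radius) || radius <= 0) stop("radius must be positive")
  lung <- as_lung_logical(lung)
  check_defect_subset(defect, lung)
  ns <- dim(defect)[3]
  scores <- numeric(0); weights <- numeric(0)
  for (s in seq_len(ns)) {
    dm <- defect[, , s]
    n_def <- sum(dm)
    if (n_def == 0L) next
    lab <- label_components(dm)
    sizes <- tabulate(lab[lab > 0L])
    coords <- arrayInd(which(dm), dim(dm))
    comp_size <- sizes[lab[dm]]
    scores <- c(scores, ddi_slice(coords, radius, comp_size))
    weights <- c(weights, n_def)
  }
  if (length(scores) == 0L) return(0)
  sum(scores * weights) / sum(weights)
}

restrict_side <- function(x, mask, side_label) {
  x & (mask$labels == side_label)
}

#' Per-subject defect metrics
#'
#' Aggregates the defect burden of one subject: whole-lung VDP, QDP and
#' matched V/Q defect percentage; side-specific VDP/QDP with the
#' whole-lung denominator (so sides sum exactly to the whole-lung value);
#' side-specific matched defects and defect distribution indices with the
#' side's own voxels as reference region; and whole-lung defect
#' distribution indices.
#'
#' @param v_defect,q_defect logical 3D defect masks (from [defect_mask()]).
#' @param mask a side-labelled [lung_mask()].
#' @param hernia_side `"left"`, `"right"` or `"none"`.
#' @param ddi_radius neighbourhood radius for
#'   [defect_distribution_index()].
#' @return object of class `defect_metrics`: list of metrics and backing
#'   voxel counts.
#' @export
compute_defect_metrics <- function(v_defect, q_defect, mask,
                                   hernia_side = "none", ddi_radius = 3) {
  stopifnot(inherits(mask, "lung_mask"))
  lung <- lung_voxels(mask)
  nm <- side_names(hernia_side)
  labs <- side_labels_for(hernia_side)

  per_side <- function(f) {
    setNames(vapply(labs, f, numeric(1)), nm)
  }

  vqd_side <- per_side(function(l) {
    side_sel <- mask$labels == l
    100 * sum(v_defect & q_defect & side_sel) / sum(side_sel)
  })
  ddi_v_side <- per_side(function(l)
    defect_distribution_index(restrict_side(v_defect, mask, l),
                              mask$labels == l, ddi_radius))
  ddi_q_side <- per_side(function(l)
    defect_distribution_index(restrict_side(q_defect, mask, l),
                              mask$labels == l, ddi_radius))

  structure(list(
    vdp = defect_percentage(v_defect, mask),
    qdp = defect_percentage(q_defect, mask),
    vqd_match = matched_defect_percentage(v_defect, q_defect, mask),
    vdp_side = side_specific_percentages(v_defect, mask, hernia_side),
    qdp_side = side_specific_percentages(q_defect, mask, hernia_side),
    vqd_side = vqd_side,
    ddi_v = defect_distribution_index(v_defect, mask, ddi_radius),
    ddi_q = defect_distribution_index(q_defect, mask, ddi_radius),
    ddi_v_side = ddi_v_side,
    ddi_q_side = ddi_q_side,
    counts = list(lung = sum(lung),
                  lung_right = sum(mask$labels == 1L),
                  lung_left = sum(mask$labels == 2L),
                  v_defect = sum(v_defect), q_defect = sum(q_defect),
                  vq_match = sum(v_defect & q_defect)),
    hernia_side = hernia_side, ddi_radius = ddi_radius),
    class = "defect_metrics")
}

#' @export
print.defect_metrics <- function(x, ...) {
  cat(sprintf("VDP %.2f%%  QDP %.2f%%  VQD_match %.2f%%\n",
              x$vdp, x$qdp, x$vqd_match))
  cat(sprintf("DDI_V %.3f  DDI_Q %.3f (radius %g)\n",
              x$ddi_v, x$ddi_q, x$ddi_radius))
  nm <- names(x$vdp_side)
  cat(sprintf("VDP by side: %s %.2f%%, %s %.2f%% (whole-lung denominator)\n",
              nm[1], x$vdp_side[1], nm[2], x$vdp_side[2]))
  invisible(x)
}
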
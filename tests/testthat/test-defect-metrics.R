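mask_of <- function(dim3, idx, value = 1L) {
  m <- array(0L, dim3)
  m[idx] <- value
  m
}

test_that("defect percentage is the defect share of lung volume", {
  labels <- mask_of(c(2, 5, 1), 1:10)  # 10 lung voxels, all right lung
  lung <- lung_mask(labels)
  defect <- array(FALSE, c(2, 5, 1)); defect[1] <- TRUE
  expect_equal(defect_percentage(defect, lung), 10)
  expect_equal(defect_percentage(array(FALSE, c(2, 5, 1)), lung), 0)
  expect_error(defect_percentage(defect, lung_mask(array(0L, c(2, 5, 1)))),
               "empty")
  outside <- array(FALSE, c(2, 5, 1))
  expect_error(defect_percentage(!outside, lung_mask(mask_of(c(2, 5, 1), 1:5))),
               "outside")
})

test_that("matched defects follow set intersection and binomial expectation", {
  labels <- mask_of(c(50, 100, 1), 1:5000)
  lung <- lung_mask(labels)
  v <- array(FALSE, c(50, 100, 1)); v[1:600] <- TRUE
  q <- array(FALSE, c(50, 100, 1)); q[601:1200] <- TRUE
  expect_equal(matched_defect_percentage(v, q, lung), 0)
  expect_equal(matched_defect_percentage(v, v, lung), 12)

  set.seed(10)
  v[] <- FALSE; q[] <- FALSE
  v[1:5000] <- runif(5000) < 0.3
  q[1:5000] <- runif(5000) < 0.3
  est <- matched_defect_percentage(v, q, lung)
  se <- 100 * sqrt(0.09 * (1 - 0.09) / 5000)
  expect_lt(abs(est - 9), 3 * se)
})

test_that("side percentages use the whole-lung denominator and sum exactly", {
  labels <- array(0L, c(10, 10, 1))
  labels[, 1:5, 1] <- 1L   # 50 right voxels
  labels[, 6:10, 1] <- 2L  # 50 left voxels
  lung <- lung_mask(labels)
  defect <- array(FALSE, c(10, 10, 1))
  defect[1:5, 6, 1] <- TRUE  # 5 defect voxels, all left
  sp <- side_specific_percentages(defect, lung, hernia_side = "left")
  expect_equal(unname(sp["affected"]), 5)
  expect_equal(unname(sp["non_affected"]), 0)
  expect_equal(sum(sp), defect_percentage(defect, lung))

  # additivity holds exactly for arbitrary masks
  set.seed(3)
  for (i in 1:5) {
    d <- array(runif(100) < 0.4, c(10, 10, 1)) & lung_voxels(lung)
    sp <- side_specific_percentages(d, lung, "right")
    expect_equal(sum(sp), defect_percentage(d, lung), tolerance = 1e-13)
  }
  one_side <- lung_mask(mask_of(c(10, 10, 1), 1:20))
  expect_error(side_specific_percentages(defect, one_side, "left"),
               "both lung sides")
})

test_that("matched defects never exceed either single-modality burden", {
  set.seed(4)
  labels <- array(0L, c(12, 12, 3))
  labels[3:10, 2:6, ] <- 1L; labels[3:10, 7:11, ] <- 2L
  lung <- lung_mask(labels)
  for (i in 1:10) {
    v <- array(runif(length(labels)) < 0.3, dim(labels)) & lung_voxels(lung)
    q <- array(runif(length(labels)) < 0.3, dim(labels)) & lung_voxels(lung)
    expect_lte(matched_defect_percentage(v, q, lung),
               min(defect_percentage(v, lung), defect_percentage(q, lung)))
  }
})

square_defect <- function(dim3, r0, c0, h, w, slice = 1) {
  d <- array(FALSE, dim3)
  d[r0:(r0 + h - 1), c0:(c0 + w - 1), slice] <- TRUE
  d
}

test_that("DDI is zero without defects or with only isolated voxels", {
  dim3 <- c(30, 30, 1)
  lung <- array(TRUE, dim3)
  expect_equal(defect_distribution_index(array(FALSE, dim3), lung), 0)
  scattered <- array(FALSE, dim3)
  scattered[cbind(seq(1, 29, by = 7), seq(1, 29, by = 7), 1)] <- TRUE
  expect_equal(defect_distribution_index(scattered, lung), 0)
})

test_that("DDI ranks aggregated defects above scattered ones", {
  dim3 <- c(40, 40, 1)
  lung <- array(TRUE, dim3)
  solid <- square_defect(dim3, 10, 10, 5, 5)
  scattered <- array(FALSE, dim3)
  scattered[cbind(rep(seq(2, 38, by = 8), 5),
                  rep(seq(2, 38, by = 8), each = 5), 1)] <- TRUE
  expect_equal(sum(solid), sum(scattered))
  expect_gt(defect_distribution_index(solid, lung),
            defect_distribution_index(scattered, lung))
})

test_that("merging separated clusters into one blob never decreases DDI", {
  dim3 <- c(40, 40, 1)
  lung <- array(TRUE, dim3)
  set.seed(9)
  for (i in 1:10) {
    h <- sample(2:4, 1); w <- sample(2:4, 1)
    two <- square_defect(dim3, 5, 5, h, w) |
      square_defect(dim3, 25, 25, h, w)
    merged <- square_defect(dim3, 15, 15, h, 2 * w)
    expect_gte(defect_distribution_index(merged, lung),
               defect_distribution_index(two, lung))
  }
})

test_that("metrics are invariant under slice reordering and joint translation", {
  ph <- generate_phantom_series(small_phantom_config(seed = 12,
                                                     defect_side = "right",
                                                     defect_fraction = 0.15))
  m <- ph$mask; d <- ph$truth$defect_mask_v
  base <- compute_defect_metrics(d, d, m, "right")
  perm <- sample(dim(d)[3])
  m2 <- lung_mask(m$labels[, , perm]); d2 <- d[, , perm]
  reord <- compute_defect_metrics(d2, d2, m2, "right")
  expect_equal(reord$vdp, base$vdp)
  expect_equal(reord$ddi_v, base$ddi_v)

  shift3 <- function(x) {
    out <- array(0L, dim(x) + c(2, 2, 0))
    out[3:(dim(x)[1] + 2), 3:(dim(x)[2] + 2), ] <- x
    out
  }
  m3 <- lung_mask(shift3(m$labels)); d3 <- shift3(d) > 0
  trans <- compute_defect_metrics(d3, d3, m3, "right")
  expect_equal(trans$vdp, base$vdp)
  expect_equal(trans$ddi_v, base$ddi_v)
  expect_equal(trans$vqd_side, base$vqd_side)
})

test_that("per-side VQD and DDI use the side's own reference region", {
  labels <- array(0L, c(10, 10, 1))
  labels[, 1:4, 1] <- 1L   # 40 right voxels
  labels[, 5:10, 1] <- 2L  # 60 left voxels
  d <- array(FALSE, c(10, 10, 1))
  d[1:3, 5:6, 1] <- TRUE   # 6 defect voxels on the left
  met <- compute_defect_metrics(d, d, lung_mask(labels), "left")
  expect_equal(unname(met$vqd_side["affected"]), 100 * 6 / 60)
  expect_equal(unname(met$vqd_side["non_affected"]), 0)
  expect_equal(unname(met$vdp_side["affected"]), 100 * 6 / 100)
  expect_equal(met$ddi_q_side[["non_affected"]], 0)
  expect_gt(met$ddi_q_side[["affected"]], 0)
})
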
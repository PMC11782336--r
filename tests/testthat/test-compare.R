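# Cross-modality regional comparison: slab matching, coregistration,
# spatial overlap, Dice and the agreement overlay.

col_map <- function(labels, dz = 1) {
  defect_map(array(labels, c(1, 1, length(labels))), "RVent", c(1, 1, dz))
}

test_that("slab votes follow unanimity and majority", {
  # slab of 4 thin slices, all defect -> defect
  a <- resample_to_slabs(col_map(rep(2L, 4)), target_thickness_mm = 4)
  expect_identical(as.vector(a$labels), 2L)
  # 1 defect of 4 -> mean 0.25 < 0.5 -> healthy
  b <- resample_to_slabs(col_map(c(2L, 1L, 1L, 1L)), target_thickness_mm = 4)
  expect_identical(as.vector(b$labels), 1L)
})

test_that("non-integer slab coverage matches the exhaustive weight oracle", {
  dz <- 3.9; slab <- 15
  nz <- 24
  labels <- rep(c(2L, 1L), length.out = nz)  # alternating defect pattern
  got <- resample_to_slabs(col_map(labels, dz), target_thickness_mm = slab)
  # brute-force overlap weights
  n_slab <- ceiling(nz * dz / slab)
  oracle <- integer(n_slab)
  for (k in seq_len(n_slab)) {
    w <- numeric(nz)
    for (j in seq_len(nz)) {
      w[j] <- max(0, min(j * dz, k * slab) - max((j - 1) * dz, (k - 1) * slab))
    }
    oracle[k] <- if (sum(w * (labels == 2L)) / sum(w) >= 0.5) 2L else 1L
  }
  expect_identical(as.vector(got$labels), oracle)
})

test_that("mixed in/out columns use the weighted in-mask majority", {
  labels <- c(0L, 0L, 0L, 2L, 2L, 2L, 2L, 2L)
  got <- resample_to_slabs(col_map(labels), target_thickness_mm = 4)
  # slab 1: 3 of 4 slices outside -> outside; slab 2: all defect
  expect_identical(as.vector(got$labels), c(0L, 2L))
  # mostly-excluded slab becomes excluded
  lab2 <- c(3L, 3L, 3L, 1L, 1L, 1L, 1L, 1L)
  got2 <- resample_to_slabs(col_map(lab2), target_thickness_mm = 4)
  expect_identical(as.vector(got2$labels), c(3L, 1L))
})

test_that("coregistration is the identity on identical grids", {
  set.seed(5)
  lab <- array(sample(0:3, 4 * 4 * 6, replace = TRUE), c(4, 4, 6))
  m <- defect_map(lab, "Combined", c(3.9, 3.9, 15))
  fixed <- image_volume(array(0, c(4, 4, 6)), c(3.9, 3.9, 15))
  out <- coregister(m, fixed)
  expect_identical(out$labels, m$labels)
})

test_that("a whole-voxel affine offset shifts labels by one voxel", {
  lab <- array(0L, c(3, 3, 6))
  lab[2, 2, 3] <- 2L
  aff <- default_affine(c(1, 1, 1))
  aff[3, 4] <- -1  # moving volume sits one voxel lower in world space
  m <- defect_map(lab, "Xe", c(1, 1, 1), affine = aff)
  fixed <- image_volume(array(0, c(3, 3, 6)), c(1, 1, 1))
  out <- coregister(m, fixed)
  expect_identical(out$labels[2, 2, 2], 2L)
  expect_identical(sum(out$labels == 2L), 1L)
})

test_that("phantom defect maps coregister onto the gas grid cleanly", {
  cfg <- tiny_config(defect_fraction = 0.2, snr = Inf, seed = 41)
  sim <- cached_phantom(cfg)
  g <- generate_gas_image(sim$truth, cfg)
  slab <- resample_to_slabs(truth_defect_map(sim$truth),
                            target_thickness_mm = cfg$gas_slab_thickness_mm)
  reg <- coregister(slab, g$gas)
  overlap <- sum(reg$mask & g$slab_lung_mask) /
    max(sum(reg$mask), sum(g$slab_lung_mask))
  expect_gte(overlap, 0.99)
})

test_that("spatial overlap matches hand counts", {
  a <- col_map(c(2L, 2L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L))
  b <- col_map(c(2L, 1L, 2L, 1L, 1L, 1L, 1L, 1L, 1L, 1L))
  expect_equal(spatial_overlap(a, b), 80)
  expect_equal(spatial_overlap(a, a), 100)
  flip <- col_map(ifelse(as.vector(a$labels) == 2L, 1L, 2L))
  expect_equal(spatial_overlap(a, flip), 0)
})

test_that("Dice follows its set formula with empty-set conventions", {
  a <- col_map(c(2L, 2L, 2L, 1L, 1L, 1L))
  b <- col_map(c(2L, 1L, 1L, 2L, 1L, 1L))
  expect_equal(dice(a, b, "defect"), 0.4)  # |A|=3, |B|=2, intersection 1
  expect_equal(dice(a, a, "defect"), 1)
  expect_equal(dice(a, a, "healthy"), 1)
  disjoint <- col_map(c(1L, 1L, 1L, 2L, 2L, 1L))
  aa <- col_map(c(2L, 2L, 1L, 1L, 1L, 1L))
  expect_equal(dice(aa, disjoint, "defect"), 0)
  none <- col_map(rep(1L, 6))
  expect_equal(dice(none, none, "defect"), 1)  # both empty
  expect_equal(dice(aa, none, "defect"), 0)    # one empty
})

test_that("agreement overlay is consistent with the standalone metrics", {
  set.seed(17)
  for (i in 1:10) {
    la <- array(sample(0:3, 80, replace = TRUE, prob = c(2, 5, 3, 1)),
                c(80, 1, 1))
    lb <- array(sample(0:3, 80, replace = TRUE, prob = c(2, 5, 3, 1)),
                c(80, 1, 1))
    a <- defect_map(la, "Combined", c(1, 1, 1))
    b <- defect_map(lb, "Xe", c(1, 1, 1))
    ag <- agreement_overlay(a, b)
    expect_equal(ag$spatial_overlap_pct, spatial_overlap(a, b))
    expect_equal(ag$dice_defect, dice(a, b, "defect"))
    expect_equal(ag$dice_healthy, dice(a, b, "healthy"))
    expect_equal(sum(ag$category_counts), ag$n_evaluable)
    # symmetry
    expect_equal(spatial_overlap(b, a), ag$spatial_overlap_pct)
    expect_equal(dice(b, a, "defect"), ag$dice_defect)
    # decomposition: disagreement complements the overlap
    expect_equal(ag$spatial_overlap_pct,
                 100 - 100 * (ag$category_counts[["a_only_defect"]] +
                              ag$category_counts[["b_only_defect"]]) /
                   ag$n_evaluable)
  }
})

test_that("identical maps yield a pure agreement overlay", {
  a <- col_map(c(2L, 2L, 1L, 1L, 3L, 0L))
  ag <- agreement_overlay(a, a)
  expect_identical(unname(ag$category_counts[c("a_only_defect",
                                               "b_only_defect")]), c(0, 0))
  expect_equal(ag$spatial_overlap_pct, 100)
})

test_that("maps with no shared evaluable voxels are rejected", {
  a <- col_map(c(3L, 3L, 0L))
  b <- col_map(c(1L, 2L, 0L))
  expect_error(spatial_overlap(a, a),
               class = "lungvent_empty_evaluation_error")
  expect_error(agreement_overlay(a, a),
               class = "lungvent_empty_evaluation_error")
})
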
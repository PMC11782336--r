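# Phase-resolved proton ventilation mapping: respiratory signal, phase
# sorting, RVent, flow-volume loops, FVL-CM and defect thresholding.

# A minimal synthetic series: uniform cube "lung" whose signal follows the
# density-inflation model with a global sinusoidal drive.
toy_series <- function(n_frames = 48, period = 4, dt = 0.25, amp = 0.3,
                       value = 0.4) {
  d <- c(4, 4, 4)
  times <- (seq_len(n_frames) - 1) * dt
  e <- amp * (1 - cos(2 * pi * times / period)) / 2
  data <- array(0, c(d, n_frames))
  for (f in seq_len(n_frames)) data[, , , f] <- value / (1 + e[f])
  dynamic_series(data, c(1, 1, 1), times, array(TRUE, d))
}

test_that("respiratory signal is offset-invariant and tracks inflation", {
  s <- toy_series()
  sig <- estimate_respiratory_signal(s)
  expect_equal(range(sig), c(0, 1))
  s2 <- s
  s2$data <- s$data + 5
  expect_equal(estimate_respiratory_signal(s2), sig)
  # peaks coincide with the phantom's true inflation peaks
  cfg <- tiny_config(defect_fraction = 0, snr = Inf, seed = 6)
  sim <- cached_phantom(cfg)
  est <- estimate_respiratory_signal(sim$series)
  expect_identical(which(est == 1), which(sim$truth$respiratory_signal == 1))
})

test_that("constant series yields a flat signal that phase sorting refuses", {
  d <- c(3, 3, 3)
  s <- dynamic_series(array(1, c(d, 10)), c(1, 1, 1), 0:9, array(TRUE, d))
  sig <- estimate_respiratory_signal(s)
  expect_true(all(sig == 0))
  expect_error(sort_to_phases(s, sig, 8),
               class = "lungvent_degenerate_signal_error")
})

test_that("empty lung mask is rejected", {
  d <- c(3, 3, 3)
  s <- dynamic_series(array(1, c(d, 10)), c(1, 1, 1), 0:9, array(FALSE, d))
  expect_error(estimate_respiratory_signal(s),
               class = "lungvent_empty_mask_error")
})

test_that("uniform sampling fills every phase bin equally", {
  # 3 cycles of 16 frames, 8 bins: the assignment rule puts exactly 6
  # frames in each bin (counting oracle over the trough-anchored rule)
  s <- toy_series(n_frames = 48)
  sig <- estimate_respiratory_signal(s)
  ph <- sort_to_phases(s, sig, 8)
  expect_identical(ph$occupancy, rep(6L, 8))
})

test_that("a single phase bin reproduces the temporal mean image", {
  s <- toy_series(n_frames = 48)
  sig <- estimate_respiratory_signal(s)
  ph <- sort_to_phases(s, sig, 1)
  expect_equal(ph$data[, , , 1],
               array(rowMeans(matrix(s$data, ncol = 48)), dim = c(4, 4, 4)))
})

test_that("fewer than one full cycle raises an insufficient-data error", {
  s <- toy_series(n_frames = 48)
  short <- dynamic_series(s$data[, , , 1:10, drop = FALSE], s$spacing,
                          s$frame_times[1:10], s$lung_mask)
  sig <- estimate_respiratory_signal(short)
  expect_error(sort_to_phases(short, sig, 8),
               class = "lungvent_insufficient_data_error")
})

test_that("healthy phantom phase signal is monotone from expiration to inspiration", {
  cfg <- tiny_config(defect_fraction = 0, snr = Inf, seed = 6)
  sim <- cached_phantom(cfg)
  sig <- estimate_respiratory_signal(sim$series)
  ph <- sort_to_phases(sim$series, sig, 8)
  means <- vapply(1:8, function(b) mean(ph$data[, , , b][ph$lung_mask]),
                  numeric(1))
  pE <- which.max(means); pI <- which.min(means)
  idx <- which(ph$lung_mask)[seq(1, sum(ph$lung_mask), by = 7)]
  m <- matrix(ph$data, ncol = 8)[idx, ]
  path <- ((pE - 1):(pE + 8 - 1)) %% 8 + 1
  path <- path[1:which(path == pI)[1]]
  diffs <- t(apply(m[, path], 1, diff))
  expect_true(all(diffs <= 1e-9))
})

test_that("RVent follows its defining ratio on a hand-built phase series", {
  d <- c(2, 2, 1)
  pd <- array(1, c(d, 4))
  pd[, , , 3] <- 0.8  # end-inspiration
  ph <- phase_series(pd, (0:3) / 4 + 0.01, array(TRUE, d))
  rv <- compute_rvent(ph, smooth_kernel = 1)
  expect_equal(unique(as.vector(rv$rvent)), 0.2)
  # constant series: zero ventilation everywhere, no error
  ph0 <- phase_series(array(1, c(d, 4)), (0:3) / 4 + 0.01, array(TRUE, d))
  rv0 <- compute_rvent(ph0, smooth_kernel = 1)
  expect_true(all(rv0$rvent == 0))
})

test_that("phantom RVent matches the closed form a / (1 + a)", {
  cfg <- tiny_config(defect_fraction = 0, snr = Inf, seed = 6)
  sim <- cached_phantom(cfg)
  sig <- estimate_respiratory_signal(sim$series)
  ph <- sort_to_phases(sim$series, sig, 8)
  rv <- compute_rvent(ph)
  a <- cfg$tidal_amplitude
  vals <- rv$rvent[sim$truth$lung_mask]
  expect_lt(max(abs(vals - a / (1 + a))) / (a / (1 + a)), 0.1)
})

test_that("flow is the cyclic central difference of volume", {
  d <- c(2, 1, 1)
  np <- 8
  pgrid <- (seq_len(np) - 0.5) / np
  v1 <- sin(2 * pi * (0:(np - 1)) / np)
  pd <- array(0, c(d, np))
  sE <- 1
  # craft signals so voxel 1 gets V = v1 and voxel 2 a constant V
  for (p in seq_len(np)) {
    pd[1, 1, 1, p] <- sE * (1 - v1[p])
    pd[2, 1, 1, p] <- sE * (1 - 0.4)
  }
  ph <- phase_series(pd, pgrid, array(TRUE, d))
  loops <- compute_fvl(ph)
  v_row <- loops$volume[which(loops$voxels == 1), ]
  f_row <- loops$flow[which(loops$voxels == 1), ]
  # hand-computed cyclic central differences
  oracle <- numeric(np)
  for (p in seq_len(np)) {
    nxt <- if (p == np) 1 else p + 1
    prv <- if (p == 1) np else p - 1
    oracle[p] <- (v_row[nxt] - v_row[prv]) / (2 / np)
  }
  expect_equal(f_row, oracle)
  # derivative of a constant volume is zero
  expect_true(all(loops$flow[which(loops$voxels == 2), ] == 0))
  # cyclic sum of F * dphi telescopes to zero for every voxel
  expect_equal(max(abs(rowSums(loops$flow) / np)), 0)
})

test_that("reference loop reduces to the shared loop of identical voxels", {
  d <- c(4, 4, 2)
  np <- 8
  v <- 0.2 * (1 - cos(2 * pi * (0:(np - 1)) / np)) / 2
  pd <- array(rep(1 - v, each = prod(d)), c(d, np))
  ph <- phase_series(pd, (seq_len(np) - 0.5) / np, array(TRUE, d))
  loops <- compute_fvl(ph)
  rv <- compute_rvent(ph, smooth_kernel = 1)
  ref <- build_reference_loop(loops, rv$rvent)
  expect_equal(ref$volume, loops$volume[1, ])
  expect_equal(ref$flow, loops$flow[1, ])
})

test_that("reference loop ignores the poorly ventilated half", {
  d <- c(4, 4, 2)
  np <- 8
  v <- 0.25 * (1 - cos(2 * pi * (0:(np - 1)) / np)) / 2
  pd <- array(1, c(d, np))
  idx <- which(array(TRUE, d))
  moving <- idx[seq_len(length(idx) / 2)]
  flat <- setdiff(idx, moving)
  for (p in seq_len(np)) {
    vol <- array(1, d)
    vol[moving] <- 1 - v[p]
    pd[, , , p] <- vol
  }
  ph <- phase_series(pd, (seq_len(np) - 0.5) / np, array(TRUE, d))
  loops <- compute_fvl(ph)
  rv <- compute_rvent(ph, smooth_kernel = 1)
  ref <- build_reference_loop(loops, rv$rvent)
  expect_equal(ref$volume, loops$volume[which(loops$voxels == moving[1]), ])
  # too few voxels above the median errors out
  expect_error(build_reference_loop(loops, rv$rvent, min_voxels = 1000),
               class = "lungvent_reference_error")
})

test_that("FVL-CM is 1 for self and scaled loops, 0 in quadrature", {
  np <- 16
  p <- (0:(np - 1)) / np
  vref <- sin(2 * pi * p)
  fref <- cos(2 * pi * p)
  ref <- flow_volume_loop(vref, fref, p + 1e-3)
  mk_loops <- function(vmat, fmat) {
    list(volume = vmat, flow = fmat, voxels = seq_len(nrow(vmat)),
         excluded = rep(FALSE, nrow(vmat)), phase_grid = p + 1e-3, pE = 1)
  }
  loops <- mk_loops(rbind(vref, 0.5 * vref, sin(2 * pi * (p - 0.25)), rep(0.3, np)),
                    rbind(fref, 0.5 * fref, cos(2 * pi * (p - 0.25)), rep(0, np)))
  r <- compute_fvlcm(loops, ref, c(4, 1, 1))
  expect_equal(r[1, 1, 1], 1)
  expect_equal(r[2, 1, 1], 1)            # amplitude-invariant
  expect_lt(abs(r[3, 1, 1]), 1e-10)      # quarter-cycle delay: orthogonal
  expect_identical(r[4, 1, 1], 0)        # zero-variance loop
  bad_ref <- flow_volume_loop(vref[1:8], fref[1:8], p[1:8])
  expect_error(compute_fvlcm(loops, bad_ref, c(4, 1, 1)),
               class = "lungvent_shape_error")
})

test_that("RVent threshold matches the sort-and-count oracle", {
  vals <- (1:100) / 100
  rv <- array(vals, c(100, 1, 1))
  mask <- array(TRUE, c(100, 1, 1))
  dm <- threshold_rvent(rv, mask)
  thr <- 0.4 * oracle_percentile(vals, 0.9)
  expect_equal(attr(dm, "threshold"), thr)
  expect_identical(sum(dm$labels == 2L), sum(vals < thr))
  # homogeneous lung: nothing below 0.4 * v
  dm2 <- threshold_rvent(array(0.5, c(10, 1, 1)), array(TRUE, c(10, 1, 1)))
  expect_equal(compute_vdp(dm2), 0)
  # all-zero map: strict inequality keeps VDP at zero
  dm3 <- threshold_rvent(array(0, c(10, 1, 1)), array(TRUE, c(10, 1, 1)))
  expect_equal(compute_vdp(dm3), 0)
  expect_error(threshold_rvent(rv, array(FALSE, c(100, 1, 1))),
               class = "lungvent_empty_mask_error")
})

test_that("FVL-CM threshold uses a strict less-than at 0.9", {
  vals <- array(c(0.95, 0.9, 0.89, 1), c(4, 1, 1))
  mask <- array(TRUE, c(4, 1, 1))
  dm <- threshold_fvlcm(vals, mask)
  expect_identical(as.vector(dm$labels), c(1L, 1L, 2L, 1L))
  expect_equal(compute_vdp(threshold_fvlcm(array(1, c(4, 1, 1)), mask)), 0)
  expect_error(threshold_fvlcm(array(1.5, c(4, 1, 1)), mask),
               class = "lungvent_value_error")
})

test_that("defect maps combine by logical OR with excluded pass-through", {
  mk <- function(v, src) defect_map(array(v, c(4, 1, 1)), src, c(1, 1, 1))
  a <- mk(c(2L, 1L, 3L, 1L), "RVent")
  b <- mk(c(1L, 1L, 1L, 2L), "FVL-CM")
  cmb <- combine_defect_maps(a, b)
  expect_identical(as.vector(cmb$labels), c(2L, 1L, 3L, 2L))
  expect_identical(cmb$source, "Combined")
  small <- defect_map(array(c(1L, 1L), c(2, 1, 1)), "FVL-CM", c(1, 1, 1))
  expect_error(combine_defect_maps(a, small),
               class = "lungvent_shape_error")
})

test_that("combined VDP dominates both inputs on random maps", {
  set.seed(99)
  for (i in 1:20) {
    la <- array(sample(c(1L, 2L, 3L), 60, replace = TRUE, prob = c(6, 3, 1)),
                c(60, 1, 1))
    lb <- array(sample(c(1L, 2L, 3L), 60, replace = TRUE, prob = c(6, 3, 1)),
                c(60, 1, 1))
    a <- defect_map(la, "RVent", c(1, 1, 1))
    b <- defect_map(lb, "FVL-CM", c(1, 1, 1))
    cmb <- combine_defect_maps(a, b)
    expect_gte(compute_vdp(cmb) + 1e-9,
               max(compute_vdp(a), compute_vdp(b)))
  }
})

test_that("VDP is the defect share of evaluable voxels", {
  lab <- array(1L, c(100, 1, 1))
  lab[1:20] <- 2L
  lab[91:100] <- 3L  # excluded: out of both numerator and denominator
  dm <- defect_map(lab, "RVent", c(1, 1, 1))
  expect_equal(compute_vdp(dm), 100 * 20 / 90)
  all_excl <- defect_map(array(3L, c(5, 1, 1)), "RVent", c(1, 1, 1))
  expect_error(compute_vdp(all_excl),
               class = "lungvent_empty_denominator_error")
})

test_that("global intensity scaling changes no proton defect label", {
  cfg <- tiny_config(defect_fraction = 0.25, defect_mode = "mixed",
                     snr = 40, seed = 21)
  sim <- cached_phantom(cfg)
  pf1 <- preful_analysis(sim$series)
  s2 <- sim$series
  s2$data <- s2$data * 2
  pf2 <- preful_analysis(s2)
  expect_identical(pf1$defects$combined$labels, pf2$defects$combined$labels)
})
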
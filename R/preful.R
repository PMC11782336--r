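# Phase-resolved ventilation mapping from a free-breathing proton series:
# respiratory-signal estimation, axial registration, phase sorting, the
# static RVent map, per-voxel flow-volume loops and their correlation
# against a healthy reference loop (FVL-CM), defect thresholding and VDP.

#' Estimate a respiratory surrogate signal from a dynamic series
#'
#' The mean in-mask parenchymal intensity per frame, sign-flipped and
#' rescaled to `[0, 1]` so that 1 corresponds to maximal inflation (lowest
#' parenchymal signal). Invariant to global intensity offsets and scaling.
#'
#' @param series A [dynamic_series].
#' @return Numeric vector, one value per frame in `[0, 1]`.
#' @export
estimate_respiratory_signal <- function(series) {
  stopifnot(inherits(series, "dynamic_series"))
  if (!any(series$lung_mask)) {
    stop_lungvent("lung mask is empty", class = "lungvent_empty_mask_error")
  }
  n <- dim(series$data)[4]
  idx <- which(series$lung_mask)
  m <- vapply(seq_len(n),
              function(f) mean(series$data[, , , f][idx]), numeric(1))
  rng <- max(m) - min(m)
  if (rng == 0) return(rep(0, n))
  (max(m) - m) / rng
}

# Resample one volume along z: source coordinate z' = s * (z - z0) + z0 + t,
# sampled only at the given voxels. Linear interpolation gives the smooth
# similarity surface used during optimisation; nearest-neighbour sampling
# is used when applying a transform, so resampled intensities are always
# observed voxel values and tissue boundaries are never blended across.
resample_axial <- function(vol, ai, s, t, z0, nearest = FALSE) {
  nz <- dim(vol)[3]
  zp <- s * (ai[, 3] - z0) + z0 + t
  base <- ai[, 1] + (ai[, 2] - 1L) * dim(vol)[1]
  sxy <- dim(vol)[1] * dim(vol)[2]
  if (nearest) {
    k <- pmin(pmax(round(zp), 1L), nz)
    return(vol[base + (k - 1L) * sxy])
  }
  k0 <- floor(zp)
  fr <- zp - k0
  k0c <- pmin(pmax(k0, 1L), nz)
  k1c <- pmin(pmax(k0 + 1L, 1L), nz)
  (1 - fr) * vol[base + (k0c - 1L) * sxy] + fr * vol[base + (k1c - 1L) * sxy]
}

#' Register frames of a dynamic series by axial translation and scale
#'
#' Each frame is resampled onto the reference frame's grid with the axial
#' transform (translation + scale about the lung apex) that minimises the
#' in-mask sum of squared differences to the reference frame. The phantom's
#' breathing motion is diaphragm-dominated and axial, so this rigid axial
#' family is sufficient; per-frame transform parameters are attached as the
#' `"transforms"` attribute.
#'
#' @param series A [dynamic_series].
#' @param reference_frame Index of the frame to register to.
#' @param mask Optional logical mask for the similarity metric. By default
#'   the lung mask dilated twice, so the high-contrast lung boundary drives
#'   the alignment; a metric restricted to near-uniform parenchyma would
#'   leave the transform under-determined.
#' @param max_translation_vox Bound on the axial translation, in voxels.
#' @param scale_range Bounds on the axial scale factor.
#' @return A registered [dynamic_series].
#' @export
register_frames <- function(series, reference_frame, mask = NULL,
                            max_translation_vox = 8,
                            scale_range = c(0.7, 1.4)) {
  stopifnot(inherits(series, "dynamic_series"))
  n <- dim(series$data)[4]
  if (reference_frame < 1 || reference_frame > n) {
    stop_lungvent("reference_frame out of range",
                  class = "lungvent_value_error")
  }
  if (is.null(mask)) mask <- dilate26(dilate26(series$lung_mask))
  idx <- which(mask)
  if (length(idx) == 0) {
    stop_lungvent("registration mask is empty",
                  class = "lungvent_empty_mask_error")
  }
  # a deterministic subsample of metric voxels is enough to drive two
  # transform parameters
  if (length(idx) > 4000) {
    idx <- idx[seq(1, length(idx), length.out = 4000)]
  }
  ai <- arrayInd(idx, dim(mask))
  z0 <- min(arrayInd(which(series$lung_mask), dim(mask))[, 3])  # lung apex
  ref_vals <- series$data[, , , reference_frame][idx]
  out <- series$data
  transforms <- matrix(0, nrow = n, ncol = 2,
                       dimnames = list(NULL, c("translation_vox", "scale")))
  transforms[, 2] <- 1
  lower <- c(-max_translation_vox, log(scale_range[1]))
  upper <- c(max_translation_vox, log(scale_range[2]))
  full_ai <- arrayInd(seq_len(prod(dim(mask))), dim(mask))
  par <- c(0, 0)  # warm start carried between consecutive frames
  for (f in seq_len(n)) {
    if (f == reference_frame) next
    vol <- series$data[, , , f]
    obj <- function(p) {
      v <- resample_axial(vol, ai, exp(p[2]), p[1], z0)
      sum((v - ref_vals)^2)
    }
    fit <- tryCatch(
      stats::optim(par, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 40, factr = 1e9)),
      error = function(e) NULL)
    if (is.null(fit)) {
      stop_lungvent("registration failed for frame ", f,
                    class = "lungvent_registration_error")
    }
    par <- fit$par
    s <- exp(fit$par[2]); t <- fit$par[1]
    transforms[f, ] <- c(t, s)
    out[, , , f] <- array(resample_axial(vol, full_ai, s, t, z0,
                                         nearest = TRUE), dim(vol))
  }
  res <- dynamic_series(out, series$spacing, series$frame_times,
                        series$lung_mask)
  attr(res, "transforms") <- transforms
  res
}

# Cycle fractions per frame from an inflation signal: end-expiratory troughs
# delimit cycles; within a cycle the phase rises linearly from 0 to 1.
# Frames outside the first/last trough are phased by cyclic extrapolation
# with the adjacent cycle's period.
assign_phases <- function(signal, times) {
  n <- length(signal)
  is_trough <- rep(FALSE, n)
  for (k in 2:(n - 1)) {
    if (signal[k] < signal[k - 1] && signal[k] <= signal[k + 1]) {
      is_trough[k] <- TRUE
    }
  }
  tr <- which(is_trough)
  if (length(tr) < 2) {
    stop_lungvent("fewer than one full breathing cycle detected",
                  class = "lungvent_insufficient_data_error")
  }
  phase <- rep(NA_real_, n)
  for (i in seq_len(length(tr) - 1)) {
    a <- tr[i]; b <- tr[i + 1]
    span <- times[b] - times[a]
    sel <- a:(b - 1)
    phase[sel] <- (times[sel] - times[a]) / span
  }
  t1 <- times[tr[2]] - times[tr[1]]
  before <- seq_len(tr[1] - 1)
  if (length(before)) phase[before] <- ((times[before] - times[tr[1]]) / t1) %% 1
  tm <- times[tr[length(tr)]] - times[tr[length(tr) - 1]]
  after <- seq(tr[length(tr)], n)
  phase[after] <- ((times[after] - times[tr[length(tr)]]) / tm) %% 1
  phase
}

#' Sort a dynamic series into respiratory phase bins
#'
#' Assigns each frame a breathing-cycle fraction by trough-to-trough linear
#' interpolation of the respiratory signal, then averages frames within
#' `n_phases` equal-width bins. Empty bins are filled by cyclic linear
#' interpolation of their nearest occupied neighbours; per-bin occupancy is
#' recorded on the result.
#'
#' @param series A [dynamic_series] (register first for moving anatomy).
#' @param signal Per-frame inflation signal from
#'   [estimate_respiratory_signal()].
#' @param n_phases Number of phase bins (default 8).
#' @return A [phase_series]; phase 0 is end-expiration.
#' @export
sort_to_phases <- function(series, signal, n_phases = 8) {
  stopifnot(inherits(series, "dynamic_series"))
  n <- dim(series$data)[4]
  if (length(signal) != n) {
    stop_lungvent("signal length must equal the number of frames",
                  class = "lungvent_dim_error")
  }
  if (stats::sd(signal) == 0) {
    stop_lungvent("respiratory signal is constant; cannot sort phases",
                  class = "lungvent_degenerate_signal_error")
  }
  phase <- assign_phases(signal, series$frame_times)
  bin <- pmin(floor(phase * n_phases) + 1L, n_phases)
  d <- dim(series$data)[1:3]
  pdata <- array(NA_real_, c(d, n_phases))
  occupancy <- integer(n_phases)
  for (b in seq_len(n_phases)) {
    sel <- which(bin == b)
    occupancy[b] <- length(sel)
    if (length(sel) == 1) {
      pdata[, , , b] <- series$data[, , , sel]
    } else if (length(sel) > 1) {
      m <- matrix(series$data, nrow = prod(d))[, sel, drop = FALSE]
      pdata[, , , b] <- array(rowMeans(m), d)
    }
  }
  empty <- which(occupancy == 0)
  if (length(empty) == length(occupancy)) {
    stop_lungvent("no frames could be phase-binned",
                  class = "lungvent_insufficient_data_error")
  }
  for (b in empty) {
    occ <- which(occupancy > 0)
    dl <- (b - occ) %% n_phases; dr <- (occ - b) %% n_phases
    left <- occ[which.min(dl)]; right <- occ[which.min(dr)]
    wl <- min(dr[occ == right]); wr <- min(dl[occ == left])
    tot <- wl + wr
    pdata[, , , b] <- (wl * pdata[, , , left] + wr * pdata[, , , right]) / tot
  }
  phase_grid <- (seq_len(n_phases) - 0.5) / n_phases
  phase_series(pdata, phase_grid, series$lung_mask, occupancy = occupancy)
}

# In-mask mean per phase bin.
phase_bin_means <- function(phases) {
  idx <- which(phases$lung_mask)
  vapply(seq_len(phases$n_phases),
         function(b) mean(phases$data[, , , b][idx]), numeric(1))
}

#' Compute the static regional ventilation (RVent) map
#'
#' For each voxel the two respiratory phases with maximal ventilation
#' amplitude are its signal maximum (local end-expiration) and minimum
#' (local end-inspiration) over the phase bins:
#' `RVent = (S_max - S_min) / S_max`. The map is median-smoothed in-mask
#' with a 3x3x3 kernel; voxels whose end-expiratory signal is non-positive
#' are marked excluded.
#'
#' @param phases A [phase_series].
#' @param smooth_kernel Odd kernel width for in-mask median smoothing
#'   (1 disables).
#' @return List with `rvent` (3D array), `excluded` (logical 3D array) and
#'   `phase_means` (in-mask mean per bin).
#' @export
compute_rvent <- function(phases, smooth_kernel = 3) {
  stopifnot(inherits(phases, "phase_series"))
  if (phases$n_phases < 2) {
    stop_lungvent("RVent needs at least two respiratory phases",
                  class = "lungvent_value_error")
  }
  means <- phase_bin_means(phases)
  d <- dim(phases$data)[1:3]
  idx <- which(phases$lung_mask)
  m <- matrix(phases$data, nrow = prod(d), ncol = phases$n_phases)[idx, ,
                                                                   drop = FALSE]
  smax <- apply(m, 1, max)
  smin <- apply(m, 1, min)
  rv <- array(0, d)
  excl <- array(FALSE, d)
  bad <- smax <= 0
  val <- ifelse(bad, 0, (smax - smin) / smax)
  rv[idx] <- val
  excl[idx] <- bad
  rv <- median_filter_mask(rv, phases$lung_mask & !excl, size = smooth_kernel)
  list(rvent = rv, excluded = excl, phase_means = means)
}

#' Compute per-voxel flow-volume loops
#'
#' The ventilation-volume trajectory of each voxel is
#' `V(p) = (S(pE) - S(p)) / S(pE)` with `pE` the global end-expiratory bin
#' (maximal in-mask mean signal), so V is zero at end-expiration and rises
#' with inflation. The flow channel is the cyclic central difference of V
#' over the phase grid.
#'
#' @param phases A [phase_series] with at least 4 bins.
#' @return List with matrices `volume` and `flow` (in-mask voxels x phases),
#'   `voxels` (linear indices), `excluded` (logical over those voxels),
#'   `phase_grid` and `pE` (end-expiratory bin index).
#' @export
compute_fvl <- function(phases) {
  stopifnot(inherits(phases, "phase_series"))
  if (phases$n_phases < 4) {
    stop_lungvent("flow-volume loops need at least four respiratory phases",
                  class = "lungvent_value_error")
  }
  means <- phase_bin_means(phases)
  pE <- which.max(means)
  d <- dim(phases$data)[1:3]
  idx <- which(phases$lung_mask)
  m <- matrix(phases$data, nrow = prod(d), ncol = phases$n_phases)[idx, ,
                                                                   drop = FALSE]
  sE <- m[, pE]
  excluded <- sE <= 0
  v <- (sE - m) / ifelse(excluded, NA_real_, sE)
  np <- phases$n_phases
  dphi <- 1 / np
  nxt <- c(2:np, 1); prv <- c(np, 1:(np - 1))
  f <- (v[, nxt, drop = FALSE] - v[, prv, drop = FALSE]) / (2 * dphi)
  list(volume = v, flow = f, voxels = idx, excluded = excluded,
       phase_grid = phases$phase_grid, pE = pE)
}

#' Build the healthy reference flow-volume loop
#'
#' The phase-wise median of the volume and flow channels over the
#' well-ventilated subset: voxels whose RVent is at or above the in-mask
#' median.
#'
#' @param loops Per-voxel loops from [compute_fvl()].
#' @param rvent RVent array from [compute_rvent()] (the selection hint).
#' @param min_voxels Minimum size of the well-ventilated subset.
#' @return A [flow_volume_loop].
#' @export
build_reference_loop <- function(loops, rvent, min_voxels = 10) {
  rv <- rvent[loops$voxels]
  sel <- !loops$excluded & rv >= stats::median(rv[!loops$excluded])
  if (sum(sel) < min_voxels) {
    stop_lungvent("too few well-ventilated voxels (", sum(sel),
                  ") to build a reference loop",
                  class = "lungvent_reference_error")
  }
  vref <- apply(loops$volume[sel, , drop = FALSE], 2, stats::median)
  fref <- apply(loops$flow[sel, , drop = FALSE], 2, stats::median)
  flow_volume_loop(vref, fref, loops$phase_grid)
}

#' Compute the flow-volume-loop cross-correlation metric (FVL-CM)
#'
#' For each voxel, the mean-centred volume and flow channels are
#' concatenated and correlated with the reference loop's concatenated
#' channels (normalised inner product), giving a value in `[-1, 1]` that is
#' invariant to loop amplitude. Zero-variance voxel loops map to 0.
#'
#' @param loops Per-voxel loops from [compute_fvl()].
#' @param reference A [flow_volume_loop] from [build_reference_loop()].
#' @param dim Grid dimensions of the output array.
#' @return 3D array of FVL-CM values (0 outside the mask; excluded voxels
#'   NA).
#' @export
compute_fvlcm <- function(loops, reference, dim) {
  stopifnot(inherits(reference, "flow_volume_loop"))
  r <- fvlcm_values(loops, reference)
  out <- array(0, dim)
  out[loops$voxels] <- r
  out
}

#' Compute both ventilation maps from a phase-resolved series
#'
#' Convenience wrapper: RVent, flow-volume loops, the healthy reference
#' loop, and FVL-CM, returned as a [vent_maps] object. Besides
#' non-positive-signal voxels, in-mask voxels whose peak phase signal
#' exceeds `bright_exclusion_factor` times the in-mask median peak signal
#' are marked excluded: within a lung mask such bright voxels are
#' non-parenchymal tissue (vessels, or boundary voxels contaminated by
#' chest-wall/abdominal signal) whose intensity does not follow the
#' density-ventilation model.
#'
#' @param phases A [phase_series].
#' @param smooth_kernel Median-smoothing kernel for RVent.
#' @param bright_exclusion_factor Peak-signal ratio above which an in-mask
#'   voxel is excluded as non-parenchymal (`Inf` disables).
#' @return A [vent_maps].
#' @export
compute_ventilation_maps <- function(phases, smooth_kernel = 3,
                                     bright_exclusion_factor = 1.5) {
  d <- dim(phases$data)[1:3]
  idx <- which(phases$lung_mask)
  m <- matrix(phases$data, nrow = prod(d),
              ncol = phases$n_phases)[idx, , drop = FALSE]
  smax <- apply(m, 1, max)
  excl <- array(FALSE, d)
  excl[idx] <- smax > bright_exclusion_factor * stats::median(smax)

  rv <- compute_rvent(phases, smooth_kernel = smooth_kernel)
  loops <- compute_fvl(phases)
  keep <- !excl[loops$voxels]
  sel_loops <- list(volume = loops$volume[keep, , drop = FALSE],
                    flow = loops$flow[keep, , drop = FALSE],
                    voxels = loops$voxels[keep],
                    excluded = loops$excluded[keep],
                    phase_grid = loops$phase_grid, pE = loops$pE)
  ref <- build_reference_loop(sel_loops, rv$rvent)
  r <- fvlcm_values(loops, ref)
  fvlcm <- array(0, d)
  fvlcm[loops$voxels] <- ifelse(is.na(r), 0, r)
  excl <- excl | rv$excluded
  excl[loops$voxels[loops$excluded]] <- TRUE
  vent_maps(rv$rvent, fvlcm, phases$lung_mask, excluded = excl)
}

fvlcm_values <- function(loops, reference) {
  np <- ncol(loops$volume)
  if (length(reference$volume) != np) {
    stop_lungvent("reference loop length does not match voxel loops",
                  class = "lungvent_shape_error")
  }
  uv <- loops$volume - rowMeans(loops$volume)
  uf <- loops$flow - rowMeans(loops$flow)
  wv <- reference$volume - mean(reference$volume)
  wf <- reference$flow - mean(reference$flow)
  num <- uv %*% wv + uf %*% wf
  den <- sqrt(rowSums(uv^2) + rowSums(uf^2)) * sqrt(sum(wv^2) + sum(wf^2))
  r <- as.numeric(num) / den
  r[den == 0] <- 0
  r <- pmin(pmax(r, -1), 1)
  r[loops$excluded] <- NA_real_
  r
}

#' Threshold an RVent map into a defect map
#'
#' The defect threshold is `factor` times the in-mask `percentile`-th
#' percentile of RVent (linear-interpolation percentile convention); voxels
#' strictly below the threshold are defect, boundary voxels are healthy.
#'
#' @param rvent 3D RVent array.
#' @param mask Logical lung mask.
#' @param excluded Optional logical array of excluded voxels (pass through).
#' @param factor Threshold multiplier (default 0.4).
#' @param percentile Percentile (0-1 scale) on which the threshold is based
#'   (default 0.9).
#' @param spacing Voxel spacing for the result.
#' @return A [defect_map] with source "RVent"; the threshold used is
#'   attached as attribute `"threshold"`.
#' @export
threshold_rvent <- function(rvent, mask, excluded = NULL, factor = 0.4,
                            percentile = 0.9, spacing = c(1, 1, 1)) {
  if (!any(mask)) {
    stop_lungvent("mask is empty", class = "lungvent_empty_mask_error")
  }
  if (is.null(excluded)) excluded <- array(FALSE, dim(mask))
  eval_mask <- mask & !excluded
  vals <- rvent[eval_mask]
  if (any(!is.finite(vals))) {
    stop_lungvent("RVent must be finite inside the mask",
                  class = "lungvent_value_error")
  }
  thr <- factor * percentile_linear(vals, percentile)
  lab <- array(label_codes[["outside"]], dim(mask))
  lab[eval_mask] <- ifelse(rvent[eval_mask] < thr,
                           label_codes[["defect"]], label_codes[["healthy"]])
  lab[mask & excluded] <- label_codes[["excluded"]]
  dm <- defect_map(lab, source = "RVent", spacing = spacing)
  attr(dm, "threshold") <- thr
  dm
}

#' Threshold an FVL-CM map into a defect map
#'
#' Voxels with FVL-CM strictly below `threshold` (default 0.9) are defect;
#' boundary voxels are healthy.
#'
#' @param fvlcm 3D FVL-CM array in `[-1, 1]`.
#' @param mask Logical lung mask.
#' @param excluded Optional logical array of excluded voxels.
#' @param threshold Fixed defect threshold (default 0.9).
#' @param spacing Voxel spacing for the result.
#' @return A [defect_map] with source "FVL-CM".
#' @export
threshold_fvlcm <- function(fvlcm, mask, excluded = NULL, threshold = 0.9,
                            spacing = c(1, 1, 1)) {
  if (is.null(excluded)) excluded <- array(FALSE, dim(mask))
  eval_mask <- mask & !excluded
  vals <- fvlcm[eval_mask]
  if (any(vals < -1 - 1e-9 | vals > 1 + 1e-9)) {
    stop_lungvent("FVL-CM values outside [-1, 1]",
                  class = "lungvent_value_error")
  }
  lab <- array(label_codes[["outside"]], dim(mask))
  lab[eval_mask] <- ifelse(vals < threshold,
                           label_codes[["defect"]], label_codes[["healthy"]])
  lab[mask & excluded] <- label_codes[["excluded"]]
  dm <- defect_map(lab, source = "FVL-CM", spacing = spacing)
  attr(dm, "threshold") <- threshold
  dm
}

#' Combine two defect maps with a logical OR
#'
#' A voxel is defect if it is defect in either input; excluded if excluded
#' in either; healthy otherwise. Both maps must share grid and mask.
#'
#' @param a,b [defect_map]s on the same grid.
#' @return A [defect_map] with source "Combined".
#' @export
combine_defect_maps <- function(a, b) {
  stopifnot(inherits(a, "defect_map"), inherits(b, "defect_map"))
  if (!identical(dim(a$labels), dim(b$labels))) {
    stop_lungvent("defect maps are on different grids",
                  class = "lungvent_shape_error")
  }
  la <- a$labels; lb <- b$labels
  lab <- array(label_codes[["outside"]], dim(la))
  inside <- la != 0L | lb != 0L
  lab[inside] <- label_codes[["healthy"]]
  lab[la == label_codes[["defect"]] | lb == label_codes[["defect"]]] <-
    label_codes[["defect"]]
  lab[la == label_codes[["excluded"]] | lb == label_codes[["excluded"]]] <-
    label_codes[["excluded"]]
  defect_map(lab, source = "Combined", spacing = a$spacing, affine = a$affine)
}

#' Ventilation defect percentage of a defect map
#'
#' `100 * defect / (defect + healthy)`; excluded voxels enter neither the
#' numerator nor the denominator.
#'
#' @param d A [defect_map].
#' @return VDP in percent.
#' @export
compute_vdp <- function(d) {
  stopifnot(inherits(d, "defect_map"))
  n_def <- sum(d$labels == label_codes[["defect"]])
  n_heal <- sum(d$labels == label_codes[["healthy"]])
  if (n_def + n_heal == 0) {
    stop_lungvent("no evaluable voxels (all excluded or outside)",
                  class = "lungvent_empty_denominator_error")
  }
  100 * n_def / (n_def + n_heal)
}

#' Run the full phase-resolved proton ventilation analysis
#'
#' Chains respiratory-signal estimation, (optional) axial registration,
#' phase sorting, ventilation mapping and defect thresholding.
#'
#' @param series A [dynamic_series].
#' @param n_phases Number of respiratory phase bins.
#' @param register Register frames axially before phase sorting.
#' @param smooth_kernel Median-smoothing kernel for RVent.
#' @param rvent_factor,rvent_percentile RVent threshold parameters.
#' @param fvlcm_threshold FVL-CM defect threshold.
#' @return List with `maps` ([vent_maps]), `defects` (RVent, FVL-CM and
#'   Combined [defect_map]s), `vdp` (named VDP values in percent), `signal`,
#'   `phases` and the thresholds used.
#' @export
preful_analysis <- function(series, n_phases = 8, register = TRUE,
                            smooth_kernel = 3, rvent_factor = 0.4,
                            rvent_percentile = 0.9, fvlcm_threshold = 0.9) {
  signal <- estimate_respiratory_signal(series)
  if (register) {
    ref_frame <- which.min(signal)  # end-expiration
    series <- register_frames(series, ref_frame)
    signal <- estimate_respiratory_signal(series)
  }
  phases <- sort_to_phases(series, signal, n_phases = n_phases)
  maps <- compute_ventilation_maps(phases, smooth_kernel = smooth_kernel)
  d_rv <- threshold_rvent(maps$rvent, maps$mask, maps$excluded,
                          factor = rvent_factor,
                          percentile = rvent_percentile,
                          spacing = series$spacing)
  d_cm <- threshold_fvlcm(maps$fvlcm, maps$mask, maps$excluded,
                          threshold = fvlcm_threshold,
                          spacing = series$spacing)
  d_comb <- combine_defect_maps(d_rv, d_cm)
  list(maps = maps,
       defects = list(rvent = d_rv, fvlcm = d_cm, combined = d_comb),
       vdp = c(rvent = compute_vdp(d_rv), fvlcm = compute_vdp(d_cm),
               combined = compute_vdp(d_comb)),
       signal = signal, phases = phases,
       thresholds = c(rvent = attr(d_rv, "threshold"),
                      fvlcm = fvlcm_threshold))
}
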
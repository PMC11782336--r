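# Synthetic 4D breathing-lung phantom.
#
# A torso with two lung compartments breathes sinusoidally: the diaphragm
# surface descends with inflation (scaled about the lung apex, so deeper
# columns travel further), while parenchymal proton signal falls inversely
# with local inflation, S(t) = S0 / (1 + e_local(t)) -- the proton-density
# assumption that free-breathing ventilation mapping rests on. Ventilation
# defects are grown as contiguous blobs: "static" defects with reduced
# inflation amplitude and "dynamic" defects with full amplitude but a phase
# lag. A matched breath-hold gas ventilation image is derived from the same
# ground truth on a thick-slab grid with a smooth multiplicative bias field.

#' Phantom configuration
#'
#' Defines the geometry, breathing pattern, defect layout and noise of the
#' synthetic phantom. Defaults give a 32 x 26 x 40 grid at 3.9 mm isotropic
#' resolution (the proton acquisition grid), a 4 s breathing period sampled
#' every 0.25 s for 44 frames (2.75 cycles), 30% regional tidal inflation,
#' and a 15 mm slab grid for the gas image.
#'
#' @param grid_shape Integer triple, voxels per axis (x, y, z); axial = z.
#' @param voxel_spacing_mm Numeric triple, mm per axis.
#' @param n_frames Number of dynamic frames; must cover at least two full
#'   breathing cycles.
#' @param frame_interval_s Seconds between frames.
#' @param breathing_period_s Breathing period in seconds.
#' @param tidal_amplitude Fractional regional inflation of healthy lung at
#'   end-inspiration, in `[0, 1]`.
#' @param defect_fraction Target fraction of lung voxels that are defective.
#' @param defect_mode One of "static", "dynamic", "mixed".
#' @param dynamic_delay_fraction Phase lag of dynamic defects, in cycle
#'   fractions.
#' @param static_amplitude_factor Multiplier on `tidal_amplitude` inside
#'   static defects (0 = no ventilation).
#' @param dynamic_gas_efficiency Fresh-gas delivery efficiency of
#'   phase-delayed regions during the breath-hold gas wash-in, in `[0, 1]`;
#'   delayed regions fill poorly within a single inhalation, so they appear
#'   dark on the gas image even though their cyclic amplitude is preserved.
#' @param amplitude_jitter Cycle-to-cycle fractional jitter of the breathing
#'   amplitude (0 = perfectly regular sinusoid).
#' @param snr Signal-to-noise ratio of parenchymal signal at end-expiration;
#'   `Inf` disables noise.
#' @param bias_strength Peak-to-trough ratio of the multiplicative bias
#'   field on the gas image (1 = no bias).
#' @param gas_slab_thickness_mm Slab thickness of the gas grid in mm.
#' @param seed Integer seed; identical configs produce identical phantoms.
#' @return A validated list of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(32, 26, 40),
                           voxel_spacing_mm = c(3.9, 3.9, 3.9),
                           n_frames = 44,
                           frame_interval_s = 0.25,
                           breathing_period_s = 4,
                           tidal_amplitude = 0.3,
                           defect_fraction = 0,
                           defect_mode = c("mixed", "static", "dynamic"),
                           dynamic_delay_fraction = 0.25,
                           static_amplitude_factor = 0,
                           dynamic_gas_efficiency = 0.1,
                           amplitude_jitter = 0,
                           snr = 30,
                           bias_strength = 1.4,
                           gas_slab_thickness_mm = 15,
                           seed = 1L) {
  defect_mode <- match.arg(defect_mode)
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_spacing_mm = as.numeric(voxel_spacing_mm),
              n_frames = as.integer(n_frames),
              frame_interval_s = as.numeric(frame_interval_s),
              breathing_period_s = as.numeric(breathing_period_s),
              tidal_amplitude = as.numeric(tidal_amplitude),
              defect_fraction = as.numeric(defect_fraction),
              defect_mode = defect_mode,
              dynamic_delay_fraction = as.numeric(dynamic_delay_fraction),
              static_amplitude_factor = as.numeric(static_amplitude_factor),
              dynamic_gas_efficiency = as.numeric(dynamic_gas_efficiency),
              amplitude_jitter = as.numeric(amplitude_jitter),
              snr = as.numeric(snr),
              bias_strength = as.numeric(bias_strength),
              gas_slab_thickness_mm = as.numeric(gas_slab_thickness_mm),
              seed = as.integer(seed))
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  in01 <- function(x) is.finite(x) && x >= 0 && x <= 1
  if (length(cfg$grid_shape) != 3 || any(cfg$grid_shape < 12)) {
    stop_lungvent("grid_shape must be three integers >= 12",
                  class = "lungvent_config_error")
  }
  if (any(cfg$voxel_spacing_mm <= 0) || cfg$gas_slab_thickness_mm <= 0) {
    stop_lungvent("all spacings must be strictly positive",
                  class = "lungvent_config_error")
  }
  if (!is.finite(cfg$breathing_period_s) || cfg$breathing_period_s <= 0 ||
      cfg$frame_interval_s <= 0) {
    stop_lungvent("breathing period and frame interval must be positive",
                  class = "lungvent_config_error")
  }
  if (!(cfg$snr > 0)) {
    stop_lungvent("snr must be positive (Inf allowed)",
                  class = "lungvent_config_error")
  }
  if (!in01(cfg$tidal_amplitude) || !in01(cfg$defect_fraction) ||
      !in01(cfg$dynamic_delay_fraction)) {
    stop_lungvent(
      "tidal_amplitude, defect_fraction, dynamic_delay_fraction must be in [0, 1]",
      class = "lungvent_config_error")
  }
  frames_per_cycle <- cfg$breathing_period_s / cfg$frame_interval_s
  if (cfg$n_frames < 2 * frames_per_cycle) {
    stop_lungvent("n_frames must cover at least two full breathing cycles",
                  class = "lungvent_config_error")
  }
  if (cfg$bias_strength < 1) {
    stop_lungvent("bias_strength is a peak-to-trough ratio and must be >= 1",
                  class = "lungvent_config_error")
  }
  invisible(cfg)
}

# Parenchymal base signal relative to soft tissue = 1.
PHANTOM_S0 <- 0.4

# Torso and lung geometry. Each lung is a vertical elliptic column with a
# flat top at the apex plane and a domed bottom surface (the diaphragm):
# zbot(x, y) = apex + depth * sqrt(1 - r^2). Inflation scales the axial
# coordinate about the apex, so the flat top and the vertical side walls
# stay fixed while the diaphragm dome descends -- diaphragm-dominated
# motion under a pure axial scaling, with every end-expiratory lung voxel
# remaining inside the lung at all inflation states.
phantom_geometry <- function(cfg) {
  d <- cfg$grid_shape
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  X <- matrix(rep(seq_len(nx), ny), nx, ny)
  Y <- matrix(rep(seq_len(ny), each = nx), nx, ny)

  torso_rx <- 0.44 * nx; torso_ry <- 0.42 * ny
  torso_inplane <- ((X - cx) / torso_rx)^2 + ((Y - cy) / torso_ry)^2 <= 1
  torso <- array(FALSE, d)
  torso[, , 2:(nz - 1)] <- torso_inplane

  lung_rx <- 0.17 * nx; lung_ry <- 0.26 * ny
  z_apex <- 0.17 * nz
  lung_depth <- 0.55 * nz
  centres <- list(c(cx - 0.21 * nx, cy), c(cx + 0.21 * nx, cy))

  zbot <- matrix(NA_real_, nx, ny)
  for (i in seq_along(centres)) {
    r2 <- ((X - centres[[i]][1]) / lung_rx)^2 +
          ((Y - centres[[i]][2]) / lung_ry)^2
    inpl <- r2 < 1
    zbot[inpl] <- z_apex + lung_depth * sqrt(1 - r2[inpl])
  }

  Z <- array(rep(seq_len(nz), each = nx * ny), c(nx, ny, nz))
  zbot3 <- array(rep(zbot, nz), d)
  lung_ref <- !is.na(zbot3) & Z >= ceiling(z_apex) & Z <= zbot3 & torso
  lung_centres <- lapply(centres, function(ct) {
    c(round(ct[1]), round(ct[2]), round(z_apex + 0.45 * lung_depth))
  })
  list(torso = torso, lung_ref = lung_ref, zbot3 = zbot3, Z = Z,
       z_apex = z_apex, lung_centres = lung_centres)
}

# Grow contiguous defect blobs inside the lung mask. Defects are modelled
# as craniocaudally extended wedges (segmental/lobar pattern): blobs are
# grown over the 2D graph of lung columns (8-connectivity in-plane) from
# seeded germ columns, each accepted column marked defective over its full
# apex-to-diaphragm extent; the final column of a blob is part-filled from
# the lung base upwards so the total defect count matches the quota
# exactly. Returns an integer array: 0 = non-lung, 1 = healthy, 2 = static
# defect, 3 = dynamic defect.
grow_defect_blobs <- function(lung_mask, fraction, mode) {
  dims <- dim(lung_mask)
  labels <- array(0L, dims)
  labels[lung_mask] <- 1L
  n_lung <- sum(lung_mask)
  quota <- round(fraction * n_lung)
  if (quota == 0) return(labels)

  col_height <- apply(lung_mask, c(1, 2), sum)
  col_state <- ifelse(col_height > 0, 1L, 0L)  # 0 non-lung, 1 available
  offs2 <- as.matrix(expand.grid(dx = -1:1, dy = -1:1))
  offs2 <- offs2[rowSums(abs(offs2)) > 0, ]
  blob_target <- max(150, ceiling(quota / 2))
  types <- if (mode == "static") 2L else if (mode == "dynamic") 3L else c(2L, 3L)

  mark_column <- function(labels, x, y, type, n_vox) {
    zs <- which(lung_mask[x, y, ])
    zs <- sort(zs, decreasing = TRUE)[seq_len(min(n_vox, length(zs)))]
    labels[x, y, zs] <- type
    labels
  }

  placed <- 0
  blob_i <- 0
  while (placed < quota) {
    avail <- which(col_state == 1L)
    if (length(avail) == 0) break
    blob_i <- blob_i + 1
    type <- types[((blob_i - 1) %% length(types)) + 1]
    blob_cols <- avail[sample.int(length(avail), 1)]
    col_state[blob_cols] <- 2L
    blob_quota <- min(blob_target, quota - placed)
    blob_n <- 0
    repeat {
      ci <- arrayInd(blob_cols[length(blob_cols)], dims[1:2])
      # take the next column: full height unless it would overshoot
      h <- col_height[blob_cols[length(blob_cols)]]
      take <- min(h, blob_quota - blob_n)
      labels <- mark_column(labels, ci[1], ci[2], type, take)
      blob_n <- blob_n + take
      placed <- placed + take
      if (blob_n >= blob_quota) break
      # frontier: available columns 8-adjacent to the blob
      bai <- arrayInd(blob_cols, dims[1:2])
      cand <- integer(0)
      for (o in seq_len(nrow(offs2))) {
        ni <- cbind(bai[, 1] + offs2[o, 1], bai[, 2] + offs2[o, 2])
        ok <- ni[, 1] >= 1 & ni[, 1] <= dims[1] &
              ni[, 2] >= 1 & ni[, 2] <= dims[2]
        lin <- ni[ok, 1] + (ni[ok, 2] - 1L) * dims[1]
        cand <- c(cand, lin[col_state[lin] == 1L])
      }
      cand <- unique(cand)
      if (length(cand) == 0) break
      nxt <- cand[sample.int(length(cand), 1)]
      col_state[nxt] <- 2L
      blob_cols <- c(blob_cols, nxt)
    }
  }
  labels
}

cycle_envelope <- function(times, cfg, cycle_mult) {
  cyc <- pmax(1L, pmin(length(cycle_mult),
                       floor(times / cfg$breathing_period_s) + 1L))
  cycle_mult[cyc]
}

#' Generate a free-breathing proton series with known ground truth
#'
#' Simulates the dynamic proton acquisition: per-frame inflation
#' `e(t) = tidal_amplitude * (1 - cos(2*pi*t / period)) / 2`, a diaphragm
#' that descends proportionally to each column's depth below the apex, and
#' parenchymal signal `S(t) = S0 / (1 + e_local(t))` so signal falls with
#' inflation. Static defects have their amplitude scaled by
#' `static_amplitude_factor`; dynamic defects keep full amplitude but lag by
#' `dynamic_delay_fraction` of a cycle. Gaussian noise is added at the
#' configured SNR. Identical configs (including seed) give identical output.
#'
#' @param config A [phantom_config()].
#' @return A list with `series` (a [dynamic_series]) and `truth`, the ground
#'   truth: `lung_mask`, `defect_labels` (0 non-lung, 1 healthy, 2 static
#'   defect, 3 dynamic defect), `true_rvent` (per-voxel fractional
#'   ventilation `a / (1 + a)`), `respiratory_signal` (per-frame inflation
#'   surrogate in `[0, 1]`), `seeds` (per-lung voxel coordinates on the slab
#'   grid) and internals used by [generate_gas_image()].
#' @export
generate_breathing_series <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  validate_phantom_config(config)
  geo <- phantom_geometry(config)
  d <- config$grid_shape
  times <- (seq_len(config$n_frames) - 1) * config$frame_interval_s

  with_seed(config$seed, {
    labels <- grow_defect_blobs(geo$lung_ref, config$defect_fraction,
                                config$defect_mode)
    n_cycles <- floor(max(times) / config$breathing_period_s) + 1L
    cycle_mult <- 1 + config$amplitude_jitter * stats::runif(n_cycles, -1, 1)

    amp <- array(0, d)
    amp[labels == 1L] <- config$tidal_amplitude
    amp[labels == 2L] <- config$tidal_amplitude * config$static_amplitude_factor
    amp[labels == 3L] <- config$tidal_amplitude
    delay <- array(0, d)
    delay[labels == 3L] <- config$dynamic_delay_fraction

    env <- cycle_envelope(times, config, cycle_mult)
    e_geom <- config$tidal_amplitude * env *
      (1 - cos(2 * pi * times / config$breathing_period_s)) / 2

    # axial advection: a voxel at z observes the reference-space material
    # at zeta = apex + (z - apex) / (1 + e); lookups are nearest-neighbour,
    # clamped to the reference lung column
    nxy <- d[1] * d[2]
    z_lo <- ceiling(geo$z_apex)
    xy_lin <- rep(seq_len(nxy), d[3])
    zb_col <- floor(geo$zbot3)

    data <- array(0, c(d, config$n_frames))
    noise_sd <- if (is.finite(config$snr)) PHANTOM_S0 / config$snr else 0
    for (f in seq_len(config$n_frames)) {
      phase <- times[f] / config$breathing_period_s
      scale_f <- 1 + e_geom[f]
      lung_f <- !is.na(geo$zbot3) & geo$Z >= z_lo &
        geo$Z <= geo$z_apex + (geo$zbot3 - geo$z_apex) * scale_f & geo$torso
      vol <- array(0, d)
      vol[geo$torso] <- 1
      zeta <- round(geo$z_apex + (geo$Z - geo$z_apex) / scale_f)
      zeta <- pmax(pmin(zeta, zb_col), z_lo)
      src <- xy_lin + (as.vector(zeta) - 1L) * nxy
      li <- which(lung_f)
      a_v <- amp[src[li]]
      d_v <- delay[src[li]]
      g <- env[f] * (1 - cos(2 * pi * (phase - d_v))) / 2
      vol[li] <- PHANTOM_S0 / (1 + a_v * g)
      if (noise_sd > 0) vol <- vol + stats::rnorm(prod(d), 0, noise_sd)
      data[, , , f] <- vol
    }

    true_rvent <- amp / (1 + amp)
    true_rvent[!geo$lung_ref] <- 0

    slab <- config$gas_slab_thickness_mm
    dz <- config$voxel_spacing_mm[3]
    seeds <- t(vapply(geo$lung_centres, function(ct) {
      c(ct[1], ct[2], max(1L, round((ct[3] - 0.5) * dz / slab + 0.5)))
    }, numeric(3)))

    truth <- list(lung_mask = geo$lung_ref,
                  defect_labels = labels,
                  true_rvent = true_rvent,
                  respiratory_signal = if (max(e_geom) > 0)
                    e_geom / max(e_geom) else e_geom,
                  seeds = seeds,
                  config = config,
                  geometry = geo)

    series <- dynamic_series(data, config$voxel_spacing_mm, times,
                             geo$lung_ref)
    list(series = series, truth = truth)
  })
}

#' Generate the matched breath-hold gas image pair
#'
#' Derives a gas ventilation image and a same-breath anatomical reference on
#' the thick-slab grid from the phantom ground truth. Gas intensity is
#' proportional to per-voxel fractional ventilation (static defects are dark
#' by construction; phase-delayed regions are scaled by
#' `dynamic_gas_efficiency` because they fill poorly during a single
#' breath-hold wash-in), slab-averaged along the axial direction, multiplied
#' by a smooth bias field with peak-to-trough ratio `bias_strength`, with
#' additive noise at the configured SNR.
#'
#' @param truth Ground truth from [generate_breathing_series()] (same
#'   config).
#' @param config The same [phantom_config()].
#' @return A list with `gas` and `anatomical` ([image_volume]s on the slab
#'   grid), `slab_lung_mask` (majority-rule lung mask on the slab grid),
#'   `bias_field` (the applied field) and `seeds`.
#' @export
generate_gas_image <- function(truth, config) {
  stopifnot(inherits(config, "phantom_config"))
  if (!identical(dim(truth$lung_mask), as.integer(config$grid_shape))) {
    stop_lungvent("truth grid does not match the configuration grid",
                  class = "lungvent_shape_error")
  }
  d <- config$grid_shape
  dz <- config$voxel_spacing_mm[3]
  slab <- config$gas_slab_thickness_mm
  w <- slab_overlap_weights(d[3], dz, slab)
  wn <- w / rowSums(w)

  eff <- array(1, d)
  eff[truth$defect_labels == 3L] <- config$dynamic_gas_efficiency
  gas_thin <- truth$true_rvent * eff

  slab_avg <- function(vol) {
    m <- matrix(vol, nrow = d[1] * d[2], ncol = d[3])
    array(m %*% t(wn), c(d[1], d[2], nrow(wn)))
  }

  gas_slab <- slab_avg(gas_thin)
  anat_thin <- array(0, d)
  anat_thin[truth$geometry$torso] <- 1
  anat_thin[truth$lung_mask] <- PHANTOM_S0
  anat_slab <- slab_avg(anat_thin)
  mask_slab <- slab_avg(truth$lung_mask * 1) >= 0.5

  ds <- dim(gas_slab)
  xn <- array(rep((seq_len(ds[1]) - 1) / (ds[1] - 1), ds[2] * ds[3]), ds)
  yn <- aperm(array(rep((seq_len(ds[2]) - 1) / (ds[2] - 1), ds[1] * ds[3]),
                    ds[c(2, 1, 3)]), c(2, 1, 3))
  zn <- aperm(array(rep((seq_len(ds[3]) - 1) / (max(1, ds[3] - 1)),
                        ds[1] * ds[2]), ds[c(3, 1, 2)]), c(2, 3, 1))
  u <- xn + 0.7 * yn + 0.4 * zn + 0.3 * xn * yn
  u <- (u - min(u)) / (max(u) - min(u))
  field <- config$bias_strength^u
  field <- field / exp(mean(log(field[mask_slab])))

  healthy_level <- config$tidal_amplitude / (1 + config$tidal_amplitude)
  noise_sd <- if (is.finite(config$snr)) healthy_level / config$snr else 0

  with_seed(config$seed + 1L, {
    gas <- gas_slab * field
    if (noise_sd > 0) {
      gas <- gas + stats::rnorm(length(gas), 0, noise_sd)
      anat_slab <- anat_slab +
        stats::rnorm(length(anat_slab), 0, PHANTOM_S0 / config$snr)
    }
    spacing <- c(config$voxel_spacing_mm[1:2], slab)
    list(gas = image_volume(gas, spacing),
         anatomical = image_volume(anat_slab, spacing),
         slab_lung_mask = mask_slab,
         bias_field = field,
         seeds = truth$seeds)
  })
}

#' Ground-truth defect map on the phantom's proton grid
#'
#' Converts the phantom's defect labels to a [defect_map] for comparison
#' against recovered maps.
#'
#' @param truth Ground truth from [generate_breathing_series()].
#' @param type Which defect classes count as defect: "any", "static" or
#'   "dynamic".
#' @return A [defect_map] with source "Truth".
#' @export
truth_defect_map <- function(truth, type = c("any", "static", "dynamic")) {
  type <- match.arg(type)
  want <- switch(type, any = c(2L, 3L), static = 2L, dynamic = 3L)
  lab <- array(label_codes[["outside"]], dim(truth$defect_labels))
  lab[truth$defect_labels > 0L] <- label_codes[["healthy"]]
  lab[truth$defect_labels %in% want] <- label_codes[["defect"]]
  defect_map(lab, source = "Truth",
             spacing = truth$config$voxel_spacing_mm)
}
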
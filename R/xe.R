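# Breath-hold gas ventilation quantification: thoracic-cavity segmentation
# by seeded region growing, smooth multiplicative bias-field correction,
# linear-binning classification of normalised intensities, and VDP.

#' Segment the thoracic cavity by seeded region growing
#'
#' Grows from the given seed voxels with an intensity-window criterion:
#' a voxel joins the region if `|I - mu| <= k * max(SD, 0.2 * mu)`, where
#' `mu` and `SD` are the mean and standard deviation of the 3x3x3
#' neighbourhoods around the seeds. Growth uses 26-connectivity; interior
#' cavities of the grown mask are filled. The relative floor on the spread
#' keeps the window defined for perfectly homogeneous seed regions and
#' admits partial-volume voxels that are majority lung.
#'
#' @param anatomical An [image_volume] (proton anatomical reference).
#' @param seeds Integer matrix of voxel coordinates (rows = seeds, columns =
#'   x, y, z); at least one seed per lung.
#' @param k Width of the intensity window in units of the seed-region
#'   spread (default 2.5).
#' @param max_fraction Guard: abort if the grown region exceeds this
#'   fraction of the volume (runaway growth from a background seed).
#' @return Logical 3D mask.
#' @export
segment_thoracic_cavity <- function(anatomical, seeds, k = 2.5,
                                    max_fraction = 0.6) {
  stopifnot(inherits(anatomical, "image_volume"))
  img <- anatomical$data
  dims <- dim(img)
  seeds <- matrix(as.integer(seeds), ncol = 3)
  if (any(seeds < 1) || any(seeds[, 1] > dims[1]) ||
      any(seeds[, 2] > dims[2]) || any(seeds[, 3] > dims[3])) {
    stop_lungvent("seed coordinates fall outside the image",
                  class = "lungvent_value_error")
  }
  seed_vals <- numeric(0)
  for (s in seq_len(nrow(seeds))) {
    xr <- max(1, seeds[s, 1] - 1):min(dims[1], seeds[s, 1] + 1)
    yr <- max(1, seeds[s, 2] - 1):min(dims[2], seeds[s, 2] + 1)
    zr <- max(1, seeds[s, 3] - 1):min(dims[3], seeds[s, 3] + 1)
    seed_vals <- c(seed_vals, as.vector(img[xr, yr, zr]))
  }
  mu <- mean(seed_vals)
  tol <- k * max(stats::sd(seed_vals), 0.2 * abs(mu))
  accept <- abs(img - mu) <= tol
  mask <- array(FALSE, dims)
  mask[seeds] <- TRUE
  offs <- neighbour_offsets()
  repeat {
    idx <- which(mask)
    ai <- arrayInd(idx, dims)
    frontier <- array(FALSE, dims)
    for (o in seq_len(nrow(offs))) {
      lin <- offset_indices(ai, offs[o, ], dims)
      lin <- lin[!is.na(lin)]
      frontier[lin] <- TRUE
    }
    frontier <- frontier & accept & !mask
    if (!any(frontier)) break
    mask <- mask | frontier
    if (sum(mask) > max_fraction * length(mask)) {
      stop_lungvent("region growing exceeded ", round(100 * max_fraction),
                    "% of the volume; seed is likely in background",
                    class = "lungvent_runaway_growth_error")
    }
  }
  fill_holes(mask)
}

#' Correct a smooth multiplicative bias field
#'
#' Contract: `corrected = image / field` with a smooth, strictly positive
#' field normalised to in-mask geometric mean 1. The default implementation
#' fits a polynomial of order `order` (default 2, all cross terms) to
#' log-intensity over the mask; in-mask voxels below 20% of the in-mask
#' median are left out of the fit, since near-zero (defect) intensities
#' carry no information about the field, and the fit is iteratively
#' trimmed: voxels falling well below the current field prediction
#' (ventilation defects rather than coil shading) are dropped and the
#' polynomial refitted. An external corrector can be swapped in behind the
#' same contract.
#'
#' @param image An [image_volume].
#' @param mask Logical 3D mask of the thoracic cavity.
#' @param order Polynomial order of the log-domain fit.
#' @param trim_iterations Number of trimming passes.
#' @param trim_log_residual Log-intensity shortfall below the fit at which
#'   a voxel is dropped from the next pass.
#' @return List with `corrected` and `field` ([image_volume]s).
#' @export
correct_bias_field <- function(image, mask, order = 2, trim_iterations = 3,
                               trim_log_residual = 0.2) {
  stopifnot(inherits(image, "image_volume"))
  if (!any(mask)) {
    stop_lungvent("mask is empty", class = "lungvent_empty_mask_error")
  }
  img <- image$data
  dims <- dim(img)
  med <- stats::median(img[mask])
  fit_mask <- mask & img > pmax(0.2 * med, 0)
  if (sum(fit_mask) < 20) {
    stop_lungvent("too few positive in-mask voxels for a bias fit",
                  class = "lungvent_bias_error")
  }
  design <- function(ai) {
    x <- (ai[, 1] - 1) / max(1, dims[1] - 1) - 0.5
    y <- (ai[, 2] - 1) / max(1, dims[2] - 1) - 0.5
    z <- (ai[, 3] - 1) / max(1, dims[3] - 1) - 0.5
    cols <- list(rep(1, nrow(ai)))
    if (order >= 1) cols <- c(cols, list(x, y, z))
    if (order >= 2) cols <- c(cols, list(x^2, y^2, z^2, x * y, x * z, y * z))
    if (order >= 3) {
      cols <- c(cols, list(x^3, y^3, z^3, x^2 * y, x^2 * z, y^2 * x,
                           y^2 * z, z^2 * x, z^2 * y, x * y * z))
    }
    do.call(cbind, cols)
  }
  ai_fit <- arrayInd(which(fit_mask), dims)
  X <- design(ai_fit)
  yv <- log(img[fit_mask])
  keep <- rep(TRUE, length(yv))
  fit <- NULL
  for (it in seq_len(trim_iterations + 1)) {
    fit <- tryCatch(stats::lm.fit(X[keep, , drop = FALSE], yv[keep]),
                    error = function(e) NULL)
    if (is.null(fit) || any(is.na(fit$coefficients))) {
      stop_lungvent("bias-field fit is singular",
                    class = "lungvent_bias_error")
    }
    if (it > trim_iterations) break
    resid_all <- yv - as.numeric(X %*% fit$coefficients)
    keep_new <- resid_all > -trim_log_residual
    if (sum(keep_new) < 20 || identical(keep_new, keep)) break
    keep <- keep_new
  }
  ai_all <- arrayInd(seq_along(img), dims)
  logf <- array(design(ai_all) %*% fit$coefficients, dims)
  logf <- logf - mean(logf[mask])  # geometric mean 1 in mask
  field <- exp(logf)
  corrected <- img / field
  list(corrected = image_volume(corrected, image$spacing, image$affine),
       field = image_volume(field, image$spacing, image$affine))
}

#' Classify normalised gas intensities into linear bins
#'
#' In-mask intensities are normalised by their 99th in-mask percentile
#' (values above 1 clipped), then each voxel is assigned the first bin
#' whose upper edge exceeds its normalised intensity. Bin 1 is the defect
#' class. Default edges partition `[0, 1]` into 6 bins with the lowest edge
#' at 0.16.
#'
#' @param image An [image_volume] (bias-corrected gas image).
#' @param mask Logical 3D mask.
#' @param edges Ascending upper bin edges in `(0, 1]`; the last edge must
#'   be 1.
#' @param normalization_percentile Percentile (0-1) used as the intensity
#'   anchor.
#' @return List of class `bin_map` with `labels` (integer bins, 0 outside
#'   mask), `n_bins`, `edges` and `normalized` (the normalised intensity
#'   array).
#' @export
linear_binning <- function(image, mask,
                           edges = c(0.16, 0.34, 0.52, 0.7, 0.88, 1),
                           normalization_percentile = 0.99) {
  stopifnot(inherits(image, "image_volume"))
  if (!any(mask)) {
    stop_lungvent("mask is empty", class = "lungvent_empty_mask_error")
  }
  edges <- as.numeric(edges)
  if (any(diff(edges) <= 0) || any(edges <= 0) || abs(edges[length(edges)] - 1) > 1e-9) {
    stop_lungvent("bin edges must be strictly increasing in (0, 1] ending at 1",
                  class = "lungvent_invalid_edges_error")
  }
  vals <- image$data[mask]
  anchor <- percentile_linear(vals, normalization_percentile)
  if (anchor <= 0) {
    stop_lungvent("normalisation anchor is non-positive",
                  class = "lungvent_value_error")
  }
  nv <- pmin(vals / anchor, 1)
  bins <- findInterval(nv, c(-Inf, edges[-length(edges)]), left.open = FALSE)
  labels <- array(0L, dim(image$data))
  labels[mask] <- as.integer(bins)
  norm <- array(NA_real_, dim(image$data))
  norm[mask] <- nv
  structure(list(labels = labels, n_bins = length(edges), edges = edges,
                 normalized = norm, mask = mask),
            class = "bin_map")
}

#' Gas ventilation defect percentage from a bin map
#'
#' `100 * (bin-1 voxels) / (in-mask voxels)`.
#'
#' @param bins A `bin_map` from [linear_binning()].
#' @return VDP in percent.
#' @export
compute_vdp_xe <- function(bins) {
  stopifnot(inherits(bins, "bin_map"))
  n <- sum(bins$mask)
  if (n == 0) {
    stop_lungvent("mask is empty", class = "lungvent_empty_mask_error")
  }
  100 * sum(bins$labels == 1L) / n
}

#' Convert a bin map to a defect map
#'
#' Bin 1 becomes defect, all higher bins healthy.
#'
#' @param bins A `bin_map` from [linear_binning()].
#' @param spacing Voxel spacing for the result.
#' @param affine Optional voxel-to-world affine.
#' @return A [defect_map] with source "Xe".
#' @export
xe_defect_map <- function(bins, spacing = c(1, 1, 1), affine = NULL) {
  stopifnot(inherits(bins, "bin_map"))
  lab <- array(label_codes[["outside"]], dim(bins$labels))
  lab[bins$mask] <- ifelse(bins$labels[bins$mask] == 1L,
                           label_codes[["defect"]], label_codes[["healthy"]])
  defect_map(lab, source = "Xe", spacing = spacing, affine = affine)
}

#' Run the full gas ventilation analysis
#'
#' Chains thoracic-cavity segmentation, bias-field correction, linear
#' binning and VDP computation.
#'
#' @param gas Gas ventilation [image_volume].
#' @param anatomical Same-breath anatomical [image_volume].
#' @param seeds Seed voxel coordinates for region growing.
#' @param edges Linear-binning edges.
#' @param bias_order Polynomial order of the bias fit.
#' @return List with `mask`, `corrected`, `field`, `bins`, `defect`
#'   ([defect_map]) and `vdp` (percent).
#' @export
xe_analysis <- function(gas, anatomical, seeds,
                        edges = c(0.16, 0.34, 0.52, 0.7, 0.88, 1),
                        bias_order = 2) {
  if (!identical(dim(gas$data), dim(anatomical$data))) {
    stop_lungvent("gas and anatomical grids differ",
                  class = "lungvent_shape_error")
  }
  mask <- segment_thoracic_cavity(anatomical, seeds)
  bc <- correct_bias_field(gas, mask, order = bias_order)
  bins <- linear_binning(bc$corrected, mask, edges = edges)
  dmap <- xe_defect_map(bins, spacing = gas$spacing, affine = gas$affine)
  list(mask = mask, corrected = bc$corrected, field = bc$field, bins = bins,
       defect = dmap, vdp = compute_vdp_xe(bins))
}
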
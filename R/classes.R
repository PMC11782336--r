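# S3 containers for image data. Volumes are plain numeric arrays in (x, y, z)
# order; the affine maps 0-based voxel indices to world millimetres.

default_affine <- function(spacing, origin = c(0, 0, 0)) {
  a <- diag(c(spacing, 1))
  a[1:3, 4] <- origin
  a
}

#' Construct a 3D image volume
#'
#' @param data 3D numeric array (x, y, z).
#' @param spacing Voxel spacing in mm, length 3, all positive.
#' @param affine Optional 4x4 voxel-to-world matrix (0-based voxel indices);
#'   defaults to a diagonal affine built from `spacing`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing, affine = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3) {
    stop_lungvent("image data must be a 3D array, got ",
                  length(dim(data)), " dims", class = "lungvent_dim_error")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop_lungvent("voxel spacing must be three positive numbers",
                  class = "lungvent_spacing_error")
  }
  if (any(!is.finite(data))) {
    stop_lungvent("image contains non-finite intensities",
                  class = "lungvent_value_error")
  }
  if (is.null(affine)) affine <- default_affine(spacing)
  structure(list(data = data, spacing = spacing, affine = affine),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' Construct a dynamic (3D+t) image series
#'
#' @param data 4D numeric array (x, y, z, frame).
#' @param spacing Voxel spacing in mm, length 3.
#' @param frame_times Acquisition time of each frame in seconds, strictly
#'   increasing.
#' @param lung_mask Logical 3D array marking lung parenchyma.
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(data, spacing, frame_times, lung_mask) {
  data <- as.array(data)
  if (length(dim(data)) != 4) {
    stop_lungvent("series data must be a 4D array (x, y, z, frame)",
                  class = "lungvent_dim_error")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0)) {
    stop_lungvent("voxel spacing must be three positive numbers",
                  class = "lungvent_spacing_error")
  }
  frame_times <- as.numeric(frame_times)
  if (length(frame_times) != dim(data)[4]) {
    stop_lungvent("frame_times length must equal the number of frames",
                  class = "lungvent_dim_error")
  }
  if (any(diff(frame_times) <= 0)) {
    stop_lungvent("frame times must be strictly increasing",
                  class = "lungvent_value_error")
  }
  lung_mask <- array(as.logical(lung_mask), dim = dim(data)[1:3])
  if (!identical(dim(lung_mask), dim(data)[1:3])) {
    stop_lungvent("lung mask shape must match the spatial shape",
                  class = "lungvent_dim_error")
  }
  structure(list(data = data, spacing = spacing, frame_times = frame_times,
                 lung_mask = lung_mask),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$data)
  cat("<dynamic_series> ", paste(d[1:3], collapse = " x "), " voxels, ",
      d[4], " frames, ", sum(x$lung_mask), " lung voxels\n", sep = "")
  invisible(x)
}

#' Construct a respiratory-phase-resolved series
#'
#' Holds a breathing cycle sorted into phase bins.
#'
#' @param data 4D numeric array (x, y, z, phase).
#' @param phase_grid Cycle fractions in `[0, 1)`, strictly increasing, one
#'   per phase bin.
#' @param lung_mask Logical 3D array.
#' @param occupancy Optional integer vector of frames averaged into each bin.
#' @return An object of class `phase_series`.
#' @export
phase_series <- function(data, phase_grid, lung_mask, occupancy = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 4) {
    stop_lungvent("phase data must be a 4D array (x, y, z, phase)",
                  class = "lungvent_dim_error")
  }
  n_phases <- dim(data)[4]
  if (n_phases < 1) {
    stop_lungvent("at least one respiratory phase is required",
                  class = "lungvent_value_error")
  }
  phase_grid <- as.numeric(phase_grid)
  if (length(phase_grid) != n_phases ||
      (n_phases > 1 && any(diff(phase_grid) <= 0)) ||
      any(phase_grid < 0) || any(phase_grid >= 1)) {
    stop_lungvent("phase_grid must be strictly increasing in [0, 1)",
                  class = "lungvent_value_error")
  }
  lung_mask <- array(as.logical(lung_mask), dim = dim(data)[1:3])
  structure(list(data = data, n_phases = n_phases, phase_grid = phase_grid,
                 lung_mask = lung_mask, occupancy = occupancy),
            class = "phase_series")
}

#' Construct a ventilation defect map
#'
#' @param labels Integer 3D array using [label_codes]: 0 outside, 1 healthy,
#'   2 defect, 3 excluded.
#' @param source Provenance, one of "RVent", "FVL-CM", "Combined", "Xe".
#' @param spacing Voxel spacing in mm.
#' @param affine Optional voxel-to-world affine.
#' @return An object of class `defect_map`.
#' @export
defect_map <- function(labels, source, spacing, affine = NULL) {
  labels <- array(as.integer(labels), dim = dim(labels))
  if (length(dim(labels)) != 3) {
    stop_lungvent("defect labels must form a 3D array",
                  class = "lungvent_dim_error")
  }
  if (!all(labels %in% label_codes)) {
    stop_lungvent("defect labels must use codes 0/1/2/3",
                  class = "lungvent_value_error")
  }
  source <- match.arg(source, c("RVent", "FVL-CM", "Combined", "Xe", "Truth"))
  spacing <- as.numeric(spacing)
  if (is.null(affine)) affine <- default_affine(spacing)
  structure(list(labels = labels, mask = labels != label_codes[["outside"]],
                 source = source, spacing = spacing, affine = affine),
            class = "defect_map")
}

#' @export
print.defect_map <- function(x, ...) {
  tab <- table(factor(x$labels[x$mask], levels = label_codes[-1],
                      labels = names(label_codes)[-1]))
  cat("<defect_map> source ", x$source, ", ",
      paste(dim(x$labels), collapse = " x "), " voxels: ",
      paste(names(tab), as.integer(tab), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Per-voxel ventilation map set
#'
#' @param rvent 3D numeric array of fractional ventilation values.
#' @param fvlcm 3D numeric array of flow-volume-loop correlations in
#'   `[-1, 1]`.
#' @param mask Logical 3D lung mask.
#' @param excluded Logical 3D array of voxels excluded from analysis.
#' @return An object of class `vent_maps`.
#' @export
vent_maps <- function(rvent, fvlcm, mask, excluded = NULL) {
  if (is.null(excluded)) excluded <- array(FALSE, dim(mask))
  ok <- mask & !excluded
  if (any(!is.finite(rvent[ok]))) {
    stop_lungvent("RVent must be finite inside the mask",
                  class = "lungvent_value_error")
  }
  if (any(fvlcm[ok] < -1 - 1e-9 | fvlcm[ok] > 1 + 1e-9)) {
    stop_lungvent("FVL-CM must lie in [-1, 1] inside the mask",
                  class = "lungvent_value_error")
  }
  structure(list(rvent = rvent, fvlcm = fvlcm, mask = mask,
                 excluded = excluded),
            class = "vent_maps")
}

#' Flow-volume loop
#'
#' A per-phase ventilation-volume trajectory `volume` and its cyclic
#' derivative `flow` with respect to the phase grid.
#'
#' @param volume Numeric vector of per-phase ventilation values.
#' @param flow Numeric vector, the discrete cyclic derivative of `volume`.
#' @param phase_grid Cycle fractions of the phases.
#' @return An object of class `flow_volume_loop`.
#' @export
flow_volume_loop <- function(volume, flow, phase_grid) {
  if (length(volume) != length(flow) || length(volume) != length(phase_grid)) {
    stop_lungvent("volume, flow and phase_grid must have equal length",
                  class = "lungvent_dim_error")
  }
  structure(list(volume = as.numeric(volume), flow = as.numeric(flow),
                 phase_grid = as.numeric(phase_grid)),
            class = "flow_volume_loop")
}
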
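# NIfTI and CSV I/O. Volumes round-trip data, spacing and affine; label
# maps are written as integer-coded NIfTI (0 outside, 1 healthy, 2 defect,
# 3 excluded); every artifact can carry a JSON sidecar with the config and
# seed that produced it.

nifti_with_geometry <- function(data, spacing, affine, time_step = NULL) {
  img <- RNifti::asNifti(data)
  pd <- spacing
  if (!is.null(time_step)) pd <- c(pd, time_step)
  RNifti::pixdim(img) <- pd
  RNifti::`sform<-`(img, structure(affine, code = 2L))
}

#' Write a 3D volume as NIfTI
#'
#' @param vol An [image_volume].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  RNifti::writeNifti(nifti_with_geometry(vol$data, vol$spacing, vol$affine),
                     path)
  invisible(path)
}

#' Read a 3D volume from NIfTI
#'
#' @param path NIfTI file path.
#' @return An [image_volume].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3) {
    stop_lungvent(path, ": expected a 3D volume, found ",
                  length(dim(img)), " dims", class = "lungvent_io_error")
  }
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop_lungvent(path, ": non-positive voxel spacing in header",
                  class = "lungvent_io_error")
  }
  data <- array(as.vector(img), dim(img))
  if (any(!is.finite(data))) {
    stop_lungvent(path, ": volume contains non-finite values",
                  class = "lungvent_io_error")
  }
  image_volume(data, spacing, affine = unclass(RNifti::xform(img))[1:4, 1:4])
}

#' Write a dynamic series as 4D NIfTI
#'
#' @param series A [dynamic_series].
#' @param path Output path.
#' @param mask_path Optional path for the lung mask volume.
#' @return The path, invisibly.
#' @export
write_series <- function(series, path, mask_path = NULL) {
  stopifnot(inherits(series, "dynamic_series"))
  dt <- if (length(series$frame_times) > 1) diff(series$frame_times)[1] else 1
  img <- nifti_with_geometry(series$data, series$spacing,
                             default_affine(series$spacing), time_step = dt)
  RNifti::writeNifti(img, path)
  if (!is.null(mask_path)) {
    write_volume(image_volume(array(as.numeric(series$lung_mask),
                                    dim(series$lung_mask)),
                              series$spacing), mask_path)
  }
  invisible(path)
}

#' Read a dynamic series from 4D NIfTI
#'
#' Frame times are reconstructed from the temporal pixdim; the lung mask is
#' read from a companion volume.
#'
#' @param path 4D NIfTI path.
#' @param mask_path Path of the lung-mask volume (non-zero = lung).
#' @return A [dynamic_series].
#' @export
read_series <- function(path, mask_path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4) {
    stop_lungvent(path, ": expected a 4D series, found ",
                  length(dim(img)), " dims", class = "lungvent_io_error")
  }
  pd <- RNifti::pixdim(img)
  spacing <- pd[1:3]
  dt <- if (length(pd) >= 4 && is.finite(pd[4]) && pd[4] > 0) pd[4] else 1
  mask <- read_volume(mask_path)
  dynamic_series(array(as.vector(img), dim(img)), spacing,
                 (seq_len(dim(img)[4]) - 1) * dt, mask$data != 0)
}

#' Write a defect map as integer-coded NIfTI
#'
#' @param d A [defect_map].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_defect_map <- function(d, path) {
  stopifnot(inherits(d, "defect_map"))
  RNifti::writeNifti(nifti_with_geometry(d$labels, d$spacing, d$affine), path)
  invisible(path)
}

#' Read a defect map from integer-coded NIfTI
#'
#' @param path NIfTI path with labels 0/1/2/3.
#' @param source Provenance label for the map.
#' @return A [defect_map].
#' @export
read_defect_map <- function(path, source) {
  vol <- read_volume(path)
  lab <- round(vol$data)
  defect_map(array(as.integer(lab), dim(lab)), source = source,
             spacing = vol$spacing, affine = vol$affine)
}

#' Read per-subject records from CSV
#'
#' Missing cells load as NA, never as zero.
#'
#' @param path CSV path with a header row.
#' @return Data frame of subject records.
#' @export
read_records <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
}

#' Write per-subject records to CSV
#'
#' @param records Data frame of subject records.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a JSON sidecar describing an artifact
#'
#' Records the configuration, seed and a config hash next to an output
#' file so runs are traceable and reproducible.
#'
#' @param config A configuration list.
#' @param path Path of the sidecar (conventionally `<artifact>.json`).
#' @return The path, invisibly.
#' @export
write_sidecar <- function(config, path) {
  payload <- list(config = config,
                  config_hash = config_hash(config),
                  package_version = as.character(utils::packageVersion("lungvent")),
                  written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

config_hash <- function(config) {
  s <- as.character(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA))
  # small stable polynomial hash; avoids a digest dependency
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
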
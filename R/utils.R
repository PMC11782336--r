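# Shared helpers: label codes, seeded evaluation, percentiles, small
# morphology on 3D arrays. All volumes use a fixed axis order (x, y, z) with
# the axial (head-foot) direction on the third axis.

#' Integer label codes used in all categorical volumes
#'
#' Defect maps code voxels as 0 = outside the mask, 1 = healthy, 2 = defect,
#' 3 = excluded. Agreement maps code 1 = both healthy, 2 = both defect,
#' 3 = defect in the first map only, 4 = defect in the second map only.
#'
#' @format A named integer vector.
#' @export
label_codes <- c(outside = 0L, healthy = 1L, defect = 2L, excluded = 3L)

agreement_codes <- c(both_healthy = 1L, both_defect = 2L,
                     a_only_defect = 3L, b_only_defect = 4L)

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not disturb the global stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Percentile with the linear-interpolation convention pinned package-wide
# (interpolation between order statistics; quantile type 7).
percentile_linear <- function(x, prob) {
  stats::quantile(x, probs = prob, type = 7, names = FALSE, na.rm = FALSE)
}

# 26-neighbourhood offsets (excluding the centre)
neighbour_offsets <- function(include_centre = FALSE) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  if (!include_centre) off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  off
}

# Linear indices of the neighbours of `idx` (linear indices into dims) for a
# single offset; returns NA where the neighbour falls outside the grid.
offset_indices <- function(ai, off, dims) {
  ni <- ai + rep(off, each = nrow(ai))
  ok <- ni[, 1] >= 1 & ni[, 1] <= dims[1] &
        ni[, 2] >= 1 & ni[, 2] <= dims[2] &
        ni[, 3] >= 1 & ni[, 3] <= dims[3]
  lin <- rep(NA_integer_, nrow(ai))
  lin[ok] <- ni[ok, 1] + (ni[ok, 2] - 1L) * dims[1] +
    (ni[ok, 3] - 1L) * dims[1] * dims[2]
  lin
}

# Dilate a logical 3D array by the 26-neighbourhood.
dilate26 <- function(mask) {
  dims <- dim(mask)
  out <- mask
  idx <- which(mask)
  if (length(idx) == 0) return(out)
  ai <- arrayInd(idx, dims)
  offs <- neighbour_offsets()
  for (o in seq_len(nrow(offs))) {
    lin <- offset_indices(ai, offs[o, ], dims)
    out[lin[!is.na(lin)]] <- TRUE
  }
  out
}

# Fill interior cavities: complement voxels not connected (6-connectivity)
# to the volume border are absorbed into the mask.
fill_holes <- function(mask) {
  dims <- dim(mask)
  outside <- array(FALSE, dims)
  comp <- !mask
  # seed with all border voxels of the complement
  border <- array(FALSE, dims)
  border[c(1, dims[1]), , ] <- TRUE
  border[, c(1, dims[2]), ] <- TRUE
  border[, , c(1, dims[3])] <- TRUE
  frontier <- comp & border
  offs <- matrix(c(1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1),
                 ncol = 3, byrow = TRUE)
  while (any(frontier)) {
    outside <- outside | frontier
    idx <- which(frontier)
    ai <- arrayInd(idx, dims)
    nxt <- array(FALSE, dims)
    for (o in seq_len(nrow(offs))) {
      lin <- offset_indices(ai, offs[o, ], dims)
      lin <- lin[!is.na(lin)]
      nxt[lin] <- TRUE
    }
    frontier <- nxt & comp & !outside
  }
  mask | (comp & !outside)
}

# In-mask 3x3x3 median filter: each in-mask voxel is replaced by the median
# of its in-mask neighbours (including itself); out-of-mask voxels are
# untouched and do not contribute. Missing neighbours (outside the grid or
# the mask) are replicate-padded with the centre voxel's own value, so the
# vote stays a full 27-sample median everywhere and mask faces are not
# dominated by their in-plane neighbours.
median_filter_mask <- function(v, mask, size = 3) {
  stopifnot(size %% 2 == 1)
  if (size == 1) return(v)
  dims <- dim(v)
  idx <- which(mask)
  if (length(idx) == 0) return(v)
  ai <- arrayInd(idx, dims)
  r <- (size - 1) / 2
  offs <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
  vals <- matrix(NA_real_, nrow = length(idx), ncol = nrow(offs))
  for (o in seq_len(nrow(offs))) {
    lin <- offset_indices(ai, offs[o, ], dims)
    ok <- !is.na(lin)
    ok[ok] <- mask[lin[ok]]
    vals[ok, o] <- v[lin[ok]]
  }
  centre <- v[idx]
  for (col in seq_len(ncol(vals))) {
    miss <- is.na(vals[, col])
    vals[miss, col] <- centre[miss]
  }
  out <- v
  out[idx] <- apply(vals, 1, stats::median)
  out
}

# Overlap weights between thin axial slices and thick output slabs.
# Returns an n_slab x nz matrix of overlap lengths in mm.
slab_overlap_weights <- function(nz, dz, slab_mm) {
  stopifnot(dz > 0, slab_mm > 0)
  n_slab <- ceiling(nz * dz / slab_mm)
  zl <- (seq_len(nz) - 1) * dz
  zh <- zl + dz
  w <- matrix(0, nrow = n_slab, ncol = nz)
  for (k in seq_len(n_slab)) {
    sl <- (k - 1) * slab_mm
    sh <- k * slab_mm
    w[k, ] <- pmax(0, pmin(zh, sh) - pmax(zl, sl))
  }
  w
}

stop_lungvent <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "lungvent_error")))
}
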
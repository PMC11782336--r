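# Regional agreement between two modalities' defect maps: slab-thickness
# matching, label coregistration, spatial overlap, Sorensen-Dice and the
# four-category agreement overlay.

#' Resample a defect map onto thick axial slabs
#'
#' Each output slab takes the overlap-weighted vote of the thin slices it
#' covers: a slab voxel is inside the mask if the weighted in-mask fraction
#' is at least 0.5, excluded if the weighted excluded fraction (among
#' in-mask contributions) is at least 0.5, and defect if the weighted
#' defect fraction among evaluable contributions reaches `majority`
#' (default 0.5). Partial geometric coverage is handled by the overlap
#' weights.
#'
#' @param d A [defect_map] on the thin-slice grid.
#' @param target_thickness_mm Output slab thickness; must be at least the
#'   source axial spacing.
#' @param majority Defect vote threshold in `(0, 1]`.
#' @return A [defect_map] on the slab grid.
#' @export
resample_to_slabs <- function(d, target_thickness_mm = 15, majority = 0.5) {
  stopifnot(inherits(d, "defect_map"))
  dz <- d$spacing[3]
  if (target_thickness_mm < dz) {
    stop_lungvent("target thickness must be >= the source axial spacing",
                  class = "lungvent_value_error")
  }
  dims <- dim(d$labels)
  w <- slab_overlap_weights(dims[3], dz, target_thickness_mm)
  n_slab <- nrow(w)
  lab2 <- matrix(d$labels, nrow = dims[1] * dims[2], ncol = dims[3])
  in_mask <- matrix(as.numeric(lab2 != label_codes[["outside"]]),
                    nrow = nrow(lab2))
  excl <- matrix(as.numeric(lab2 == label_codes[["excluded"]]),
                 nrow = nrow(lab2))
  defect <- matrix(as.numeric(lab2 == label_codes[["defect"]]),
                   nrow = nrow(lab2))
  evaluable <- in_mask - excl

  tw <- colSums(t(w))  # total in-volume weight per slab
  wm <- in_mask %*% t(w)
  wx <- excl %*% t(w)
  wd <- defect %*% t(w)
  we <- evaluable %*% t(w)

  out <- matrix(label_codes[["outside"]], nrow = nrow(lab2), ncol = n_slab)
  inside <- sweep(wm, 2, tw, "/") >= 0.5
  excl_s <- inside & (wx >= 0.5 * wm)
  def_s <- inside & !excl_s & we > 0 & (wd / pmax(we, .Machine$double.eps)
                                        >= majority)
  heal_s <- inside & !excl_s & !def_s
  out[heal_s] <- label_codes[["healthy"]]
  out[def_s] <- label_codes[["defect"]]
  out[excl_s] <- label_codes[["excluded"]]

  aff <- d$affine
  aff[3, 3] <- aff[3, 3] * target_thickness_mm / dz
  defect_map(array(out, c(dims[1], dims[2], n_slab)), source = d$source,
             spacing = c(d$spacing[1:2], target_thickness_mm), affine = aff)
}

#' Coregister a defect map onto a fixed grid
#'
#' Resamples the moving map's labels onto the fixed volume's grid via the
#' affine relation between the two spaces (nearest-neighbour for labels).
#' Optionally refines an axial integer translation to maximise mask
#' overlap. The applied transform is attached as attribute `"transform"`.
#'
#' @param moving A [defect_map] with a valid affine.
#' @param fixed An [image_volume] (or [defect_map]) defining the target
#'   grid.
#' @param refine_translation Search integer axial offsets (+-2 voxels) that
#'   maximise mask overlap.
#' @return A [defect_map] on the fixed grid.
#' @export
coregister <- function(moving, fixed, refine_translation = FALSE) {
  stopifnot(inherits(moving, "defect_map"))
  fixed_affine <- if (inherits(fixed, "image_volume")) fixed$affine else fixed$affine
  fixed_dim <- if (inherits(fixed, "image_volume")) dim(fixed$data) else dim(fixed$labels)
  rel <- tryCatch(solve(moving$affine) %*% fixed_affine,
                  error = function(e) NULL)
  if (is.null(rel)) {
    stop_lungvent("moving affine is not invertible",
                  class = "lungvent_geometry_error")
  }
  ai <- arrayInd(seq_len(prod(fixed_dim)), fixed_dim) - 1L
  src <- cbind(ai, 1) %*% t(rel)

  sample_labels <- function(zshift) {
    sv <- round(src[, 1:3])
    sv[, 3] <- sv[, 3] + zshift
    ok <- sv[, 1] >= 0 & sv[, 1] < dim(moving$labels)[1] &
          sv[, 2] >= 0 & sv[, 2] < dim(moving$labels)[2] &
          sv[, 3] >= 0 & sv[, 3] < dim(moving$labels)[3]
    lab <- rep(label_codes[["outside"]], nrow(sv))
    lin <- sv[ok, 1] + 1L + sv[ok, 2] * dim(moving$labels)[1] +
      sv[ok, 3] * dim(moving$labels)[1] * dim(moving$labels)[2]
    lab[ok] <- moving$labels[lin]
    lab
  }

  shift <- 0
  if (refine_translation) {
    fixed_mask <- if (inherits(fixed, "defect_map")) {
      as.vector(fixed$labels != label_codes[["outside"]])
    } else NULL
    if (!is.null(fixed_mask)) {
      scores <- vapply(-2:2, function(s) {
        sum((sample_labels(s) != label_codes[["outside"]]) & fixed_mask)
      }, numeric(1))
      shift <- (-2:2)[which.max(scores)]
    }
  }
  lab <- sample_labels(shift)
  out <- defect_map(array(lab, fixed_dim), source = moving$source,
                    spacing = moving$spacing, affine = fixed_affine)
  attr(out, "transform") <- list(relative_affine = rel, z_shift = shift)
  out
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a$labels), dim(b$labels))) {
    stop_lungvent("defect maps are on different grids",
                  class = "lungvent_shape_error")
  }
}

evaluable_voxels <- function(a, b) {
  ok <- function(l) l == label_codes[["healthy"]] | l == label_codes[["defect"]]
  ok(a$labels) & ok(b$labels)
}

#' Spatial overlap of two defect maps
#'
#' The percentage of evaluable voxels (healthy-or-defect in both maps) on
#' which the two maps agree: both defect or both healthy.
#'
#' @param a,b [defect_map]s on the same grid.
#' @return Overlap percentage in `[0, 100]`.
#' @export
spatial_overlap <- function(a, b) {
  check_same_grid(a, b)
  ev <- evaluable_voxels(a, b)
  n <- sum(ev)
  if (n == 0) {
    stop_lungvent("no evaluable voxels shared by both maps",
                  class = "lungvent_empty_evaluation_error")
  }
  agree <- sum(a$labels[ev] == b$labels[ev])
  100 * agree / n
}

#' Sorensen-Dice coefficient of a label class
#'
#' `2 |A intersect B| / (|A| + |B|)` over evaluable voxels of class `cls`;
#' defined as 1 when both sets are empty and 0 when exactly one is empty.
#'
#' @param a,b [defect_map]s on the same grid.
#' @param cls "defect" or "healthy".
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b, cls = c("defect", "healthy")) {
  check_same_grid(a, b)
  cls <- match.arg(cls)
  code <- label_codes[[cls]]
  ev <- evaluable_voxels(a, b)
  A <- a$labels == code & ev
  B <- b$labels == code & ev
  na <- sum(A); nb <- sum(B)
  if (na + nb == 0) return(1)
  2 * sum(A & B) / (na + nb)
}

#' Full regional agreement of two defect maps
#'
#' One-pass computation of the four-category agreement map (both healthy,
#' both defect, defect in `a` only, defect in `b` only over the evaluable
#' set) and the scalar agreement metrics, which equal the standalone
#' [spatial_overlap()] and [dice()] results.
#'
#' @param a,b [defect_map]s on the same grid.
#' @return An object of class `agreement_result` with fields
#'   `spatial_overlap_pct`, `dice_healthy`, `dice_defect`, `agreement_map`
#'   (integer codes 0 outside evaluable, 1 both healthy, 2 both defect,
#'   3 a-only defect, 4 b-only defect), `category_counts` and
#'   `n_evaluable`.
#' @export
agreement_overlay <- function(a, b) {
  check_same_grid(a, b)
  ev <- evaluable_voxels(a, b)
  n <- sum(ev)
  if (n == 0) {
    stop_lungvent("no evaluable voxels shared by both maps",
                  class = "lungvent_empty_evaluation_error")
  }
  ad <- a$labels == label_codes[["defect"]]
  bd <- b$labels == label_codes[["defect"]]
  cmap <- array(0L, dim(a$labels))
  cmap[ev & !ad & !bd] <- agreement_codes[["both_healthy"]]
  cmap[ev & ad & bd] <- agreement_codes[["both_defect"]]
  cmap[ev & ad & !bd] <- agreement_codes[["a_only_defect"]]
  cmap[ev & !ad & bd] <- agreement_codes[["b_only_defect"]]
  counts <- vapply(agreement_codes, function(code) sum(cmap == code),
                   numeric(1))
  na <- sum(ad & ev); nb <- sum(bd & ev)
  dice_d <- if (na + nb == 0) 1 else 2 * counts[["both_defect"]] / (na + nb)
  ha <- n - na; hb <- n - nb
  dice_h <- if (ha + hb == 0) 1 else 2 * counts[["both_healthy"]] / (ha + hb)
  structure(list(
    spatial_overlap_pct = 100 * (counts[["both_healthy"]] +
                                 counts[["both_defect"]]) / n,
    dice_healthy = dice_h,
    dice_defect = dice_d,
    agreement_map = cmap,
    category_counts = counts,
    n_evaluable = n), class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "<agreement_result> overlap %.1f%%, Dice healthy %.3f, Dice defect %.3f (n = %d)\n",
    x$spatial_overlap_pct, x$dice_healthy, x$dice_defect, x$n_evaluable))
  invisible(x)
}
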
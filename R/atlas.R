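# Canonical functional units used throughout; cortical_motor first so that
# default assignments favour the unit carrying the planted disease effect.
UNIT_LEVELS <- c("cortical_motor", "subcortical", "cerebellar",
                 "frontal", "parietal", "occipital", "temporal")

#' Build a toy label atlas
#'
#' Partitions a 3D grid into \code{n_rois} contiguous parcels (consecutive
#' runs in the flattened voxel order, i.e. blocks along the fastest-varying
#' axis) and assigns each parcel to a functional unit. The atlas stands in
#' for an anatomical parcellation (AAL-style): an integer label volume plus a
#' lookup table mapping region ids to names and lobule/functional units.
#'
#' The construction is fully deterministic: no random number generation is
#' involved, so two calls with the same arguments return identical volumes.
#'
#' @param n_rois Number of regions (>= 2).
#' @param grid_shape Integer vector of length 3; the label volume dimensions.
#' @param unit_assignment Named integer vector mapping unit names (a subset of
#'   \code{cortical_motor, subcortical, cerebellar, frontal, parietal,
#'   occipital, temporal}) to region counts summing to \code{n_rois}. When
#'   \code{NULL}, regions are spread as evenly as possible over all seven
#'   units, earlier units (cortical_motor first) receiving the remainder.
#'
#' @return An object of class \code{toy_atlas}: list with \code{label_volume}
#'   (3D integer array, 0 = background), \code{roi_table} (data.frame with
#'   \code{roi_id}, \code{name}, \code{unit}), and \code{voxel_counts}
#'   (named integer vector).
#' @export
make_toy_atlas <- function(n_rois, grid_shape, unit_assignment = NULL) {
  stopifnot(length(grid_shape) == 3, n_rois >= 2)
  grid_shape <- as.integer(grid_shape)
  n_vox <- prod(grid_shape)
  if (n_vox < 8L * n_rois)
    stop("grid too small: need at least 8 voxels per ROI (",
         8L * n_rois, " > ", n_vox, ")")

  if (is.null(unit_assignment)) {
    base <- n_rois %/% length(UNIT_LEVELS)
    rem <- n_rois %% length(UNIT_LEVELS)
    unit_assignment <- stats::setNames(
      rep(base, length(UNIT_LEVELS)) + c(rep(1L, rem),
                                         rep(0L, length(UNIT_LEVELS) - rem)),
      UNIT_LEVELS)
    unit_assignment <- unit_assignment[unit_assignment > 0L]
  }
  if (!all(names(unit_assignment) %in% UNIT_LEVELS))
    stop("unknown unit(s): ",
         paste(setdiff(names(unit_assignment), UNIT_LEVELS), collapse = ", "))
  if (sum(unit_assignment) != n_rois)
    stop("unit_assignment counts must sum to n_rois")

  # near-equal contiguous runs over the flattened grid
  sizes <- rep(n_vox %/% n_rois, n_rois)
  sizes[seq_len(n_vox %% n_rois)] <- sizes[seq_len(n_vox %% n_rois)] + 1L
  labels <- rep.int(seq_len(n_rois), sizes)
  vol <- array(as.integer(labels), dim = grid_shape)

  units <- rep(names(unit_assignment), times = unit_assignment)
  roi_table <- data.frame(
    roi_id = seq_len(n_rois),
    name = sprintf("%s_%02d", units, stats::ave(seq_along(units), units,
                                                FUN = seq_along)),
    unit = units,
    stringsAsFactors = FALSE)

  structure(
    list(label_volume = vol,
         roi_table = roi_table,
         voxel_counts = stats::setNames(as.integer(sizes), seq_len(n_rois))),
    class = "toy_atlas")
}

#' @export
print.toy_atlas <- function(x, ...) {
  cat("toy_atlas:", nrow(x$roi_table), "ROIs on grid",
      paste(dim(x$label_volume), collapse = "x"), "\n")
  print(table(x$roi_table$unit))
  invisible(x)
}

#' Region centroids in world coordinates
#'
#' Unweighted means of 0-based voxel indices per region, mapped through the
#' supplied affine (voxel-to-world, 4x4). Used for connectome node export.
#'
#' @param atlas A \code{toy_atlas} (or a 3D integer label volume).
#' @param affine 4x4 voxel-to-world matrix; default identity.
#' @return Matrix with one row per ROI (ordered by roi_id), columns x, y, z.
#' @export
roi_centroids <- function(atlas, affine = diag(4)) {
  vol <- if (inherits(atlas, "toy_atlas")) atlas$label_volume else atlas
  ids <- sort(unique(as.vector(vol)))
  ids <- ids[ids > 0]
  idx <- arrayInd(which(vol > 0), dim(vol)) - 1L   # 0-based
  lab <- vol[vol > 0]
  cent <- apply(idx, 2, function(col) tapply(col, lab, mean))
  cent <- matrix(cent, ncol = 3, dimnames = list(ids, c("x", "y", "z")))
  world <- cbind(cent, 1) %*% t(affine)
  world[, 1:3, drop = FALSE]
}

# internal: validate atlas invariants (ids unique, positive, present in volume)
check_atlas <- function(atlas) {
  ids <- atlas$roi_table$roi_id
  stopifnot(all(ids > 0), !anyDuplicated(ids))
  in_vol <- sort(unique(as.vector(atlas$label_volume)))
  in_vol <- in_vol[in_vol > 0]
  if (!setequal(in_vol, ids))
    stop("atlas roi_table and label volume disagree on region ids")
  invisible(TRUE)
}
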
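#' Wrap a 4D array as a subject scan
#'
#' @param data 4D numeric array (x, y, z, frames).
#' @param modality \code{"fpet"} or \code{"fmri"}.
#' @param subject_id Subject identifier.
#' @param frame_duration_s Frame duration in seconds (60 for one-minute PET
#'   frames, 1.04 for the BOLD repetition time).
#' @param brain_mask 3D logical array; defaults to all voxels. Typically the
#'   union of atlas labels via \code{\link{atlas_mask}}.
#' @return Object of class \code{subject_scan}.
#' @export
subject_scan <- function(data, modality = c("fpet", "fmri"),
                         subject_id = "sub-01",
                         frame_duration_s = if (modality == "fpet") 60 else 1.04,
                         brain_mask = NULL) {
  modality <- match.arg(modality)
  stopifnot(length(dim(data)) == 4, dim(data)[4] >= 1)
  if (is.null(brain_mask))
    brain_mask <- array(TRUE, dim(data)[1:3])
  stopifnot(identical(dim(brain_mask), dim(data)[1:3]), any(brain_mask))
  structure(list(data = data, modality = modality, subject_id = subject_id,
                 frame_duration_s = frame_duration_s,
                 brain_mask = brain_mask),
            class = "subject_scan")
}

#' Brain mask from an atlas (union of all labels)
#' @param atlas A \code{toy_atlas} or 3D integer label volume.
#' @return 3D logical array.
#' @export
atlas_mask <- function(atlas) {
  vol <- if (inherits(atlas, "toy_atlas")) atlas$label_volume else atlas
  vol > 0
}

#' Retain the final frames of a dynamic series
#'
#' Early constant-infusion PET frames carry low signal; analyses operate on
#' the trailing window (default: the last 30 of 90 one-minute frames).
#'
#' @param x A \code{subject_scan} or \code{roi_series}.
#' @param keep_last Number of trailing frames to keep.
#' @return Same class as \code{x}, frames truncated, order preserved.
#' @export
retain_frames <- function(x, keep_last = 30L) UseMethod("retain_frames")

#' @export
retain_frames.subject_scan <- function(x, keep_last = 30L) {
  n <- dim(x$data)[4]
  if (keep_last > n)
    stop("keep_last (", keep_last, ") exceeds available frames (", n, ")")
  x$data <- x$data[, , , (n - keep_last + 1):n, drop = FALSE]
  x
}

#' @export
retain_frames.roi_series <- function(x, keep_last = 30L) {
  n <- ncol(x$values)
  if (keep_last > n)
    stop("keep_last (", keep_last, ") exceeds available frames (", n, ")")
  x$values <- x$values[, (n - keep_last + 1):n, drop = FALSE]
  x
}

#' Global-mean intensity normalization
#'
#' Divides every frame by its own in-mask mean, so each frame's in-mask mean
#' becomes exactly 1. Idempotent; out-of-mask voxels never influence in-mask
#' values. For region series the global mean is the voxel-count-weighted mean
#' over regions (identical to the volumetric global mean when the mask is the
#' atlas union).
#'
#' @param x A \code{subject_scan} or \code{roi_series}.
#' @param voxel_counts For the \code{roi_series} method: per-region voxel
#'   counts used as weights.
#' @return Same class as \code{x}, normalized (flag set for series).
#' @export
global_mean_normalize <- function(x, ...) UseMethod("global_mean_normalize")

#' @rdname global_mean_normalize
#' @param ... Passed to methods.
#' @export
global_mean_normalize.subject_scan <- function(x, ...) {
  dims <- dim(x$data)
  mat <- matrix(x$data, prod(dims[1:3]), dims[4])
  mask <- as.vector(x$brain_mask)
  gm <- colMeans(mat[mask, , drop = FALSE])
  if (any(gm == 0))
    stop("zero in-mask global mean in frame(s) ",
         paste(which(gm == 0), collapse = ", "))
  x$data <- array(sweep(mat, 2, gm, "/"), dim = dims)
  x
}

#' @rdname global_mean_normalize
#' @export
global_mean_normalize.roi_series <- function(x, voxel_counts, ...) {
  stopifnot(length(voxel_counts) == nrow(x$values))
  w <- voxel_counts / sum(voxel_counts)
  gm <- as.numeric(crossprod(w, x$values))
  if (any(gm == 0)) stop("zero weighted global mean in a frame")
  x$values <- sweep(x$values, 2, gm, "/")
  x$normalized <- TRUE
  x
}

#' Remove the per-voxel linear trend of a dynamic series
#'
#' Ordinary least-squares detrending of every voxel (or region) series
#' within the scan: the standard way to remove the slowly rising
#' constant-infusion uptake baseline before decomposition analyses, leaving
#' the metabolic fluctuations. (For correlation analyses the global-mean
#' normalization pathway is used instead; Pearson correlation is invariant
#' to each series' own location and scale.)
#'
#' @param x A \code{subject_scan}, \code{roi_series}, or frames x voxels
#'   matrix.
#' @return Same class as \code{x} with each series' linear trend removed.
#' @export
detrend_frames <- function(x) UseMethod("detrend_frames")

detrend_mat <- function(m) {   # frames x series
  tt <- seq_len(nrow(m))
  stats::lm.fit(cbind(1, tt), m)$residuals
}

#' @export
detrend_frames.subject_scan <- function(x) {
  dims <- dim(x$data)
  mat <- t(matrix(x$data, prod(dims[1:3]), dims[4]))
  x$data <- array(t(detrend_mat(mat)), dim = dims)
  x
}

#' @export
detrend_frames.roi_series <- function(x) {
  x$values <- t(detrend_mat(t(x$values)))
  x
}

#' @export
detrend_frames.matrix <- function(x) detrend_mat(x)

#' Sum a dynamic scan into a static image
#'
#' Voxelwise sum over the scan's current frames (i.e. after any frame
#' retention applied upstream); the static-PET analogue of a summed uptake
#' image.
#'
#' @param scan A \code{subject_scan}.
#' @return 3D array.
#' @export
sum_frames <- function(scan) {
  stopifnot(inherits(scan, "subject_scan"))
  apply(scan$data, 1:3, sum)
}

#' Extract region-by-frame signal series
#'
#' Entry (i, t) is the unweighted arithmetic mean over voxels labelled with
#' the i-th region id at frame t (MarsBaR-equivalent behaviour; no
#' partial-volume weighting). Row order follows the atlas roi_table.
#'
#' @param scan A \code{subject_scan}.
#' @param atlas A \code{toy_atlas} or 3D integer label volume.
#' @return Object of class \code{roi_series}: list with \code{values}
#'   (ROI x frame matrix), \code{roi_ids}, \code{modality},
#'   \code{subject_id}, \code{normalized}.
#' @export
extract_roi_series <- function(scan, atlas) {
  stopifnot(inherits(scan, "subject_scan"))
  vol <- if (inherits(atlas, "toy_atlas")) atlas$label_volume else atlas
  roi_ids <- if (inherits(atlas, "toy_atlas")) atlas$roi_table$roi_id else {
    u <- sort(unique(as.vector(vol))); u[u > 0]
  }
  if (!identical(dim(vol), dim(scan$data)[1:3]))
    stop("atlas spatial shape ", paste(dim(vol), collapse = "x"),
         " does not match scan ", paste(dim(scan$data)[1:3], collapse = "x"))
  lab <- as.vector(vol)
  present <- unique(lab[lab > 0])
  missing <- setdiff(roi_ids, present)
  if (length(missing))
    stop("region id(s) absent from label volume: ",
         paste(missing, collapse = ", "))
  dims <- dim(scan$data)
  mat <- matrix(scan$data, prod(dims[1:3]), dims[4])
  inb <- lab > 0
  sums <- rowsum(mat[inb, , drop = FALSE], lab[inb])
  counts <- as.vector(table(lab[inb]))
  means <- sums / counts
  means <- means[match(roi_ids, as.integer(rownames(sums))), , drop = FALSE]
  structure(list(values = unname(means), roi_ids = roi_ids,
                 modality = scan$modality, subject_id = scan$subject_id,
                 normalized = FALSE),
            class = "roi_series")
}

#' Assemble a roi_series object from a matrix
#'
#' Convenience constructor for series-mode cohorts and tests.
#' @param values ROI x frame matrix.
#' @param roi_ids Region ids (row order).
#' @param modality,subject_id,normalized Metadata fields.
#' @return A \code{roi_series}.
#' @export
roi_series <- function(values, roi_ids = seq_len(nrow(values)),
                       modality = "fpet", subject_id = "sub-01",
                       normalized = FALSE) {
  stopifnot(is.matrix(values), !anyNA(values),
            length(roi_ids) == nrow(values))
  structure(list(values = values, roi_ids = roi_ids, modality = modality,
                 subject_id = subject_id, normalized = normalized),
            class = "roi_series")
}

#' Per-group static uptake table
#'
#' Builds the subject-by-region matrix of summed (retained, normalized)
#' uptake for one group: the input to static metabolic covariance. By
#' default the same retained window feeds both the static and the dynamic
#' analysis so the two PET constructions see identical data.
#'
#' @param series_list List of per-subject \code{roi_series} (already
#'   retained/normalized as configured).
#' @param group Group label.
#' @return Object of class \code{static_uptake}: subject x ROI matrix with
#'   attributes \code{group} and \code{roi_ids}.
#' @export
static_uptake <- function(series_list, group = "group") {
  stopifnot(length(series_list) >= 1)
  ids <- series_list[[1]]$roi_ids
  for (s in series_list)
    if (!identical(s$roi_ids, ids)) stop("roi_id mismatch across subjects")
  m <- t(vapply(series_list, function(s) rowSums(s$values),
                numeric(length(ids))))
  rownames(m) <- vapply(series_list, function(s) s$subject_id, character(1))
  colnames(m) <- ids
  structure(m, group = group, roi_ids = ids, class = "static_uptake")
}
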
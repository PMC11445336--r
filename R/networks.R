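#' Temporally concatenate a group's series for spatial ICA
#'
#' Stacks per-subject (frames x voxels) matrices row-wise in subject order,
#' recording per-subject frame offsets. Accepts \code{subject_scan}s (in-mask
#' voxels become columns), plain frames-by-voxel matrices, or
#' \code{roi_series} (regions play the role of voxels).
#'
#' @param series_list List of scans / matrices / roi_series sharing one
#'   spatial shape and mask.
#' @param mask Optional 3D logical mask applied to \code{subject_scan}
#'   inputs; defaults to the first scan's mask.
#' @param center_subjects Subtract each subject's per-voxel temporal mean
#'   before stacking (default TRUE): standard for temporal-concatenation
#'   group ICA, so between-subject baseline offsets do not masquerade as
#'   temporal components.
#' @return List with \code{data} (frames_total x voxels), \code{offsets}
#'   (cumulative starting row per subject), \code{mask}.
#' @export
concatenate_group <- function(series_list, mask = NULL,
                              center_subjects = TRUE) {
  stopifnot(length(series_list) >= 1)
  to_mat <- function(x) {
    if (inherits(x, "subject_scan")) {
      if (is.null(mask)) mask <<- x$brain_mask
      if (!identical(dim(x$brain_mask), dim(mask)))
        stop("mask shape mismatch across subjects")
      dims <- dim(x$data)
      t(matrix(x$data, prod(dims[1:3]), dims[4])[as.vector(mask), ,
                                                 drop = FALSE])
    } else if (inherits(x, "roi_series")) {
      t(x$values)
    } else as.matrix(x)
  }
  mats <- lapply(series_list, to_mat)
  if (center_subjects)
    mats <- lapply(mats, function(m) sweep(m, 2, colMeans(m)))
  p <- unique(vapply(mats, ncol, integer(1)))
  if (length(p) != 1) stop("voxel dimension mismatch across subjects")
  frames <- vapply(mats, nrow, integer(1))
  list(data = do.call(rbind, mats),
       offsets = cumsum(c(1L, frames[-length(frames)])),
       frames = frames,
       mask = mask)
}

# One symmetric FastICA pass on whitened data Z (k x voxels, rows
# uncorrelated, unit variance): logcosh contrast with symmetric
# decorrelation, all components updated in parallel. Returns the
# orthonormal unmixing matrix W (k x k) or NULL on non-convergence.
fastica_parallel <- function(Z, k, max_iter = 500, tol = 1e-7) {
  p <- ncol(Z)
  sym_decor <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decor(matrix(stats::rnorm(k * nrow(Z)), k))
  for (it in seq_len(max_iter)) {
    WX <- W %*% Z
    G <- tanh(WX)
    W1 <- sym_decor(tcrossprod(G, Z) / p - diag(rowMeans(1 - G^2)) %*% W)
    conv <- max(abs(abs(diag(tcrossprod(W1, W))) - 1))
    W <- W1
    if (conv < tol) return(W)
  }
  NULL
}

#' Group spatial independent component analysis
#'
#' Single-stage PCA reduction of the temporally concatenated data to
#' \code{n_components} dimensions (whitening), followed by symmetric
#' (parallel-update) FastICA with the logcosh contrast, maximizing spatial
#' non-Gaussianity. Spatial maps are z-scored over (in-mask) voxels and sign
#' is fixed so each map's spatial skewness is nonnegative, removing the ICA
#' sign ambiguity. Up to \code{restarts} seeded restarts are attempted on
#' non-convergence.
#'
#' @param data frames_total x voxels matrix (e.g. from
#'   \code{\link{concatenate_group}}), or the list that function returns.
#' @param n_components Number of components (the study analyses use 10).
#' @param seed Integer seed controlling the (deterministic) ICA restarts.
#' @param group,modality Labels carried through to the result.
#' @param max_iter,tol,restarts FastICA iteration controls.
#' @return Object of class \code{component_maps}: \code{maps} (component x
#'   voxel, z-scored), \code{mixing} (frames x component), \code{n_components},
#'   \code{group}, \code{modality}, \code{seed}, \code{converged}.
#' @export
group_spatial_ica <- function(data, n_components = 10L, seed = 1L,
                              group = "group", modality = "fpet",
                              max_iter = 500L, tol = 1e-7, restarts = 5L) {
  if (is.list(data) && !is.null(data$data)) data <- data$data
  stopifnot(is.matrix(data))
  n <- nrow(data); p <- ncol(data)
  if (n_components > min(n, p))
    stop("n_components exceeds min(frames_total, voxels)")

  X <- sweep(data, 2, colMeans(data))          # center each voxel over time
  # economy PCA: eigen-decompose the smaller Gram matrix
  if (n <= p) {
    G <- tcrossprod(X) / p
    eg <- eigen(G, symmetric = TRUE)
    keep <- seq_len(n_components)
    U <- eg$vectors[, keep, drop = FALSE]
    d <- sqrt(pmax(eg$values[keep], .Machine$double.eps))
    Z <- crossprod(U, X) / d                   # k x voxels, rows whitened
  } else {
    # voxel-space Gram matrix route: right singular vectors are the
    # whitened spatial patterns directly
    C <- crossprod(X)
    eg <- eigen(C, symmetric = TRUE)
    keep <- seq_len(n_components)
    V <- eg$vectors[, keep, drop = FALSE]
    Z <- t(V) * sqrt(p)              # k x voxels, rows whitened
  }

  W <- NULL
  for (r in seq_len(restarts)) {
    set.seed(as.integer((seed + 7907 * (r - 1)) %% 2147483647))
    W <- fastica_parallel(Z, n_components, max_iter, tol)
    if (!is.null(W)) break
  }
  if (is.null(W))
    stop("FastICA failed to converge after ", restarts, " restarts")

  S <- W %*% Z                                 # component x voxel maps
  S <- (S - rowMeans(S)) / sqrt(apply(S, 1, stats::var) * (p - 1) / p)
  skew <- rowMeans(S^3)
  flip <- ifelse(skew < 0, -1, 1)
  S <- S * flip
  mixing <- X %*% t(S) %*% solve(tcrossprod(S))   # least-squares time courses

  structure(list(maps = S, mixing = mixing, n_components = n_components,
                 group = group, modality = modality, seed = seed,
                 converged = TRUE),
            class = "component_maps")
}

#' Threshold a spatial component into a network mask
#'
#' One-sided positive threshold on the z-scored spatial map (figures display
#' positive-z clusters). The default z = 1.5 matches the standard component
#' threshold; z = 1 is the documented choice for the sensorimotor component.
#'
#' @param maps A \code{component_maps}.
#' @param component 1-based component index.
#' @param z Threshold.
#' @param mask_dim Optional 3D dims to reshape the voxel vector into a
#'   volume; when the ICA ran on masked voxels, supply \code{mask} instead.
#' @param mask Optional 3D logical mask the voxel columns correspond to.
#' @return Object of class \code{network_mask}: \code{mask} (logical vector
#'   or 3D array), \code{threshold_z}, \code{source_component}.
#' @export
threshold_component <- function(maps, component, z = 1.5,
                                mask_dim = NULL, mask = NULL) {
  stopifnot(inherits(maps, "component_maps"))
  if (component < 1 || component > maps$n_components)
    stop("component index out of range 1..", maps$n_components)
  sel <- maps$maps[component, ] > z
  out <- sel
  if (!is.null(mask)) {
    vol <- array(FALSE, dim(mask))
    vol[mask] <- sel
    out <- vol
  } else if (!is.null(mask_dim)) {
    out <- array(sel, mask_dim)
  }
  structure(list(mask = out, threshold_z = z, source_component = component),
            class = "network_mask")
}

#' Parcellate a network mask against an atlas
#'
#' Returns the region ids whose fraction of voxels inside the mask is at
#' least \code{min_fraction}, sorted by roi_id. Resolves which parcels a
#' thresholded component engages (e.g. identifying motor-network regions).
#'
#' @param mask A \code{network_mask} (volume form) or 3D logical array.
#' @param atlas A \code{toy_atlas} or label volume.
#' @param min_fraction Minimum in-mask voxel fraction (default 0.1).
#' @return Integer vector of region ids (possibly empty).
#' @export
parcellate_mask <- function(mask, atlas, min_fraction = 0.1) {
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  m <- if (inherits(mask, "network_mask")) mask$mask else mask
  vol <- if (inherits(atlas, "toy_atlas")) atlas$label_volume else atlas
  stopifnot(identical(dim(m), dim(vol)))
  lab <- as.vector(vol); inb <- lab > 0
  tot <- table(lab[inb])
  hit <- table(factor(lab[inb & as.vector(m)], levels = names(tot)))
  frac <- as.vector(hit) / as.vector(tot)
  ids <- as.integer(names(tot))
  keep <- if (min_fraction == 0) frac > 0 else frac >= min_fraction
  sort(ids[keep])
}

# exact assignment maximizing total score by bitmask dynamic programming
# (rows assigned in order; feasible for n up to ~18)
solve_assignment <- function(score) {
  n <- nrow(score)
  stopifnot(n == ncol(score), n <= 18)
  full <- bitwShiftL(1L, n) - 1L
  best <- rep(-Inf, full + 1L); best[1L] <- 0
  choice <- matrix(NA_integer_, full + 1L, 1L)
  pred <- rep(NA_integer_, full + 1L)
  for (m in 0:(full - 1L)) {
    if (!is.finite(best[m + 1L])) next
    i <- sum(bitwAnd(m, bitwShiftL(1L, 0:(n - 1L))) != 0L) + 1L  # next row
    for (j in 0:(n - 1L)) {
      if (bitwAnd(m, bitwShiftL(1L, j)) != 0L) next
      m2 <- bitwOr(m, bitwShiftL(1L, j))
      v <- best[m + 1L] + score[i, j + 1L]
      if (v > best[m2 + 1L]) {
        best[m2 + 1L] <- v
        choice[m2 + 1L, 1L] <- j + 1L
        pred[m2 + 1L] <- m
      }
    }
  }
  assign <- integer(n); m <- full
  while (m > 0L) {
    j <- choice[m + 1L, 1L]
    mprev <- pred[m + 1L]
    i <- sum(bitwAnd(mprev, bitwShiftL(1L, 0:(n - 1L))) != 0L) + 1L
    assign[i] <- j
    m <- mprev
  }
  assign
}

#' Match components across two decompositions
#'
#' One-to-one pairing of components maximizing the total absolute spatial
#' correlation (exact optimal assignment), e.g. for comparing group or
#' modality ICAs. Signed correlations are reported.
#'
#' @param maps_a,maps_b \code{component_maps} over the same voxel space.
#' @return data.frame with \code{index_a}, \code{index_b}, \code{spatial_r},
#'   ordered by \code{index_a}.
#' @export
match_components <- function(maps_a, maps_b) {
  stopifnot(inherits(maps_a, "component_maps"),
            inherits(maps_b, "component_maps"))
  if (ncol(maps_a$maps) != ncol(maps_b$maps))
    stop("voxel counts differ between decompositions")
  ka <- nrow(maps_a$maps); kb <- nrow(maps_b$maps)
  stopifnot(ka == kb)
  R <- stats::cor(t(maps_a$maps), t(maps_b$maps))
  assign <- solve_assignment(abs(R))
  data.frame(index_a = seq_len(ka), index_b = assign,
             spatial_r = R[cbind(seq_len(ka), assign)])
}

#' Identify the component best covering a region set
#'
#' Scores each component by the mean z-value over the voxels of the given
#' regions and returns the top index; the pipeline's stand-in for the
#' anatomical selection of the sensorimotor component.
#'
#' @param maps A \code{component_maps} computed over the atlas mask.
#' @param atlas A \code{toy_atlas}.
#' @param roi_ids Template region ids (e.g. the cortical_motor unit).
#' @param mask Logical mask the map columns correspond to (default: atlas
#'   union mask).
#' @return Integer component index.
#' @export
select_component <- function(maps, atlas, roi_ids, mask = atlas_mask(atlas)) {
  lab <- as.vector(atlas$label_volume)[as.vector(mask)]
  sel <- lab %in% roi_ids
  scores <- rowMeans(maps$maps[, sel, drop = FALSE])
  which.max(scores)
}
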
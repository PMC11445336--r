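upper_edges <- function(a, reference = c("positive", "all")) {
  reference <- match.arg(reference)
  ut <- upper.tri(a)
  if (reference == "positive") ut & a > 0 else ut & a != 0
}

#' Multimodal common-edge (tertiary) connectome
#'
#' Edge-wise intersection of two modality adjacencies: an edge is common iff
#' it is nonzero in both and the signs agree, keeping the sign (+1 common
#' positive, -1 common negative). The Dice coefficient of the two edge sets
#' is computed on the strict upper triangle under the reference filter
#' (\code{"positive"} restricts counting to positive edges, the convention
#' for the within-network comparisons; \code{"all"} counts every significant
#' edge).
#'
#' @param adj1,adj2 \code{adjacency} objects with identical roi_ids.
#' @param reference \code{"positive"} (default) or \code{"all"}.
#' @param modalities Optional character pair labelling the sources.
#' @param group Optional group label.
#' @return Object of class \code{multimodal_connectome}: \code{tertiary}
#'   (ROI x ROI in {-1, 0, +1}), \code{dice}, \code{reference},
#'   \code{modalities}, \code{group}, \code{roi_ids},
#'   \code{dice_degenerate} (TRUE when both edge sets were empty).
#' @export
common_edges <- function(adj1, adj2, reference = c("positive", "all"),
                         modalities = c(adj1$source, adj2$source),
                         group = NA_character_) {
  stopifnot(inherits(adj1, "adjacency"), inherits(adj2, "adjacency"))
  reference <- match.arg(reference)
  if (!identical(adj1$roi_ids, adj2$roi_ids))
    stop("roi_id mismatch between adjacencies")
  common <- adj1$a != 0 & adj1$a == adj2$a
  tert <- matrix(0L, nrow(adj1$a), ncol(adj1$a), dimnames = dimnames(adj1$a))
  tert[common] <- adj1$a[common]
  diag(tert) <- 0L
  dc <- dice(adj1, adj2, reference)
  structure(list(tertiary = tert, dice = dc$dice,
                 dice_degenerate = dc$degenerate,
                 reference = reference, modalities = modalities,
                 group = group, roi_ids = adj1$roi_ids),
            class = "multimodal_connectome")
}

#' @export
print.multimodal_connectome <- function(x, ...) {
  cat("multimodal_connectome (", paste(x$modalities, collapse = " vs "),
      if (!is.na(x$group)) paste0(", ", x$group), "): ",
      sum(x$tertiary[upper.tri(x$tertiary)] != 0),
      " common edges, Dice = ", round(x$dice, 3), "\n", sep = "")
  invisible(x)
}

#' Soerensen-Dice similarity of two adjacency edge sets
#'
#' DC = 2 |M1 intersect M2| / (|M1| + |M2|) over strict-upper-triangle edge
#' sets (sign-consistent intersection). The degenerate 0/0 case (both edge
#' sets empty) is defined as 0 and flagged.
#'
#' @param adj1,adj2 \code{adjacency} objects with identical roi_ids.
#' @param reference Edge filter, \code{"positive"} or \code{"all"}.
#' @return List with \code{dice}, \code{n1}, \code{n2}, \code{n_common},
#'   \code{degenerate}.
#' @export
dice <- function(adj1, adj2, reference = c("positive", "all")) {
  reference <- match.arg(reference)
  if (!identical(adj1$roi_ids, adj2$roi_ids))
    stop("roi_id mismatch between adjacencies")
  e1 <- upper_edges(adj1$a, reference)
  e2 <- upper_edges(adj2$a, reference)
  common <- e1 & e2 & adj1$a == adj2$a
  n1 <- sum(e1); n2 <- sum(e2); nc <- sum(common)
  degenerate <- (n1 + n2) == 0
  list(dice = if (degenerate) 0 else 2 * nc / (n1 + n2),
       n1 = n1, n2 = n2, n_common = nc, degenerate = degenerate)
}

#' Nodal degree of an adjacency or tertiary matrix
#'
#' degree(i) = number of counted nonzero off-diagonal entries in row i of the
#' symmetric matrix (the number of significant connections per region).
#'
#' @param m An \code{adjacency}, \code{multimodal_connectome}, or square
#'   ternary matrix.
#' @param count_sign \code{"all"} (default) counts every nonzero edge;
#'   \code{"positive"} only +1 edges.
#' @return Named integer vector (one entry per region).
#' @export
nodal_degree <- function(m, count_sign = c("all", "positive")) {
  count_sign <- match.arg(count_sign)
  a <- if (inherits(m, "adjacency")) m$a
       else if (inherits(m, "multimodal_connectome")) m$tertiary
       else m
  stopifnot(is.matrix(a), nrow(a) == ncol(a))
  counted <- if (count_sign == "positive") a > 0 else a != 0
  diag(counted) <- FALSE
  stats::setNames(as.integer(rowSums(counted)),
                  rownames(a) %||% seq_len(nrow(a)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Aggregate nodal degree by functional unit
#'
#' @param degrees Named degree vector (names = roi_ids) or subject x ROI
#'   degree matrix (column names = roi_ids).
#' @param roi_table Atlas roi_table mapping every region to exactly one
#'   unit.
#' @param statistic \code{"sum"} (default) or \code{"mean"} over member
#'   regions.
#' @return For a vector input, a named vector per unit; for a matrix input,
#'   a subject x unit matrix.
#' @export
aggregate_by_unit <- function(degrees, roi_table,
                              statistic = c("sum", "mean")) {
  statistic <- match.arg(statistic)
  fun <- if (statistic == "sum") sum else mean
  agg_one <- function(v) {
    ids <- as.integer(names(v))
    unit <- roi_table$unit[match(ids, roi_table$roi_id)]
    if (anyNA(unit))
      stop("region(s) not mapped to a unit: ",
           paste(ids[is.na(unit)], collapse = ", "))
    tapply(v, unit, fun)
  }
  if (is.matrix(degrees)) {
    out <- t(apply(degrees, 1, function(row)
      agg_one(stats::setNames(row, colnames(degrees)))))
    out
  } else {
    res <- agg_one(degrees)
    stats::setNames(as.vector(res), names(res))
  }
}

#' Subject-level nodal degree within a network
#'
#' Within the submatrix of the given network regions, degree(i) counts edges
#' with p < alpha in the subject-level connectivity result; equals
#' \code{nodal_degree(build_adjacency(result, alpha))} restricted to the
#' network.
#'
#' @param result Subject-level \code{connectivity_result}.
#' @param network_rois Region ids of the network (must be a subset of the
#'   result's roi_ids).
#' @param alpha Edge significance level.
#' @param count_sign Passed to \code{\link{nodal_degree}}.
#' @return Named integer vector over the network regions.
#' @export
subject_nodal_degree <- function(result, network_rois, alpha = 0.05,
                                 count_sign = "all") {
  stopifnot(inherits(result, "connectivity_result"))
  if (!all(network_rois %in% result$roi_ids))
    stop("network region(s) outside the parcellation: ",
         paste(setdiff(network_rois, result$roi_ids), collapse = ", "))
  adj <- build_adjacency(result, alpha)
  ix <- match(network_rois, result$roi_ids)
  sub <- adj$a[ix, ix, drop = FALSE]
  nodal_degree(sub, count_sign)
}
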
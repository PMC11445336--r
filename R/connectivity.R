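# r clipped to +/-(1 - 1e-7) before atanh so degenerate duplicates stay finite
R_CLIP <- 1 - 1e-7

fisher_z <- function(r) atanh(pmin(pmax(r, -R_CLIP), R_CLIP))

# p-value of a Pearson correlation under the t distribution with df degrees
# of freedom (two-sided)
cor_pvalue <- function(r, df) {
  r2 <- pmin(abs(r), 1)
  t <- r2 * sqrt(df / pmax(1 - r2^2, .Machine$double.eps))
  p <- 2 * stats::pt(t, df, lower.tail = FALSE)
  p[r2 >= 1] <- 0
  p
}

new_connectivity <- function(r, p, modality, level, n_units, roi_ids,
                             flagged = integer(0)) {
  diag(r) <- 0; diag(p) <- 1
  dimnames(r) <- dimnames(p) <- list(roi_ids, roi_ids)
  structure(list(r = r, z = fisher_z(r), p = p, modality = modality,
                 level = level, n_units = n_units, roi_ids = roi_ids,
                 flagged_rois = flagged),
            class = "connectivity_result")
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat("connectivity_result:", x$modality, "/", x$level, "-",
      length(x$roi_ids), "ROIs, n_units =", x$n_units, "\n")
  invisible(x)
}

#' Group-level static metabolic covariance
#'
#' Pearson correlation of summed regional uptake across the subjects of one
#' group (metabolic covariance: the only connectivity construction available
#' to static PET, defined at group level). Significance per edge comes from
#' the correlation t test with n_subjects - 2 degrees of freedom.
#'
#' @param static A \code{static_uptake} (subject x ROI matrix) for one group.
#' @return A \code{connectivity_result} (modality \code{"spet"}, level
#'   \code{"group"}).
#' @export
static_covariance <- function(static) {
  stopifnot(inherits(static, "static_uptake"))
  n <- nrow(static)
  if (n < 4) stop("static covariance needs >= 4 subjects, got ", n)
  m <- unclass(static)
  sds <- apply(m, 2, stats::sd)
  flagged <- which(sds == 0)
  r <- suppressWarnings(stats::cor(m))
  r[!is.finite(r)] <- 0
  p <- cor_pvalue(r, n - 2)
  p[flagged, ] <- 1; p[, flagged] <- 1
  new_connectivity(r, p, "spet", "group", n, attr(static, "roi_ids"),
                   flagged)
}

#' Subject-level time-series connectivity
#'
#' Pearson correlation between all pairs of region series over frames
#' (metabolic for 30-frame PET windows, hemodynamic for 490-frame BOLD),
#' with per-edge p from the correlation t test (frames - 2 df; used only for
#' subject-level degree). Zero-variance regions are flagged and their edges
#' recorded as r = 0, p = 1 (conservative, keeps matrices total).
#'
#' @param series A \code{roi_series}.
#' @return A \code{connectivity_result} (level \code{"subject"}).
#' @export
subject_connectivity <- function(series) {
  stopifnot(inherits(series, "roi_series"))
  tvals <- t(series$values)
  n <- nrow(tvals)
  if (n < 4) stop("subject connectivity needs >= 4 frames, got ", n)
  sds <- apply(tvals, 2, stats::sd)
  flagged <- which(sds == 0)
  r <- suppressWarnings(stats::cor(tvals))
  r[!is.finite(r)] <- 0
  p <- cor_pvalue(r, n - 2)
  p[flagged, ] <- 1; p[, flagged] <- 1
  new_connectivity(r, p, series$modality, "subject", n, series$roi_ids,
                   flagged)
}

#' Group-mean connectivity from subject-level results
#'
#' Averages the Fisher-transformed correlations edge-wise over subjects and
#' tests each edge with a two-sided one-sample t test of the subjects'
#' z-values against zero ("standardised" strength = Fisher z, per the
#' figure colorbars). Degenerate edges with zero sample variance get p = 0
#' when the mean is nonzero and p = 1 when it is zero.
#'
#' @param results List of subject-level \code{connectivity_result}s with
#'   identical roi_ids.
#' @return A \code{connectivity_result} (level \code{"group"}) whose \code{r}
#'   is the back-transformed mean z (\code{tanh}).
#' @export
group_mean_connectivity <- function(results) {
  stopifnot(length(results) >= 3)
  ids <- results[[1]]$roi_ids
  for (res in results)
    if (!identical(res$roi_ids, ids)) stop("roi_id mismatch across subjects")
  n <- length(results)
  zs <- vapply(results, function(res) res$z, results[[1]]$z)
  zbar <- apply(zs, 1:2, mean)
  zsd <- apply(zs, 1:2, stats::sd)
  tstat <- zbar / (zsd / sqrt(n))
  p <- 2 * stats::pt(abs(tstat), n - 1, lower.tail = FALSE)
  p[zsd == 0 & zbar != 0] <- 0
  p[zsd == 0 & zbar == 0] <- 1
  out <- new_connectivity(tanh(zbar), p, results[[1]]$modality, "group", n,
                          ids)
  out$z <- zbar ; diag(out$z) <- 0
  out
}

#' Signed adjacency from a connectivity result
#'
#' Binarizes a connectivity matrix keeping only significant edges:
#' a(i, j) = sign(effect) where p < alpha, 0 otherwise (raw p, no edge-level
#' multiplicity correction; correction is applied downstream to degree
#' comparisons only).
#'
#' @param result A \code{connectivity_result}.
#' @param alpha Significance level (default 0.05).
#' @param sign_from Effect used for the sign: \code{"r"} or \code{"mean_z"}
#'   (identical sign; provided for explicitness).
#' @return Object of class \code{adjacency}: list with \code{a} (ROI x ROI
#'   matrix in {-1, 0, +1}), \code{alpha}, \code{roi_ids}, \code{source}.
#' @export
build_adjacency <- function(result, alpha = 0.05,
                            sign_from = c("r", "mean_z")) {
  stopifnot(inherits(result, "connectivity_result"))
  sign_from <- match.arg(sign_from)
  eff <- if (sign_from == "r") result$r else result$z
  a <- matrix(0L, nrow(eff), ncol(eff), dimnames = dimnames(eff))
  sig <- result$p < alpha
  a[sig] <- as.integer(sign(eff[sig]))
  diag(a) <- 0L
  structure(list(a = a, alpha = alpha, roi_ids = result$roi_ids,
                 source = paste(result$modality, result$level, sep = "/")),
            class = "adjacency")
}

#' @export
print.adjacency <- function(x, ...) {
  cat("adjacency (", x$source, "): ", sum(x$a[upper.tri(x$a)] != 0),
      " significant edges at alpha = ", x$alpha, "\n", sep = "")
  invisible(x)
}
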
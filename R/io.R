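#' Read / write NIfTI volumes
#'
#' Thin wrappers around RNifti providing lossless data + affine round-trips
#' and descriptive failures naming the offending path. Integer label volumes
#' round-trip with an integer datatype.
#'
#' @param path File path (.nii or .nii.gz).
#' @return \code{read_nifti}: list with \code{data} (plain array) and
#'   \code{affine} (4x4 voxel-to-world matrix).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("failed to read NIfTI '", path, "': ",
                         conditionMessage(e)))
  aff <- structure(RNifti::xform(img), class = NULL)
  list(data = array(as.vector(img), dim = dim(img)),
       affine = matrix(as.numeric(aff), 4, 4))
}

#' @rdname read_nifti
#' @param data Numeric or integer array (3D or 4D).
#' @param affine 4x4 voxel-to-world matrix (default identity).
#' @param datatype NIfTI storage type; \code{"auto"} picks \code{"int32"}
#'   for integer data and \code{"double"} otherwise.
#' @export
write_nifti <- function(data, path, affine = diag(4), datatype = "auto") {
  if (datatype == "auto")
    datatype <- if (is.integer(data)) "int32" else "double"
  img <- RNifti::asNifti(data, datatype = datatype)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write / read a square ROI matrix as TSV with a JSON sidecar
#'
#' Tab-delimited UTF-8, '.' decimal; first column and header row carry the
#' roi_ids. The sidecar (same path with extension \code{.json}) stores
#' modality/level/parameter metadata so every matrix can be re-derived.
#'
#' @param m Square matrix.
#' @param path Output TSV path.
#' @param roi_ids Region ids (default from dimnames).
#' @param sidecar Named list of metadata (may be empty).
#' @return The path, invisibly.
#' @export
write_matrix_tsv <- function(m, path, roi_ids = rownames(m),
                             sidecar = list()) {
  stopifnot(nrow(m) == ncol(m))
  if (is.null(roi_ids)) roi_ids <- seq_len(nrow(m))
  if (anyDuplicated(roi_ids)) stop("duplicated roi_id in header")
  df <- data.frame(roi_id = roi_ids, m, check.names = FALSE)
  colnames(df) <- c("roi_id", roi_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(c(sidecar, list(roi_ids = roi_ids)),
                       paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @return \code{read_matrix_tsv}: list with \code{matrix}, \code{roi_ids},
#'   \code{sidecar}.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(m) != ncol(m)) stop("non-square matrix in ", path)
  dimnames(m) <- list(ids, ids)
  side_path <- paste0(tools::file_path_sans_ext(path), ".json")
  sidecar <- if (file.exists(side_path))
    jsonlite::read_json(side_path, simplifyVector = TRUE) else list()
  if (length(sidecar$roi_ids) &&
      !identical(as.character(sidecar$roi_ids), as.character(ids)))
    stop("header roi_ids disagree with sidecar in ", path)
  list(matrix = m, roi_ids = ids, sidecar = sidecar)
}

#' Write a region-by-frame series as wide TSV
#'
#' First column \code{roi_id}, then one column per frame.
#' @param series A \code{roi_series}.
#' @param path Output path.
#' @export
write_roi_series_tsv <- function(series, path) {
  df <- data.frame(roi_id = series$roi_ids, series$values)
  colnames(df) <- c("roi_id", sprintf("frame_%d", seq_len(ncol(series$values))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a connectome in BrainNet Viewer text formats
#'
#' Writes a \code{.node} file (columns x, y, z, color, size, label; one row
#' per region, size proportional to nodal degree with a documented minimum
#' of 0.5 for zero-degree regions so nodes stay visible) and a \code{.edge}
#' file (whitespace-delimited R x R matrix).
#'
#' @param connectome A \code{multimodal_connectome} (or \code{adjacency}).
#' @param degrees Named per-region degree vector matching the connectome's
#'   regions.
#' @param atlas A \code{toy_atlas} supplying centroid coordinates and unit
#'   colors.
#' @param prefix Output path prefix; writes \code{<prefix>.node} and
#'   \code{<prefix>.edge}.
#' @param affine Voxel-to-world matrix for the centroids.
#' @return Character vector of the two paths, invisibly.
#' @export
export_brainnet <- function(connectome, degrees, atlas, prefix,
                            affine = diag(4)) {
  tert <- if (inherits(connectome, "multimodal_connectome"))
    connectome$tertiary else connectome$a
  ids <- if (inherits(connectome, "multimodal_connectome"))
    connectome$roi_ids else connectome$roi_ids
  if (!identical(as.character(names(degrees)), as.character(ids)))
    stop("degree names do not match connectome regions")
  cent <- roi_centroids(atlas, affine)
  cent <- cent[match(as.character(ids), rownames(cent)), , drop = FALSE]
  unit <- atlas$roi_table$unit[match(ids, atlas$roi_table$roi_id)]
  node <- data.frame(x = cent[, 1], y = cent[, 2], z = cent[, 3],
                     color = as.integer(factor(unit, levels = UNIT_LEVELS)),
                     size = pmax(as.numeric(degrees), 0.5),
                     label = atlas$roi_table$name[match(ids,
                                                        atlas$roi_table$roi_id)])
  node_path <- paste0(prefix, ".node")
  edge_path <- paste0(prefix, ".edge")
  utils::write.table(node, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(unname(as.matrix(tert)), edge_path, sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(c(node_path, edge_path))
}

#' Write cohort and ROI lookup tables
#'
#' @param cohort A \code{synthetic_cohort}.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_cohort_tables <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lut <- file.path(dir, "roi_lut.tsv")
  utils::write.table(cohort$atlas$roi_table, lut, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  coh <- file.path(dir, "cohort.tsv")
  utils::write.table(cohort$subjects, coh, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  man <- file.path(dir, "truth_manifest.json")
  jsonlite::write_json(truth_manifest(cohort), man, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(list(lut = lut, cohort = coh, manifest = man))
}
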
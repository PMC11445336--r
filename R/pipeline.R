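PIPELINE_DEFAULTS <- list(
  keep_last = 30L,
  n_components = 10L,
  z_threshold = 1.5,
  motor_z_threshold = 1.0,
  alpha = 0.05,
  min_fraction = 0.1,
  reference = "positive",
  unit_statistic = "sum",
  normalize_fmri = FALSE,
  run_ica = TRUE,
  write_scans = FALSE)

#' Pipeline configuration
#'
#' Bundles the analysis parameters (frame retention, ICA dimensionality,
#' component z thresholds, edge significance level, parcellation overlap,
#' Dice reference, unit aggregation statistic), the synthetic cohort
#' configuration, seeds, and the output directory. Unknown keys are
#' rejected: a typo must fail loudly, not fall back to a default.
#'
#' @param cohort A \code{cohort_config} (or named list of overrides) for the
#'   synthetic cohort stage.
#' @param seed Integer global seed for the whole run.
#' @param outdir Output directory (NULL suppresses file output).
#' @param ... Analysis parameter overrides; see
#'   \code{fpetconn:::PIPELINE_DEFAULTS} for names and defaults
#'   (\code{keep_last = 30}, \code{n_components = 10},
#'   \code{z_threshold = 1.5}, \code{motor_z_threshold = 1},
#'   \code{alpha = 0.05}, \code{min_fraction = 0.1},
#'   \code{reference = "positive"}, \code{unit_statistic = "sum"},
#'   \code{normalize_fmri = FALSE}, \code{run_ica = TRUE},
#'   \code{write_scans = FALSE}).
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(cohort = cohort_config(), seed = 1L,
                            outdir = NULL, ...) {
  dots <- list(...)
  unknown <- setdiff(names(dots), names(PIPELINE_DEFAULTS))
  if (length(unknown))
    stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "))
  pars <- utils::modifyList(PIPELINE_DEFAULTS, dots)
  stopifnot(pars$keep_last >= 4, pars$n_components >= 2,
            pars$alpha > 0, pars$alpha <= 1,
            pars$min_fraction >= 0, pars$min_fraction <= 1,
            pars$reference %in% c("positive", "all"),
            pars$unit_statistic %in% c("sum", "mean"))
  structure(c(list(cohort = as_cohort_config(cohort),
                   seed = as.integer(seed), outdir = outdir), pars),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys \code{cohort}, \code{seed}, \code{outdir} plus any
#' analysis parameter; unknown keys at either level are errors.
#' @param path YAML file path.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  known_top <- c("cohort", "seed", "outdir", names(PIPELINE_DEFAULTS))
  unknown <- setdiff(names(y), known_top)
  if (length(unknown))
    stop("unknown config key(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  args <- y[setdiff(names(y), c("cohort", "seed", "outdir"))]
  do.call(pipeline_config,
          c(list(cohort = as_cohort_config(y$cohort %||% list()),
                 seed = y$seed %||% 1L, outdir = y$outdir), args))
}

# preprocess one subject's fPET data (scan or series): retain trailing
# frames, global-mean normalize, return a normalized roi_series
prep_fpet_subject <- function(x, atlas, subject_id, keep_last) {
  if (inherits(x, "subject_scan") || length(dim(x)) == 4) {
    if (!inherits(x, "subject_scan"))
      x <- subject_scan(x, "fpet", subject_id, brain_mask = atlas_mask(atlas))
    x <- retain_frames(x, keep_last)
    x <- global_mean_normalize(x)
    series <- extract_roi_series(x, atlas)
    series$normalized <- TRUE
    series
  } else {
    s <- roi_series(x, atlas$roi_table$roi_id, "fpet", subject_id)
    s <- retain_frames(s, keep_last)
    global_mean_normalize(s, atlas$voxel_counts)
  }
}

prep_fmri_subject <- function(x, atlas, subject_id, normalize) {
  if (inherits(x, "subject_scan") || length(dim(x)) == 4) {
    if (!inherits(x, "subject_scan"))
      x <- subject_scan(x, "fmri", subject_id, brain_mask = atlas_mask(atlas))
    if (normalize) x <- global_mean_normalize(x)
    series <- extract_roi_series(x, atlas)
    series$normalized <- normalize
    series
  } else {
    s <- roi_series(x, atlas$roi_table$roi_id, "fmri", subject_id)
    if (normalize) s <- global_mean_normalize(s, atlas$voxel_counts)
    s
  }
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate -> preprocess (frame retention, global-mean
#' normalization, ROI extraction, static summation) -> group spatial ICA and
#' motor-network identification -> the three connectivity constructions
#' (group-level static covariance; subject-level dynamic PET; subject-level
#' BOLD) -> signed adjacency -> multimodal common-edge connectomes
#' (sPET-fMRI, fPET-fMRI, sPET-fPET) with Dice similarity -> nodal-degree
#' group statistics with Holm correction -> severity correlations, and
#' writes matrices, tables, BrainNet exports and a run manifest when
#' \code{config$outdir} is set.
#'
#' @param config A \code{pipeline_config}.
#' @return Object of class \code{pipeline_result} (invisibly contains every
#'   intermediate product plus the manifest).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  log_stage <- function(...) message("[fpetconn] ", ...)

  log_stage("simulate: cohort seed ", config$seed)
  cohort <- simulate_cohort(config$cohort, config$seed)
  atlas <- cohort$atlas
  subs <- cohort$subjects
  groups <- c("PD", "HC")

  log_stage("preprocess: keep_last = ", config$keep_last)
  fpet_raw <- if (!is.null(cohort$fpet_scans)) cohort$fpet_scans
              else cohort$fpet_series
  fmri_raw <- if (!is.null(cohort$fmri_scans)) cohort$fmri_scans
              else cohort$fmri_series
  fpet_series <- lapply(subs$subject_id, function(id)
    prep_fpet_subject(fpet_raw[[id]], atlas, id, config$keep_last))
  fmri_series <- lapply(subs$subject_id, function(id)
    prep_fmri_subject(fmri_raw[[id]], atlas, id, config$normalize_fmri))
  names(fpet_series) <- names(fmri_series) <- subs$subject_id

  static <- lapply(groups, function(g)
    static_uptake(fpet_series[subs$group == g], g))
  names(static) <- groups

  ica <- NULL
  network_rois <- atlas$roi_table$roi_id[atlas$roi_table$unit ==
                                           "cortical_motor"]
  if (config$run_ica) {
    log_stage("ica: ", config$n_components, " components per group")
    # voxel-level spatial ICA on the normalized retained dynamics when
    # volumes exist (shared network factors are only separable as single
    # components with voxels as samples); region-level ICA in series mode
    voxel_mode <- !is.null(cohort$fpet_scans)
    # the infusion baseline is removed by per-voxel linear detrending for
    # the decomposition (division by a 30-region global mean would couple
    # the global mode to the largest network at this parcel count)
    ica_input <- function(g) {
      ids <- subs$subject_id[subs$group == g]
      if (voxel_mode) {
        scans <- lapply(ids, function(id) {
          sc <- subject_scan(fpet_raw[[id]], "fpet", id,
                             brain_mask = atlas_mask(atlas))
          detrend_frames(retain_frames(sc, config$keep_last))
        })
        concatenate_group(scans)
      } else {
        concatenate_group(lapply(fpet_series[ids], detrend_frames))
      }
    }
    ica <- lapply(groups, function(g)
      group_spatial_ica(ica_input(g)$data, config$n_components,
                        seed = config$seed, group = g, modality = "fpet"))
    names(ica) <- groups
    # identify the sensorimotor component in the patient decomposition and
    # parcellate it (network analyses use the identified region set)
    motor_comp <- select_component_series(ica$PD, atlas, network_rois)
    network_rois_ica <- if (voxel_mode) {
      nm <- threshold_component(ica$PD, motor_comp,
                                config$motor_z_threshold,
                                mask = atlas_mask(atlas))
      parcellate_mask(nm, atlas, config$min_fraction)
    } else {
      # series-mode ICA: columns are regions, threshold directly
      sort(atlas$roi_table$roi_id[ica$PD$maps[motor_comp, ] >
                                    config$motor_z_threshold])
    }
    if (length(network_rois_ica) >= 3) network_rois <- network_rois_ica
    log_stage("ica: motor component ", motor_comp, ", network of ",
              length(network_rois), " regions")
  }

  log_stage("connectivity: three constructions, alpha = ", config$alpha)
  conn <- list()
  for (g in groups) {
    in_g <- subs$group == g
    conn[[g]] <- list(
      spet = static_covariance(static[[g]]),
      fpet = group_mean_connectivity(
        lapply(fpet_series[in_g], subject_connectivity)),
      fmri = group_mean_connectivity(
        lapply(fmri_series[in_g], subject_connectivity)))
  }
  adj <- lapply(conn, lapply, build_adjacency, alpha = config$alpha)

  log_stage("connectomes: common edges + Dice")
  pairs <- list(c("spet", "fmri"), c("fpet", "fmri"), c("spet", "fpet"))
  connectomes <- list()
  for (g in groups) for (pr in pairs) {
    key <- paste(pr[1], pr[2], g, sep = "_")
    connectomes[[key]] <- common_edges(adj[[g]][[pr[1]]], adj[[g]][[pr[2]]],
                                       reference = config$reference,
                                       modalities = pr, group = g)
  }

  log_stage("statistics: unit degree + severity")
  degree_stats <- list()
  for (pr in pairs) {
    key <- paste(pr[1], pr[2], sep = "_")
    dpd <- nodal_degree(connectomes[[paste0(key, "_PD")]])
    dhc <- nodal_degree(connectomes[[paste0(key, "_HC")]])
    degree_stats[[key]] <- list(
      degree_pd = dpd, degree_hc = dhc,
      unit_pd = aggregate_by_unit(dpd, atlas$roi_table,
                                  config$unit_statistic),
      unit_hc = aggregate_by_unit(dhc, atlas$roi_table,
                                  config$unit_statistic),
      tests = compare_unit_degrees(dhc, dpd, atlas$roi_table,
                                   config$alpha))
  }

  pd_ids <- subs$subject_id[subs$group == "PD"]
  motor_degree <- vapply(pd_ids, function(id)
    sum(subject_nodal_degree(subject_connectivity(fpet_series[[id]]),
                             network_rois, config$alpha)), numeric(1))
  severity <- stats::setNames(subs$severity[subs$group == "PD"], pd_ids)
  severity_test <- spearman_severity(motor_degree, severity)

  result <- structure(
    list(config = config, cohort = cohort, atlas = atlas,
         fpet_series = fpet_series, fmri_series = fmri_series,
         static = static, ica = ica, network_rois = network_rois,
         connectivity = conn, adjacency = adj, connectomes = connectomes,
         degree_stats = degree_stats,
         motor_degree = motor_degree, severity_test = severity_test),
    class = "pipeline_result")

  if (!is.null(config$outdir))
    result$manifest <- write_pipeline_outputs(result, config$outdir)
  invisible(result)
}

# variant of select_component for the pipeline (kept separate so the
# exported one keeps its mask-based contract)
select_component_series <- function(maps, atlas, roi_ids) {
  lab_of_col <- atlas$roi_table$roi_id
  if (ncol(maps$maps) == sum(atlas_mask(atlas))) {
    lab <- as.vector(atlas$label_volume)[as.vector(atlas_mask(atlas))]
    sel <- lab %in% roi_ids
  } else {
    sel <- lab_of_col %in% roi_ids
  }
  which.max(rowMeans(maps$maps[, sel, drop = FALSE]))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result: seed", x$config$seed, "\n")
  for (key in names(x$connectomes))
    cat(sprintf("  %-16s Dice = %.3f\n", key, x$connectomes[[key]]$dice))
  cat("  severity rho =", signif(x$severity_test$statistic, 3),
      "(p =", signif(x$severity_test$p, 3), ")\n")
  invisible(x)
}

# write all pipeline products + manifest with per-file hashes
write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  paths <- write_cohort_tables(result$cohort, outdir)

  for (g in names(result$connectivity)) {
    for (mod in names(result$connectivity[[g]])) {
      res <- result$connectivity[[g]][[mod]]
      write_matrix_tsv(res$z, file.path(outdir,
                                        sprintf("conn_%s_%s_z.tsv", mod, g)),
                       sidecar = list(modality = mod, level = res$level,
                                      n_units = res$n_units, group = g))
      write_matrix_tsv(result$adjacency[[g]][[mod]]$a,
                       file.path(outdir, sprintf("adj_%s_%s.tsv", mod, g)),
                       sidecar = list(modality = mod, group = g,
                                      alpha = cfg$alpha))
    }
  }
  for (key in names(result$connectomes)) {
    cm <- result$connectomes[[key]]
    write_matrix_tsv(cm$tertiary,
                     file.path(outdir, sprintf("tertiary_%s.tsv", key)),
                     sidecar = list(dice = cm$dice,
                                    reference = cm$reference,
                                    modalities = cm$modalities,
                                    group = cm$group))
    export_brainnet(cm, nodal_degree(cm), result$atlas,
                    file.path(outdir, sprintf("connectome_%s", key)))
  }

  man <- list(
    package_version = as.character(utils::packageVersion("fpetconn")),
    seed = cfg$seed,
    parameters = unclass(cfg)[setdiff(names(unclass(cfg)),
                                      c("cohort", "outdir"))],
    cohort_config = unclass(cfg$cohort),
    network_rois = result$network_rois,
    dice = lapply(result$connectomes, function(cm) cm$dice),
    severity_rho = result$severity_test$statistic,
    severity_p = result$severity_test$p,
    timestamp = format(Sys.time(), tz = "UTC"))
  files <- setdiff(list.files(outdir, full.names = TRUE), character(0))
  man$file_hashes <- as.list(tools::md5sum(files))
  names(man$file_hashes) <- basename(files)
  jsonlite::write_json(man, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  man
}
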
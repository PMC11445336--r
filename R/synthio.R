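#' Synthetic cohort configuration
#'
#' Validated parameter set for the synthetic multimodal cohort generator.
#' Defaults encode the study conditions the pipeline targets: 12 patients and
#' 13 healthy controls, 90 one-minute PET frames with fluctuations carried by
#' the final 30 frames, 490 BOLD time points, and a planted excess of
#' cortical-motor edges in the patient group whose strength is coupled to a
#' per-patient severity score.
#'
#' @param n_pd,n_hc Group sizes (patients, controls).
#' @param n_rois Number of atlas regions.
#' @param grid_shape 3D grid for the toy atlas.
#' @param unit_assignment Optional named counts per functional unit (see
#'   \code{\link{make_toy_atlas}}).
#' @param edge_strength Target Pearson correlation of a planted time-series
#'   edge at coupling 1 (0 < s < 1).
#' @param spet_edge_strength Target across-subject correlation of summed
#'   regional uptake for planted edges (static PET covariance).
#' @param n_networks Number of planted intrinsic networks (communities) per
#'   group, defaulting to the decomposition dimension used in the analyses
#'   (10 components): starting from one whole-unit community per functional
#'   unit, the largest non-motor community is split in half until this many
#'   networks exist (or none is large enough to split).
#' @param hc_motor_clique Number of motor regions forming the control group's
#'   (smaller) motor community; the patient community spans all motor regions.
#' @param fluct_amp,fmri_amp Fluctuation amplitudes (relative to baseline for
#'   PET; absolute signal units for BOLD).
#' @param ar_coefficient AR(1) coefficient of the BOLD latent processes.
#' @param noise_sd I.i.d. Gaussian voxel noise standard deviation.
#' @param spet_cv Coefficient of variation of across-subject baseline uptake
#'   fluctuations (drives static-PET covariance).
#' @param coupling_range Range of the per-subject motor coupling score.
#' @param severity_intercept,severity_slope,severity_noise_sd Affine-monotone
#'   map from coupling score to a UPDRS-III-like severity score plus noise.
#' @param n_frames_fpet,n_frames_fmri Frame counts (defaults 90 and 490).
#' @param fluct_frames Number of trailing PET frames carrying fluctuations.
#' @param volumes When \code{TRUE} full 4D volumes are generated; when
#'   \code{FALSE} the cohort carries region-by-frame series directly (same
#'   latent process; voxel averaging emulated by shrinking the noise sd by
#'   \code{1/sqrt(n_voxels)}).
#' @return Object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_pd = 12L, n_hc = 13L,
                          n_rois = 30L,
                          grid_shape = c(12L, 12L, 8L),
                          unit_assignment = c(cortical_motor = 6L,
                                              subcortical = 4L,
                                              cerebellar = 4L,
                                              frontal = 5L,
                                              parietal = 4L,
                                              occipital = 3L,
                                              temporal = 4L),
                          edge_strength = 0.55,
                          spet_edge_strength = 0.75,
                          n_networks = 10L,
                          hc_motor_clique = 3L,
                          fluct_amp = 2,
                          fmri_amp = 3,
                          ar_coefficient = 0.4,
                          noise_sd = 0.5,
                          spet_cv = 0.05,
                          coupling_range = c(0.3, 1),
                          severity_intercept = 10,
                          severity_slope = 35,
                          severity_noise_sd = 4,
                          n_frames_fpet = 90L,
                          n_frames_fmri = 490L,
                          fluct_frames = 30L,
                          volumes = TRUE) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_pd >= 1, cfg$n_hc >= 1, cfg$n_rois >= 2,
            cfg$edge_strength >= 0, cfg$edge_strength <= 1,
            cfg$spet_edge_strength >= 0, cfg$spet_edge_strength < 1,
            cfg$ar_coefficient >= 0, cfg$ar_coefficient < 1,
            cfg$noise_sd >= 0, cfg$severity_noise_sd >= 0,
            length(cfg$coupling_range) == 2,
            cfg$coupling_range[1] >= 0, cfg$coupling_range[2] <= 1,
            cfg$coupling_range[1] <= cfg$coupling_range[2],
            cfg$severity_slope > 0,
            cfg$fluct_frames >= 1, cfg$fluct_frames <= cfg$n_frames_fpet)
  class(cfg) <- "cohort_config"
  cfg
}

REQUIRED_CONFIG_FIELDS <- names(formals(cohort_config))

#' Coerce a plain list to a cohort configuration
#'
#' Unknown keys are an error (typos must not silently fall back to defaults);
#' missing keys take the documented defaults.
#' @param x Named list of configuration overrides.
#' @return A \code{cohort_config}.
#' @export
as_cohort_config <- function(x) {
  if (inherits(x, "cohort_config")) return(x)
  stopifnot(is.list(x))
  unknown <- setdiff(names(x), REQUIRED_CONFIG_FIELDS)
  if (length(unknown))
    stop("unknown cohort config key(s): ", paste(unknown, collapse = ", "))
  do.call(cohort_config, x)
}

# -- ground truth -----------------------------------------------------------

#' Plant the ground-truth network structure
#'
#' Builds the per-group planted communities (cliques sharing one latent
#' factor each), the corresponding signed adjacency matrices, per-subject
#' motor coupling scores, patient severity scores, and across-subject
#' baseline uptake values. Every planted edge (i, j) inside a community with
#' weight w has model correlation exactly w: member regions load
#' \code{sqrt(w)} on the shared factor and \code{sqrt(1 - w)} on a unique
#' factor, all factors having unit variance.
#'
#' The patient motor community spans all \code{cortical_motor} regions; the
#' control motor community only the first \code{hc_motor_clique} of them, so
#' the patient truth matrix strictly exceeds the control one in
#' motor-to-motor edges. All other units carry identical communities in both
#' groups.
#'
#' @param atlas A \code{toy_atlas}.
#' @param config A \code{cohort_config}.
#' @param seed Integer seed (the generator's global seed).
#' @return Object of class \code{ground_truth}.
#' @export
make_ground_truth <- function(atlas, config, seed) {
  config <- as_cohort_config(config)
  check_atlas(atlas)
  rt <- atlas$roi_table
  n <- nrow(rt)

  motor_ids <- rt$roi_id[rt$unit == "cortical_motor"]
  if (length(motor_ids) < 2)
    stop("ground truth requires at least 2 cortical_motor regions")
  # one whole-unit community per non-motor unit, then split the largest in
  # half until n_networks communities exist (motor counts as one); a
  # community needs >= 4 members to split into two cliques of >= 2
  base_comm <- Filter(function(x) length(x) >= 2,
                      lapply(setdiff(unique(rt$unit), "cortical_motor"),
                             function(u) rt$roi_id[rt$unit == u]))
  repeat {
    if (1L + length(base_comm) >= config$n_networks) break
    sizes <- lengths(base_comm)
    i <- which.max(sizes)
    if (sizes[i] < 4) break
    ids <- base_comm[[i]]
    h <- ceiling(length(ids) / 2)
    base_comm <- c(base_comm[-i], list(ids[seq_len(h)]), list(ids[-seq_len(h)]))
  }

  hc_motor <- motor_ids[seq_len(min(config$hc_motor_clique,
                                    length(motor_ids)))]
  communities <- list(
    PD = c(list(motor = motor_ids), base_comm),
    HC = c(list(motor = hc_motor), base_comm))

  adj_from <- function(comms) {
    a <- matrix(0L, n, n, dimnames = list(rt$roi_id, rt$roi_id))
    for (cc in comms) {
      ix <- match(cc, rt$roi_id)
      a[ix, ix] <- 1L
    }
    diag(a) <- 0L
    a
  }
  group_adjacency <- lapply(communities, adj_from)

  set.seed(as.integer(seed %% 2147483647))
  n_sub <- config$n_pd + config$n_hc
  subjects <- data.frame(
    subject_id = sprintf("sub-%02d", seq_len(n_sub)),
    group = rep(c("PD", "HC"), c(config$n_pd, config$n_hc)),
    stringsAsFactors = FALSE)
  coupling <- stats::runif(n_sub, config$coupling_range[1],
                           config$coupling_range[2])
  severity <- rep(NA_real_, n_sub)
  pd <- subjects$group == "PD"
  severity[pd] <- config$severity_intercept +
    config$severity_slope * coupling[pd] +
    stats::rnorm(sum(pd), 0, config$severity_noise_sd)
  subjects$severity <- severity

  b0 <- stats::runif(n, 0.9, 1.1)                    # per-ROI baseline slope

  # across-subject baseline fluctuations with the planted community structure
  # (static-PET covariance): z_i(s) = sqrt(w) G_c(s) + sqrt(1-w) h_i(s)
  w_spet <- config$spet_edge_strength
  z <- matrix(stats::rnorm(n_sub * n), n_sub, n)     # unique parts h_i(s)
  baselines <- matrix(0, n_sub, n,
                      dimnames = list(subjects$subject_id, rt$roi_id))
  for (s in seq_len(n_sub)) {
    comms <- communities[[subjects$group[s]]]
    zi <- z[s, ]
    if (w_spet > 0) {
      g <- stats::rnorm(length(comms))
      for (k in seq_along(comms)) {
        ix <- match(comms[[k]], rt$roi_id)
        zi[ix] <- sqrt(w_spet) * g[k] + sqrt(1 - w_spet) * z[s, ix]
      }
    }
    baselines[s, ] <- b0 * (1 + config$spet_cv * zi)
  }

  structure(
    list(communities = communities,
         group_adjacency = group_adjacency,
         edge_strength = config$edge_strength,
         spet_edge_strength = w_spet,
         motor_rois = motor_ids,
         subjects = subjects,
         coupling_score = stats::setNames(coupling, subjects$subject_id),
         severity = stats::setNames(severity, subjects$subject_id),
         baselines = baselines,
         config = config,
         seed = as.integer(seed)),
    class = "ground_truth")
}

# -- latent processes -------------------------------------------------------

# Stationary AR(1) series with unit marginal variance (phi = 0 gives white
# noise); n x m matrix, one series per column.
ar1_noise <- function(n, m, phi) {
  e <- matrix(stats::rnorm(n * m), n, m)
  if (phi == 0 || n == 1) return(e)
  e[-1, ] <- e[-1, ] * sqrt(1 - phi^2)   # keeps marginal variance at 1
  matrix(apply(e, 2, function(col)
    as.numeric(stats::filter(col, phi, method = "recursive"))), n, m)
}

# ROI x T latent fluctuation matrix for one subject. Community c with weight
# w contributes sqrt(w) * shared factor + sqrt(1-w) * unique factor to each
# member region; regions outside every (nonzero-weight) community stay flat.
latent_roi_fluctuations <- function(truth, subject, n_frames, phi = 0) {
  sub <- truth$subjects
  s <- match(subject, sub$subject_id)
  if (is.na(s)) stop("unknown subject: ", subject)
  comms <- truth$communities[[sub$group[s]]]
  n <- ncol(truth$baselines)
  x <- matrix(0, n, n_frames)
  coupling <- truth$coupling_score[[subject]]
  factors <- ar1_noise(n_frames, length(comms), phi)
  for (k in seq_along(comms)) {
    w <- truth$edge_strength *
      if (identical(names(comms)[k], "motor")) coupling else 1
    if (w <= 0) next
    ix <- match(comms[[k]], colnames(truth$baselines))
    uniq <- ar1_noise(n_frames, length(ix), phi)
    x[ix, ] <- sqrt(w) * matrix(factors[, k], length(ix), n_frames,
                                byrow = TRUE) +
      sqrt(1 - w) * t(uniq)
  }
  x
}

# Documented counter scheme: stream 2*k (fPET) / 2*k + 1 (fMRI) for subject
# index k, folded into [1, 2^31 - 2] so each subject regenerates individually.
substream_seed <- function(seed, subject_index, modality = c("fpet", "fmri")) {
  modality <- match.arg(modality)
  stream <- 2 * subject_index + (modality == "fmri")
  as.integer((as.numeric(seed) + 104729 * stream) %% 2147483646 + 1)
}

# -- subject-level simulators -----------------------------------------------

#' Simulate one subject's dynamic constant-infusion PET scan
#'
#' Voxel model (region i, frame t, 1-based):
#' \deqn{y_v(t) = b_i (t + a\, x_i(t)\, [t > T - F]) + \epsilon_{vt}}
#' where \eqn{b_i} is the subject's regional baseline slope (monotone tracer
#' accumulation under constant infusion), \eqn{a} the fluctuation amplitude,
#' \eqn{x_i(t)} the unit-variance latent community fluctuation (see
#' \code{\link{make_ground_truth}}), injected only into the final \eqn{F}
#' frames (default 30; early frames carry low signal), and
#' \eqn{\epsilon \sim N(0, \sigma^2)} i.i.d. voxel noise.
#'
#' @param atlas A \code{toy_atlas}.
#' @param truth A \code{ground_truth}.
#' @param subject Subject id present in the truth.
#' @param n_frames Number of one-minute frames (default 90).
#' @param noise_sd Voxel noise sd; defaults to the truth's configuration.
#' @param seed Substream seed; defaults to the documented counter scheme
#'   applied to the truth's global seed.
#' @return 4D array (x, y, z, frame).
#' @export
simulate_subject_fpet <- function(atlas, truth, subject,
                                  n_frames = 90L,
                                  noise_sd = truth$config$noise_sd,
                                  seed = NULL) {
  stopifnot(noise_sd >= 0)
  s <- match(subject, truth$subjects$subject_id)
  if (is.na(s)) stop("unknown subject: ", subject)
  if (is.null(seed)) seed <- substream_seed(truth$seed, s, "fpet")
  set.seed(seed)
  series <- fpet_roi_signal(truth, subject, n_frames)
  roi_series_to_volume(series, atlas, noise_sd)
}

# ROI-level fPET signal (baseline ramp + windowed fluctuations), R x T.
# Consumes RNG for the latent draws only.
fpet_roi_signal <- function(truth, subject, n_frames) {
  cfg <- truth$config
  fw <- min(cfg$fluct_frames, n_frames)
  b <- truth$baselines[subject, ]
  x <- latent_roi_fluctuations(truth, subject, fw, phi = 0)
  ramp <- outer(b, seq_len(n_frames))
  fl <- matrix(0, length(b), n_frames)
  fl[, (n_frames - fw + 1):n_frames] <- cfg$fluct_amp * b * x
  ramp + fl
}

#' Simulate one subject's BOLD fMRI scan
#'
#' Region series are AR(1)-filtered latent community fluctuations with the
#' same loading structure (and motor coupling) as the PET model, on a flat
#' baseline of \code{100 * b_i}; no accumulation ramp. Cross-correlations are
#' unchanged by the AR(1) filtering, so a planted edge with weight w still
#' has model correlation w.
#'
#' @inheritParams simulate_subject_fpet
#' @param n_frames Number of BOLD time points (default 490).
#' @param ar_coefficient AR(1) coefficient in [0, 1).
#' @return 4D array (x, y, z, frame).
#' @export
simulate_subject_fmri <- function(atlas, truth, subject,
                                  n_frames = 490L,
                                  ar_coefficient = truth$config$ar_coefficient,
                                  noise_sd = truth$config$noise_sd,
                                  seed = NULL) {
  stopifnot(ar_coefficient >= 0, ar_coefficient < 1, noise_sd >= 0)
  s <- match(subject, truth$subjects$subject_id)
  if (is.na(s)) stop("unknown subject: ", subject)
  if (is.null(seed)) seed <- substream_seed(truth$seed, s, "fmri")
  set.seed(seed)
  series <- fmri_roi_signal(truth, subject, n_frames, ar_coefficient)
  roi_series_to_volume(series, atlas, noise_sd)
}

fmri_roi_signal <- function(truth, subject, n_frames, phi) {
  cfg <- truth$config
  b <- truth$baselines[subject, ]
  x <- latent_roi_fluctuations(truth, subject, n_frames, phi = phi)
  100 * b + cfg$fmri_amp * x
}

# Broadcast an R x T ROI signal matrix onto the atlas grid and add voxel
# noise (RNG state is the caller's).
roi_series_to_volume <- function(series, atlas, noise_sd) {
  dims <- dim(atlas$label_volume)
  lab <- as.vector(atlas$label_volume)
  n_frames <- ncol(series)
  vox <- matrix(0, length(lab), n_frames)
  inb <- lab > 0
  vox[inb, ] <- series[lab[inb], ]
  if (noise_sd > 0)
    vox <- vox + matrix(stats::rnorm(length(vox), 0, noise_sd), nrow(vox))
  array(vox, dim = c(dims, n_frames))
}

# -- cohort -----------------------------------------------------------------

#' Simulate a complete synthetic multimodal cohort
#'
#' Generates the toy atlas, the ground truth, and per-subject dynamic PET and
#' BOLD data. With \code{config$volumes = TRUE} full 4D arrays are produced;
#' otherwise region-by-frame series (raw, unnormalized) are attached
#' directly, with voxel noise scaled by \code{1/sqrt(n_voxels per region)} to
#' emulate region averaging. Regeneration with the same (config, seed) is
#' bit-identical; each subject draws from its own documented seed substream.
#'
#' @param config A \code{cohort_config} (or a named list of overrides).
#' @param seed Integer global seed.
#' @return Object of class \code{synthetic_cohort} with fields \code{atlas},
#'   \code{subjects}, \code{truth}, \code{seed}, and either
#'   \code{fpet_scans}/\code{fmri_scans} (lists of 4D arrays) or
#'   \code{fpet_series}/\code{fmri_series} (lists of R x T matrices).
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L) {
  config <- as_cohort_config(config)
  atlas <- make_toy_atlas(config$n_rois, config$grid_shape,
                          config$unit_assignment)
  truth <- make_ground_truth(atlas, config, seed)
  subs <- truth$subjects$subject_id
  out <- list(atlas = atlas, subjects = truth$subjects, truth = truth,
              seed = as.integer(seed), config = config)

  if (config$volumes) {
    out$fpet_scans <- lapply(subs, function(id)
      simulate_subject_fpet(atlas, truth, id, config$n_frames_fpet))
    out$fmri_scans <- lapply(subs, function(id)
      simulate_subject_fmri(atlas, truth, id, config$n_frames_fmri))
    names(out$fpet_scans) <- names(out$fmri_scans) <- subs
  } else {
    nv <- atlas$voxel_counts
    roi_noise <- function(mat, sd_vec) {
      mat + matrix(stats::rnorm(length(mat)), nrow(mat)) * sd_vec
    }
    out$fpet_series <- lapply(seq_along(subs), function(k) {
      set.seed(substream_seed(seed, k, "fpet"))
      roi_noise(fpet_roi_signal(truth, subs[k], config$n_frames_fpet),
                config$noise_sd / sqrt(nv))
    })
    out$fmri_series <- lapply(seq_along(subs), function(k) {
      set.seed(substream_seed(seed, k, "fmri"))
      roi_noise(fmri_roi_signal(truth, subs[k], config$n_frames_fmri,
                                config$ar_coefficient),
                config$noise_sd / sqrt(nv))
    })
    names(out$fpet_series) <- names(out$fmri_series) <- subs
  }
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", sum(x$subjects$group == "PD"), "PD /",
      sum(x$subjects$group == "HC"), "HC,", nrow(x$atlas$roi_table),
      "ROIs, seed", x$seed, "\n")
  invisible(x)
}

#' Ground-truth manifest
#'
#' JSON-serializable summary of the planted structure, suitable for test
#' assertions and provenance records.
#' @param cohort A \code{synthetic_cohort}.
#' @return Named list (communities, adjacency edge lists, coupling scores,
#'   severity, seed, config).
#' @export
truth_manifest <- function(cohort) {
  tr <- cohort$truth
  edges <- lapply(tr$group_adjacency, function(a) {
    ut <- which(upper.tri(a) & a != 0, arr.ind = TRUE)
    data.frame(i = as.integer(rownames(a)[ut[, 1]]),
               j = as.integer(colnames(a)[ut[, 2]]),
               sign = a[ut])
  })
  list(seed = tr$seed,
       groups = table(tr$subjects$group),
       communities = lapply(tr$communities, lapply, as.integer),
       edges = edges,
       coupling_score = as.list(tr$coupling_score),
       severity = as.list(tr$severity[!is.na(tr$severity)]),
       config = unclass(tr$config))
}
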
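# Shared fixtures: tiny cohort configurations used across test files.
# Everything is generated in code; nothing is read from disk.

# 6-ROI config with one planted motor edge of tunable strength; series mode
# keeps simulation cheap. coupling_range c(1, 1) makes the motor edge
# strength equal edge_strength exactly.
tiny_config <- function(edge_strength = 0.6, noise_sd = 0, n_pd = 1L,
                        n_hc = 1L, coupling = c(1, 1), volumes = FALSE,
                        ...) {
  cohort_config(
    n_pd = n_pd, n_hc = n_hc, n_rois = 6L, grid_shape = c(4L, 4L, 4L),
    unit_assignment = c(cortical_motor = 2L, occipital = 2L, frontal = 2L),
    hc_motor_clique = 2L,
    edge_strength = edge_strength, noise_sd = noise_sd,
    coupling_range = coupling, volumes = volumes, ...)
}

# default-conditions cohort in series mode (fast path for property tests)
series_cohort <- function(seed, ...) {
  simulate_cohort(cohort_config(volumes = FALSE, ...), seed)
}

# preprocessed fPET roi_series for one subject of a series-mode cohort
prep_series <- function(cohort, subject_id, keep_last = 30L) {
  s <- roi_series(cohort$fpet_series[[subject_id]],
                  cohort$atlas$roi_table$roi_id, "fpet", subject_id)
  s <- retain_frames(s, keep_last)
  global_mean_normalize(s, cohort$atlas$voxel_counts)
}
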
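test_that("toy atlas partitions the grid into valid contiguous parcels", {
  # forced split: 2 ROIs on 4x4x4 -> two parcels of 32 voxels
  a <- make_toy_atlas(2, c(4, 4, 4),
                      c(cortical_motor = 1L, occipital = 1L))
  expect_identical(unname(a$voxel_counts), c(32L, 32L))
  expect_setequal(unique(as.vector(a$label_volume)), c(1L, 2L))

  # default mix: every parcel has >= 8 voxels, table and volume agree
  b <- make_toy_atlas(30, c(20, 20, 20))
  expect_equal(nrow(b$roi_table), 30)
  expect_true(all(b$voxel_counts >= 8))
  expect_setequal(as.vector(b$label_volume), b$roi_table$roi_id)

  # deterministic: same call twice -> identical volumes
  expect_identical(make_toy_atlas(7, c(6, 6, 6))$label_volume,
                   make_toy_atlas(7, c(6, 6, 6))$label_volume)

  # grid too small to host parcels of >= 8 voxels
  expect_error(make_toy_atlas(10, c(4, 4, 4)), "8 voxels")
  expect_error(make_toy_atlas(3, c(4, 4, 4),
                              c(cortical_motor = 1L, frontal = 1L)),
               "sum")
})

test_that("ground truth plants a symmetric motor excess in the patient group", {
  cfg <- cohort_config(volumes = FALSE)
  atlas <- make_toy_atlas(cfg$n_rois, cfg$grid_shape, cfg$unit_assignment)
  tr <- make_ground_truth(atlas, cfg, seed = 42)

  motor <- tr$motor_rois
  for (g in c("PD", "HC")) {
    a <- tr$group_adjacency[[g]]
    expect_identical(a, t(a))
    expect_true(all(diag(a) == 0))
  }
  im <- match(motor, atlas$roi_table$roi_id)
  motor_edges <- function(a) sum(a[im, im][upper.tri(a[im, im])] != 0)
  expect_gt(motor_edges(tr$group_adjacency$PD),
            motor_edges(tr$group_adjacency$HC))

  # severity is strictly increasing in coupling before noise
  cfg0 <- cohort_config(volumes = FALSE, severity_noise_sd = 0)
  tr0 <- make_ground_truth(atlas, cfg0, seed = 42)
  pd <- tr0$subjects$group == "PD"
  expect_equal(cor(tr0$coupling_score[pd], tr0$severity[pd],
                   method = "spearman"), 1)
})

test_that("noise-free fPET reduces to the baseline ramp and exact shared factors", {
  # no edges, no noise -> every ROI mean series is exactly b_i * t
  co <- simulate_cohort(tiny_config(edge_strength = 0), seed = 7)
  b <- co$truth$baselines["sub-01", ]
  expect_equal(co$fpet_series[["sub-01"]],
               outer(unname(b), seq_len(90)), tolerance = 1e-12,
               ignore_attr = TRUE)

  # shared factor with loading 1 -> planted-edge correlation exactly 1
  co1 <- simulate_cohort(tiny_config(edge_strength = 1), seed = 7)
  s <- roi_series(co1$fpet_series[["sub-01"]], 1:6, "fpet", "sub-01")
  r <- subject_connectivity(retain_frames(s, 30))$r
  expect_equal(r[1, 2], 1, tolerance = 1e-12)
})

test_that("planted fPET edge strength is recovered in Monte Carlo", {
  # 200 patients, one planted motor edge at r = 0.6, mild voxel noise;
  # 20 regions keep the global-mean normalization's share per region small
  cfg <- cohort_config(n_pd = 200L, n_hc = 1L, n_rois = 20L,
                       grid_shape = c(8L, 8L, 4L),
                       unit_assignment = c(cortical_motor = 2L,
                                           frontal = 6L, parietal = 6L,
                                           occipital = 6L),
                       hc_motor_clique = 2L,
                       edge_strength = 0.6, noise_sd = 0.1,
                       coupling_range = c(1, 1), volumes = FALSE)
  co <- simulate_cohort(cfg, seed = 11)
  rs <- vapply(co$subjects$subject_id[co$subjects$group == "PD"],
               function(id) subject_connectivity(prep_series(co, id))$r[1, 2],
               numeric(1))
  expect_lt(mean(abs(rs - 0.6)), 0.15)
})

test_that("fMRI series carry the AR(1) signature and the full frame count", {
  # ar = 0, shared factor loading 1 -> planted-edge correlation exactly 1
  co <- simulate_cohort(tiny_config(edge_strength = 1,
                                    ar_coefficient = 0), seed = 3)
  s <- roi_series(co$fmri_series[["sub-01"]], 1:6, "fmri", "sub-01")
  expect_equal(subject_connectivity(s)$r[1, 2], 1, tolerance = 1e-12)

  # lag-1 autocorrelation of a connected ROI near the AR coefficient
  co4 <- simulate_cohort(tiny_config(edge_strength = 0.5, noise_sd = 0.1,
                                     n_pd = 100L, ar_coefficient = 0.4),
                         seed = 5)
  ac1 <- vapply(co4$subjects$subject_id[co4$subjects$group == "PD"],
                function(id) {
                  v <- co4$fmri_series[[id]][1, ]
                  cor(v[-1], v[-length(v)])
                }, numeric(1))
  expect_lt(abs(mean(ac1) - 0.4), 0.1)

  # volumetric output shape is grid x frames
  cov <- simulate_cohort(tiny_config(volumes = TRUE, n_pd = 1L), seed = 2)
  expect_identical(dim(cov$fmri_scans[["sub-01"]]), c(4L, 4L, 4L, 490L))
  expect_identical(dim(cov$fpet_scans[["sub-01"]]), c(4L, 4L, 4L, 90L))
})

test_that("cohort generation honours study group sizes and is reproducible", {
  co <- series_cohort(seed = 1)
  expect_equal(sum(co$subjects$group == "PD"), 12)
  expect_equal(sum(co$subjects$group == "HC"), 13)
  expect_identical(dim(co$fpet_series[[1]]), c(30L, 90L))
  expect_identical(dim(co$fmri_series[[1]]), c(30L, 490L))

  # bit-identical regeneration, including the manifest
  co2 <- series_cohort(seed = 1)
  expect_identical(co$fpet_series, co2$fpet_series)
  expect_identical(co$fmri_series, co2$fmri_series)
  expect_identical(truth_manifest(co), truth_manifest(co2))

  # a different seed changes the data
  co3 <- series_cohort(seed = 2)
  expect_false(identical(co$fpet_series, co3$fpet_series))

  # unknown configuration keys are rejected
  expect_error(as_cohort_config(list(n_pd = 5, bogus_key = 1)), "bogus_key")
})

test_that("planted edges dominate non-planted pairs at high coupling", {
  # strong-effect configuration: the planted motor edge must carry the
  # largest off-diagonal correlation in the subject matrix
  co <- simulate_cohort(tiny_config(edge_strength = 0.9, noise_sd = 0.05),
                        seed = 13)
  r <- subject_connectivity(prep_series(co, "sub-01"))$r
  a_true <- co$truth$group_adjacency$PD
  planted <- a_true != 0 & upper.tri(a_true)
  null_e <- a_true == 0 & upper.tri(a_true)
  expect_gt(min(abs(r[planted])), max(abs(r[null_e])))
})

test_that("subject seed substreams regenerate subjects individually", {
  cfg <- tiny_config(edge_strength = 0.5, noise_sd = 0.2, n_pd = 3L,
                     volumes = TRUE)
  co <- simulate_cohort(cfg, seed = 21)
  tr <- co$truth
  # regenerating subject 2 alone reproduces its scan bit-for-bit
  again <- simulate_subject_fpet(co$atlas, tr, "sub-02")
  expect_identical(co$fpet_scans[["sub-02"]], again)
  expect_error(simulate_subject_fpet(co$atlas, tr, "sub-99"), "unknown")
})
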
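make_scan <- function(data, mask = NULL, modality = "fpet") {
  subject_scan(data, modality, "sub-01", brain_mask = mask)
}

test_that("frame retention keeps the trailing window in order", {
  arr <- array(0, c(2, 2, 2, 90))
  arr[1, 1, 1, ] <- 1:90
  sc <- make_scan(arr)

  kept <- retain_frames(sc, 30)
  expect_identical(dim(kept$data)[4], 30L)
  expect_equal(kept$data[1, 1, 1, ], 61:90)           # frames 61..90

  expect_identical(retain_frames(sc, 90)$data, sc$data)  # identity
  expect_error(retain_frames(sc, 91), "exceeds")
})

test_that("global-mean normalization divides each frame by its in-mask mean", {
  # constant frame of 7 -> all in-mask voxels become 1
  arr <- array(7, c(2, 2, 1, 3))
  out <- global_mean_normalize(make_scan(arr))
  expect_equal(as.vector(out$data), rep(1, length(arr)))

  # two-voxel mask with values (2, 6): mean 4 -> (0.5, 1.5)
  arr2 <- array(0, c(2, 1, 1, 1))
  arr2[1, 1, 1, 1] <- 2; arr2[2, 1, 1, 1] <- 6
  out2 <- global_mean_normalize(make_scan(arr2))
  expect_equal(as.vector(out2$data), c(0.5, 1.5))

  # postcondition on synthetic data: per-frame in-mask mean exactly 1
  co <- simulate_cohort(tiny_config(edge_strength = 0.5, noise_sd = 0.3,
                                    volumes = TRUE), seed = 4)
  mask <- atlas_mask(co$atlas)
  sc <- make_scan(co$fpet_scans[["sub-01"]], mask)
  norm <- global_mean_normalize(sc)
  gm <- apply(norm$data, 4, function(f) mean(f[mask]))
  expect_equal(gm, rep(1, 90), tolerance = 1e-12)

  # idempotence
  twice <- global_mean_normalize(norm)
  expect_equal(twice$data, norm$data, tolerance = 1e-12)

  # mask sensitivity: corrupting out-of-mask voxels leaves in-mask
  # normalized values untouched
  corrupted <- sc
  corrupted$data[!rep(mask, 90)] <- 1e6
  nc <- global_mean_normalize(corrupted)
  expect_equal(nc$data[rep(mask, 90)], norm$data[rep(mask, 90)],
               tolerance = 1e-12)

  # zero in-mask mean is an error
  expect_error(global_mean_normalize(make_scan(array(0, c(2, 2, 1, 2)))),
               "zero")
})

test_that("frame summation matches closed forms", {
  expect_equal(sum_frames(make_scan(array(1, c(2, 2, 2, 3)))),
               array(3, c(2, 2, 2)))
  one <- array(runif(8), c(2, 2, 2, 1))
  expect_equal(sum_frames(make_scan(one)), one[, , , 1])

  # ramp b*t summed over retained frames 61..90 equals 2265 * b
  b <- 1.3
  ramp <- array(rep(b * (1:90), each = 8), c(2, 2, 2, 90))
  kept <- retain_frames(make_scan(ramp), 30)
  expect_equal(sum_frames(kept), array(b * sum(61:90), c(2, 2, 2)),
               tolerance = 1e-12)
  expect_equal(sum(61:90), 2265)
})

test_that("ROI extraction averages labelled voxels in roi_table order", {
  atlas <- make_toy_atlas(2, c(4, 4, 4),
                          c(cortical_motor = 1L, occipital = 1L))
  # ROI mean: two voxels (1, 3) -> 2
  arr <- array(0, c(4, 4, 4, 1))
  lab <- atlas$label_volume
  v1 <- which(lab == 1)
  arr[v1[1]] <- 1; arr[v1[2]] <- 3
  sc <- make_scan(arr, atlas_mask(atlas))
  series <- extract_roi_series(sc, atlas)
  expect_equal(series$values[1, 1], 4 / 32)   # mean over all 32 ROI voxels
  expect_identical(series$roi_ids, atlas$roi_table$roi_id)

  # rows follow roi_table order even with permuted label values
  atlas_perm <- atlas
  atlas_perm$label_volume <- 3L - atlas$label_volume  # swap labels 1 <-> 2
  s2 <- extract_roi_series(sc, atlas_perm)
  expect_identical(s2$roi_ids, atlas$roi_table$roi_id)
  expect_equal(s2$values[2, 1], 4 / 32)       # data followed the swap

  # brute-force per-voxel oracle on a random 4x4x4 scan
  set.seed(99)
  arr4 <- array(rnorm(4 * 4 * 4 * 5), c(4, 4, 4, 5))
  s4 <- extract_roi_series(make_scan(arr4), atlas)
  for (k in 1:2) for (t in 1:5) {
    acc <- 0; cnt <- 0
    for (i in 1:4) for (j in 1:4) for (l in 1:4) {
      if (atlas$label_volume[i, j, l] == k) {
        acc <- acc + arr4[i, j, l, t]; cnt <- cnt + 1
      }
    }
    expect_equal(s4$values[k, t], acc / cnt, tolerance = 1e-12)
  }

  # shape mismatch and missing labels are errors
  expect_error(extract_roi_series(make_scan(array(0, c(3, 3, 3, 2))), atlas),
               "shape")
  atlas_bad <- atlas
  atlas_bad$label_volume[atlas_bad$label_volume == 2L] <- 1L
  expect_error(extract_roi_series(sc, atlas_bad), "absent")
})

test_that("retention and extraction commute", {
  co <- simulate_cohort(tiny_config(edge_strength = 0.5, noise_sd = 0.3,
                                    volumes = TRUE), seed = 8)
  sc <- make_scan(co$fpet_scans[["sub-01"]], atlas_mask(co$atlas))
  a <- extract_roi_series(retain_frames(sc, 30), co$atlas)$values
  b <- extract_roi_series(sc, co$atlas)$values[, 61:90]
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("static uptake assembles positive subject-by-region sums", {
  co <- simulate_cohort(tiny_config(edge_strength = 0.5, noise_sd = 0.1,
                                    n_pd = 4L), seed = 6)
  ids <- co$subjects$subject_id[co$subjects$group == "PD"]
  series <- lapply(ids, function(id) prep_series(co, id))
  su <- static_uptake(series, "PD")
  expect_identical(dim(unclass(su)), c(4L, 6L))
  expect_true(all(su > 0))
  # summed normalized frames: rows sum to ~ keep_last * n_rois-weighted total
  expect_equal(unname(rowSums(sweep(unclass(su), 2,
                                    co$atlas$voxel_counts / 64, "*"))),
               rep(30, 4), tolerance = 1e-9)
})
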
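test_that("normality gate routes between Welch t and Mann-Whitney U", {
  set.seed(1)
  # exact normal scores pass the Shapiro gate deterministically
  x <- qnorm(ppoints(12))
  y <- 1.2 * qnorm(ppoints(12)) + 100

  # identical constant samples: statistic 0, p = 1
  same <- shapiro_gate_compare(rep(3, 5), rep(3, 5))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  # clear separation on normal data takes the t path
  sep <- shapiro_gate_compare(x, y)
  expect_identical(sep$statistic_name, "t_welch")
  expect_lt(sep$p, 0.001)

  # alpha_norm = 1 forces the rank path; U follows the first-sample
  # orientation and matches the brute-force pair count
  u <- shapiro_gate_compare(c(1, 2, 3), c(4, 5, 6), alpha_norm = 1)
  expect_identical(u$statistic_name, "U")
  expect_equal(unname(u$statistic), bf_u_stat(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(unname(u$statistic), 0)

  # skewed data fails the gate on its own
  skew <- shapiro_gate_compare(exp(rnorm(20, 0, 2)), exp(rnorm(20, 0, 2)))
  expect_identical(skew$statistic_name, "U")

  expect_error(shapiro_gate_compare(1:2, 1:5), "n >= 3")
})

test_that("Welch t from summaries reproduces demographic-table statistics", {
  # Age row: (59.54, 5.13, 13) vs (62.92, 9.48, 12) -> t = -1.10
  age <- t_from_summary(59.54, 5.13, 13, 62.92, 9.48, 12)
  expect_equal(round(age$statistic, 2), -1.10)
  expect_gt(age$p, 0.05)

  # depression-score row: (7.62, 6.97, 13) vs (7.33, 6.08, 12) -> t = 0.11
  bdi <- t_from_summary(7.62, 6.97, 13, 7.33, 6.08, 12)
  expect_equal(round(bdi$statistic, 2), 0.11)

  expect_equal(t_from_summary(5, 1, 10, 5, 2, 10)$statistic, 0)
  expect_error(t_from_summary(1, 0, 5, 2, 0, 5), "zero pooled")

  # equals the full-data Welch t when fed a sample's own summaries
  set.seed(2)
  for (k in 1:5) {
    a <- rnorm(8 + k, sd = 1 + k / 5); b <- rnorm(12, 1, 2)
    tt <- t.test(a, b)
    ts <- t_from_summary(mean(a), sd(a), length(a),
                         mean(b), sd(b), length(b))
    expect_equal(ts$statistic, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(ts$p, tt$p.value, tolerance = 1e-12)
  }
})

test_that("Holm correction is step-down, monotone, and bounded by Bonferroni", {
  expect_equal(holm_correct(0.03)$adjusted_p, 0.03)
  expect_equal(holm_correct(c(0.01, 0.04))$adjusted_p, c(0.02, 0.04))
  expect_equal(holm_correct(rep(1, 4))$adjusted_p, rep(1, 4))

  set.seed(3)
  for (k in 1:5) {
    p <- runif(7)
    hf <- holm_correct(p)
    expect_equal(hf$adjusted_p, bf_holm(p), tolerance = 1e-12)
    expect_true(all(hf$adjusted_p >= p))
    bonf <- pmin(1, p * length(p))
    expect_true(all(hf$adjusted_p <= bonf + 1e-12))
    # Holm rejections contain Bonferroni rejections
    expect_true(all(!(bonf < 0.05) | hf$rejected))
  }
})

test_that("Spearman severity correlation handles small-n exactly", {
  expect_equal(spearman_severity(1:8, (1:8)^3)$statistic, 1)
  expect_equal(spearman_severity(1:8, -(1:8))$statistic, -1)
  expect_identical(spearman_severity(1:8, (1:8)^2)$test_chosen_by,
                   "exact permutation p")
  big <- spearman_severity(1:12, (1:12) + rnorm(12))
  expect_identical(big$test_chosen_by, "t approximation")
  expect_error(spearman_severity(rep(1, 6), 1:6), "constant")

  # exact p agrees with the permutation null for a tiny case
  set.seed(4)
  x <- c(2.3, 1.1, 5.2, 4.4, 3.0)
  y <- c(1.0, 0.5, 4.0, 5.5, 2.0)
  got <- spearman_severity(x, y)
  rho_obs <- cor(x, y, method = "spearman")
  perms <- combinat_perms(5)
  rhos <- apply(perms, 1, function(pp) cor(rank(x), rank(y)[pp]))
  expect_equal(got$p, mean(abs(rhos) >= abs(rho_obs) - 1e-12),
               tolerance = 1e-9)
})

test_that("odds ratio is the conditional MLE with Fisher's exact p", {
  # printed sex table: HC 7/6, PD 9/3 -> OR = 0.40
  sex <- fisher_or(matrix(c(7, 6, 9, 3), 2, byrow = TRUE))
  expect_equal(round(sex$statistic, 2), 0.40)
  expect_equal(round(sex$p, 2), 0.41)

  expect_equal(fisher_or(matrix(5, 2, 2))$statistic, 1, tolerance = 1e-6)

  degen <- fisher_or(matrix(c(2, 0, 0, 2), 2))
  expect_true(is.infinite(degen$statistic))
  expect_false(is.na(degen$flag))

  expect_error(fisher_or(matrix(c(1, 0, 2, 0), 2)), "margin")

  # direction property: conditional MLE < 1 iff the sample OR < 1
  set.seed(5)
  for (k in 1:10) {
    tb <- matrix(rpois(4, 8) + 1, 2)
    s_or <- (tb[1, 1] * tb[2, 2]) / (tb[1, 2] * tb[2, 1])
    if (abs(s_or - 1) < 1e-9) next
    expect_equal(fisher_or(tb)$statistic < 1, s_or < 1)
  }
})

test_that("cross-modal association recovers affine relations and Pearson r", {
  set.seed(6)
  res1 <- subject_connectivity(roi_series(matrix(rnorm(6 * 30), 6, 30)))

  same <- cross_modal_association(res1, res1)
  expect_equal(same$pearson_r, 1, tolerance = 1e-12)
  expect_equal(same$slope, 1, tolerance = 1e-12)
  expect_equal(same$intercept, 0, tolerance = 1e-12)

  res2 <- res1
  res2$z <- 2 * res1$z + 0.1
  aff <- cross_modal_association(res1, res2)
  expect_equal(aff$slope, 2, tolerance = 1e-12)
  expect_equal(aff$intercept, 0.1, tolerance = 1e-12)
  expect_equal(aff$pearson_r, 1, tolerance = 1e-12)

  # brute-force Pearson over the vectorized upper triangle
  res3 <- subject_connectivity(roi_series(matrix(rnorm(6 * 30), 6, 30)))
  got <- cross_modal_association(res1, res3)
  ut <- upper.tri(res1$z)
  expect_equal(got$pearson_r, bf_pearson(res1$z[ut], res3$z[ut]),
               tolerance = 1e-12)
  expect_equal(got$n_edges, 15)
})

test_that("unit-degree comparison applies one Holm family per connectome", {
  rt <- data.frame(roi_id = 1:18,
                   unit = rep(c("cortical_motor", "frontal", "occipital"),
                              each = 6))
  d1 <- setNames(c(0L, 1L, 0L, 1L, 1L, 0L,
                   2L, 1L, 2L, 2L, 1L, 2L,
                   3L, 2L, 2L, 3L, 2L, 3L), 1:18)
  d2 <- setNames(c(5L, 6L, 5L, 7L, 6L, 5L,
                   2L, 2L, 1L, 2L, 1L, 2L,
                   3L, 2L, 3L, 3L, 2L, 2L), 1:18)
  out <- compare_unit_degrees(d1, d2, rt)
  expect_identical(nrow(out), 3L)
  expect_equal(out$p_holm, bf_holm(out$p), tolerance = 1e-12)
  expect_true(out$rejected[out$unit == "cortical_motor"])
  expect_false(any(out$rejected[out$unit != "cortical_motor"]))
})
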
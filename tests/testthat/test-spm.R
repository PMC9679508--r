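# Paired t fields, smoothness estimation, RFT thresholds, clusters, and
# the sign-flip permutation oracle.

test_that("paired t field matches hand computation and basic invariances", {
  Q <- 101
  A <- matrix(rep(1:8, Q), 8, Q)
  B <- matrix(0, 8, Q)
  ft <- paired_t_field(A, B)
  expect_equal(ft$df, 7)
  # differences 1..8: t = 4.5 / (2.4495 / sqrt(8)) = 5.196
  expect_equal(unique(round(ft$t, 3)), 5.196)

  expect_true(all(paired_t_field(A, A)$t == 0))
  shifted <- paired_t_field(A + 100, B + 100)
  expect_equal(shifted$t, ft$t, tolerance = 1e-9)

  expect_error(paired_t_field(A[1:2, ], B[1:2, ]), class = "emgait_pairing_error")
  expect_error(paired_t_field(A, B[, 1:50]), class = "emgait_pairing_error")
  # zero variance with nonzero mean difference is degenerate
  expect_error(paired_t_field(matrix(1, 5, 3), matrix(0, 5, 3)),
               class = "emgait_degenerate_error")
})

test_that("FWHM estimator tracks known smoothness", {
  set.seed(11)
  # white noise: mean squared normalized central-difference gradient is 1/2,
  # giving a theoretical FWHM of sqrt(4 log 2 / 0.5) = 2.355 nodes
  fw_white <- mean(replicate(100, estimate_fwhm(matrix(rnorm(8 * 101), 8))))
  expect_equal(fw_white, sqrt(4 * log(2) / 0.5), tolerance = 0.20)

  fw20 <- mean(replicate(100, estimate_fwhm(smooth_gaussian_field(8, 101, 20))))
  expect_equal(fw20, 20, tolerance = 0.15)

  R <- smooth_gaussian_field(6, 101, 15)
  expect_equal(estimate_fwhm(rbind(R, R)), estimate_fwhm(R), tolerance = 1e-9)

  expect_identical(estimate_fwhm(matrix(0, 4, 101)), Inf)
})

test_that("RFT threshold is the t quantile at infinite smoothness and is monotone", {
  expect_equal(rft_threshold(7, Inf, alpha = 0.05), qt(0.975, 7), tolerance = 1e-9)
  expect_equal(round(rft_threshold(7, Inf), 3), 2.365)

  t20 <- rft_threshold(7, 20); t10 <- rft_threshold(7, 10)
  expect_gt(t10, t20)                       # fewer resels, lower threshold
  expect_gt(rft_threshold(7, 20, m_comparisons = 5), t20)
  expect_gte(rft_threshold(5, 20), rft_threshold(20, 20))
  expect_error(rft_threshold(7, 20, alpha = 1.2), class = "emgait_config_error")
})

test_that("suprathreshold clusters are maximal runs with interpolated edges", {
  Q <- 101
  tf <- rep(0, Q)
  expect_equal(nrow(suprathreshold_clusters(tf, 3, 7, 20)), 0)

  # single excursion spanning nodes 27..52 (0-based 26..51 % stride)
  tf[28:52] <- 5
  cl <- suprathreshold_clusters(tf, 3, 7, 20)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$start_pct, 26.6, tolerance = 0.1)
  expect_equal(cl$end_pct, 51.4, tolerance = 0.1)
  expect_lte(cl$p, 0.05)

  # two excursions separated by a single sub-threshold node
  tf2 <- rep(0, Q); tf2[10:20] <- 4; tf2[22:30] <- -4
  cl2 <- suprathreshold_clusters(tf2, 3, 7, 20)
  expect_equal(nrow(cl2), 2)

  # two-tailed symmetry: flipping the field leaves the cluster set unchanged
  cl2n <- suprathreshold_clusters(-tf2, 3, 7, 20)
  expect_equal(cl2n[, c("start_pct", "end_pct", "p")],
               cl2[, c("start_pct", "end_pct", "p")])
})

test_that("exhaustive sign-flip permutation is deterministic and null-safe", {
  set.seed(21)
  A <- smooth_gaussian_field(8, 101, 20)
  B <- smooth_gaussian_field(8, 101, 20)
  p1 <- permutation_spm(A, B, seed = 1)
  p2 <- permutation_spm(A, B, seed = 999)
  expect_true(p1$exhaustive)
  expect_identical(p1$threshold, p2$threshold)   # 256 flips enumerated

  # A = B: every permutation's max |t| is 0, so the observed field can
  # never exceed the permutation threshold
  pn <- permutation_spm(A, A)
  expect_equal(max(pn$max_t), 0)
  expect_false(max(abs(paired_t_field(A, A)$t)) > pn$threshold)
})

test_that("RFT and permutation thresholds agree on smooth nulls", {
  set.seed(31)
  ratios <- replicate(12, {
    A <- smooth_gaussian_field(8, 101, 20)
    B <- smooth_gaussian_field(8, 101, 20)
    ft <- paired_t_field(A, B)
    rft_threshold(ft$df, estimate_fwhm(ft$residuals)) /
      permutation_spm(A, B)$threshold
  })
  expect_lt(abs(mean(ratios) - 1), 0.10)
})

test_that("spm_paired assembles the full chain and its methods run", {
  set.seed(41)
  A <- smooth_gaussian_field(8, 101, 20)
  B <- A - 2 + 0.3 * smooth_gaussian_field(8, 101, 20)  # strong effect + noise
  sp <- spm_paired(A, B, variable = "demo")
  expect_s3_class(sp, "emgait_spm")
  expect_gt(nrow(sp$clusters), 0)
  expect_output(print(sp), "demo")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(sp))

  expect_equal(median_stride(matrix(rep(1:101, each = 5), 5)), 1:101,
               ignore_attr = TRUE)
})
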
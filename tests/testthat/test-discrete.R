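# Mirroring, mixed-model contrasts, FDR adjustment, and the
# induction-sufficiency classifier.

test_that("mirroring negates right-sided inductions and is an involution", {
  expect_equal(mirror_for_side(10, "right"), -10)
  expect_equal(mirror_for_side(mirror_for_side(10, "right"), "right"), 10)
  expect_equal(mirror_for_side(c(-3, 5), "left"), c(-3, 5))

  df <- data.frame(min_diff_poll = c(4, -2), hip_hike = c(1, 1),
                   duration = c(0.7, 0.7))
  mr <- mirror_for_side(df, "right")
  expect_equal(mr$min_diff_poll, c(-4, 2))
  expect_equal(mr$hip_hike, c(-1, -1))
  expect_equal(mr$duration, df$duration)    # unsigned variables untouched
  expect_equal(mirror_for_side(mr, "right"), df)

  expect_equal(side_role(c("left", "right"), "left"), c("LS", "NLS"))
})

test_that("BH adjustment matches the worked example and a brute-force oracle", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.37), 0.37)
  expect_equal(fdr_adjust(c(1, 1)), c(1, 1))
  set.seed(5)
  for (i in 1:5) {
    p <- runif(7)
    expect_equal(fdr_adjust(p), bh_oracle(p), tolerance = 1e-12)
    perm <- sample(7)
    expect_equal(fdr_adjust(p[perm]), bh_oracle(p)[perm], tolerance = 1e-12)
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), class = "emgait_config_error")
})

make_contrast_table <- function(delta, gamma = 0, dspeed = 0, seed = 1,
                                n_sub = 8, n_str = 20, subj_sd = 0.1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_sub), function(s) {
    b <- rnorm(1, 0, subj_sd)
    sp <- rep(c(3.1, 3.1 + dspeed), each = n_str) + rnorm(2 * n_str, 0, 0.15)
    data.frame(subject = sprintf("S%02d", s),
               condition = rep(c("baseline1", "iFL"), each = n_str),
               variable = "v",
               value = b + rep(c(0, delta), each = n_str) + gamma * sp +
                 rnorm(2 * n_str, 0, 0.15),
               speed = sp)
  }))
}

test_that("mixed-model contrast recovers a known condition effect", {
  ct <- contrast_conditions(make_contrast_table(delta = 0.2, seed = 2))
  expect_equal(ct$note, "lmm")
  expect_lt(abs(ct$difference - 0.2), 2 * ct$se_difference)
  expect_lt(ct$p_fdr, 0.01)
})

test_that("null contrasts are non-significant at close to the nominal rate", {
  hits <- 0
  for (i in 1:60) {
    ct <- contrast_conditions(make_contrast_table(delta = 0, seed = 100 + i,
                                                  n_sub = 6, n_str = 8))
    if (ct$p_raw < 0.05) hits <- hits + 1
  }
  expect_lte(hits / 60, 0.10)   # >= 90 % of null simulations stay above 0.05
})

test_that("speed correction de-confounds a speed-driven difference", {
  tab <- make_contrast_table(delta = 0.2, gamma = 0.5, dspeed = 0.4, seed = 3)
  plain <- contrast_conditions(tab)
  corr <- contrast_conditions(tab, speed_correction = TRUE)
  # uncorrected is biased toward delta + gamma * dspeed = 0.4
  expect_gt(plain$difference, 0.3)
  expect_lt(abs(corr$difference - 0.2), 2 * corr$se_difference)
})

test_that("contrasts absorb per-subject constants in the random intercept", {
  tab <- make_contrast_table(delta = 0.15, seed = 4)
  ct1 <- contrast_conditions(tab)
  tab2 <- tab
  shift <- as.numeric(factor(tab2$subject)) * 10
  tab2$value <- tab2$value + shift
  ct2 <- contrast_conditions(tab2)
  expect_equal(ct2$difference, ct1$difference, tolerance = 1e-6)
})

test_that("percentage difference uses the baseline EM mean, n/a for signed indices", {
  tab <- rbind(make_contrast_table(delta = 0.2, seed = 6),
               transform(make_contrast_table(delta = 0.2, seed = 7),
                         variable = "min_diff_poll"))
  ct <- contrast_conditions(tab)
  expect_true(is.finite(ct$pct_difference[ct$variable == "v"]))
  expect_true(is.na(ct$pct_difference[ct$variable == "min_diff_poll"]))
})

test_that("sufficiency verdicts follow the 13 mm / 5 mm reference rules", {
  mk <- function(poll_mean, pelvis_mean = 0, sd = 1, n = 30) {
    set.seed(8)
    data.frame(min_diff_poll = rnorm(n, poll_mean, sd),
               max_diff_poll = rnorm(n, 0, sd),
               min_diff_pelvis = rnorm(n, pelvis_mean, sd),
               max_diff_pelvis = rnorm(n, 0, sd))
  }
  # head asymmetry change of -53.73 mm with small spread: sufficient
  v1 <- induction_sufficiency(mk(-3.36), mk(-57.09))
  expect_equal(v1$forelimb, "sufficient")

  # 10 mm head and 2 mm pelvis changes: below both references
  v2 <- induction_sufficiency(mk(0), mk(-10, -2))
  expect_equal(v2$forelimb, "insufficient")
  expect_equal(v2$hindlimb, "insufficient")

  # large pelvic change but SD exceeding the induced mean: variability rule
  v3 <- induction_sufficiency(mk(0, 0, sd = 0.5),
                              mk(0, -22, sd = 30, n = 200))
  expect_equal(v3$hindlimb, "insufficient")

  # missing index: indeterminate
  v4 <- induction_sufficiency(data.frame(x = 1), data.frame(x = 2))
  expect_equal(v4$forelimb, "indeterminate")
})
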
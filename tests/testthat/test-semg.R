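# sEMG conditioning, ARV, outlier rule, RVC normalization, and the
# double-threshold activation detector.

test_that("conditioning chain behaves on analytic inputs", {
  fs <- 2000; n <- 8000
  t <- (0:(n - 1)) / fs

  dc <- emg_channel("triceps", "left", rep(0.7, n))
  pd <- preprocess_emg(dc)
  expect_lt(max(abs(pd$filtered)), 1e-9)
  expect_lt(max(pd$envelope25), 1e-9)

  s100 <- emg_channel("triceps", "left", sin(2 * pi * 100 * t))
  p100 <- preprocess_emg(s100)
  expect_equal(mean(p100$rectified[1000:7000]), 2 / pi, tolerance = 0.01)

  s10 <- emg_channel("triceps", "left", sin(2 * pi * 10 * t))
  p10 <- preprocess_emg(s10)
  expect_lt(max(abs(p10$filtered[1000:7000])), 0.01)  # removed by 40 Hz HP
  expect_true(all(p10$rectified >= 0))
})

test_that("stride ARV equals the closed-form mean of rectified sinusoids", {
  fs <- 2000
  t <- (0:(fs - 1)) / fs
  A <- 0.8
  proc <- structure(list(rectified = abs(A * sin(2 * pi * 10 * t)), fs = fs,
                         muscle = "biceps", side = "left"),
                    class = "processed_emg")
  win <- data.frame(start = 0, end = 1)   # ten full periods
  arv <- stride_arv(proc, win)
  expect_equal(arv$arv_raw, 2 * A / pi, tolerance = 1e-3)

  proc$rectified <- proc$rectified * 3
  expect_equal(stride_arv(proc, win)$arv_raw, 3 * arv$arv_raw, tolerance = 1e-12)

  proc$rectified <- rep(0, fs)
  expect_equal(stride_arv(proc, win)$arv_raw, 0)

  expect_error(stride_arv(proc, data.frame(start = 5, end = 6)),
               class = "emgait_strides_error")
})

test_that("2-SD outlier rule flags strictly-outside values once, reproducibly", {
  rec <- data.frame(muscle = "triceps", side = "left", condition = "baseline1",
                    arv_raw = c(rep(1, 8), 2), outlier = FALSE)
  out <- flag_arv_outliers(rec)
  expect_identical(out$outlier, c(rep(FALSE, 8), TRUE))
  expect_identical(flag_arv_outliers(out)$outlier, out$outlier)  # single pass, no randomness

  all_eq <- data.frame(muscle = "x", side = "left", condition = "c",
                       arv_raw = rep(3.3, 6), outlier = FALSE)
  expect_false(any(flag_arv_outliers(all_eq)$outlier))

  small <- data.frame(muscle = "x", side = "left", condition = "c",
                      arv_raw = c(1, 100), outlier = FALSE)
  expect_warning(res <- flag_arv_outliers(small), "fewer than 3")
  expect_false(any(res$outlier))
})

test_that("values exactly at the 2-SD limit are kept (strictly-outside rule)", {
  # tune a probe so it sits exactly at mean + 2 SD of its own group
  base <- c(1, 2, 3, 2, 2)
  zscore <- function(p) {
    g <- c(base, p)
    (p - mean(g)) / sd(g)
  }
  p_star <- uniroot(function(p) zscore(p) - 2, c(3, 50), tol = 1e-10)$root
  rec <- data.frame(muscle = "m", side = "left", condition = "c",
                    arv_raw = c(base, p_star * (1 - 1e-6)), outlier = FALSE)
  expect_false(any(flag_arv_outliers(rec)$outlier))
  rec$arv_raw[6] <- p_star * 1.001
  expect_true(flag_arv_outliers(rec)$outlier[6])
})

test_that("RVC normalization uses the surviving baseline maximum", {
  out <- rvc_normalize(c(0.6, 0.5), baseline_values = c(0.3, 0.5, 0.4))
  expect_equal(out$rvc, 0.5)
  expect_equal(out$pct, c(120, 100))   # induced strides may exceed 100 %

  # an inflated baseline stride flagged as outlier is excluded from the RVC
  out2 <- rvc_normalize(1, baseline_values = c(0.3, 0.5, 5),
                        baseline_outlier = c(FALSE, FALSE, TRUE))
  expect_equal(out2$rvc, 0.5)

  expect_error(rvc_normalize(1, baseline_values = c(1, 2),
                             baseline_outlier = c(TRUE, TRUE)),
               class = "emgait_norm_error")
})

test_that("double-threshold detector recovers clean bursts and drops short ones", {
  fs <- 2000; n <- fs
  t <- (0:(n - 1)) / fs
  win <- data.frame(start = 0, end = 1)

  env <- numeric(n); env[t >= 0.30 & t < 0.60] <- 1
  act <- detect_activation(env, fs, win, baseline_mean_stride_duration = 1)
  expect_equal(nrow(act), 1)
  expect_equal(act$onset_pct, 30, tolerance = 1)
  expect_equal(act$offset_pct, 60, tolerance = 1)

  # 4 % burst with a 5 % timing threshold: discarded
  env4 <- numeric(n); env4[t >= 0.4 & t < 0.44] <- 1
  expect_equal(nrow(detect_activation(env4, fs, win, 1)), 0)

  # detector is invariant to positive rescaling (thresholds are relative)
  act_scaled <- detect_activation(env * 7.3, fs, win, 1)
  expect_equal(act_scaled, act, tolerance = 1e-12)

  # sub-threshold dips shorter than the timing threshold are merged
  env_dip <- env
  env_dip[t >= 0.44 & t < 0.46] <- 0
  act_dip <- detect_activation(env_dip, fs, win, 1)
  expect_equal(nrow(act_dip), 1)
  expect_equal(act_dip$offset_pct, 60, tolerance = 1)

  # flat zero envelope: zero bursts, not an error
  expect_equal(nrow(detect_activation(numeric(n), fs, win, 1)), 0)
})

test_that("two-burst activation is recovered within 1 % stride of the detectable truth", {
  sim <- sim_clean_baseline()
  ev <- events_of(sim)
  bdur <- mean(diff(ev$impacts$HR))
  res <- analyze_emg_channel(sim$trial, "semitendinosus_left", ev, bdur)
  act <- res$activation
  dt <- sim$truth$bursts$semitendinosus_left$detectable
  expect_setequal(unique(act$burst), 1:2)
  for (bi in 1:2) {
    # interior strides (the first truth stride precedes the first detected impact)
    got_on <- mean(act$onset_pct[act$burst == bi & act$stride %in% 2:6])
    exp_on <- mean(dt$onset_pct[dt$burst == bi & dt$stride %in% 3:7])
    got_off <- mean(act$offset_pct[act$burst == bi & act$stride %in% 2:6])
    exp_off <- mean(dt$offset_pct[dt$burst == bi & dt$stride %in% 3:7])
    expect_lt(abs(got_on - exp_on), 1)
    expect_lt(abs(got_off - exp_off), 1)
  }
})

test_that("stride ARV tracks the modulation ground truth within 5 %", {
  # ARV of envelope-modulated unit-variance noise ~ mean(envelope) * sqrt(2/pi)
  for (seed in 1:3) {
    sc <- scenario_preset("baseline", seed = seed, n_strides = 6,
                          stride_duration_cv = 0, emg_noise_floor = 0.02)
    sim <- simulate_trial(sc)
    ev <- detect_hindlimb_impacts(sim$trial)
    res <- analyze_emg_channel(sim$trial, "gluteal_left", ev,
                               mean(diff(ev$impacts$HR)))
    b <- sc$burst_spec$gluteal_left
    env_mean <- b$amplitude * ((b$offset - b$onset - 2) / 100) +
      0.02 * b$amplitude
    expected <- env_mean * sqrt(2 / pi)
    expect_equal(mean(res$arv$arv_raw), expected, tolerance = 0.05)
  }
})
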
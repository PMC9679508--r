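# Event detection, stride speed, asymmetry indices, angles, and
# 101-node time normalization.

test_that("noiseless impacts are recovered within 5 ms of ground truth", {
  sim <- sim_clean_baseline()
  ev <- events_of(sim)
  for (limb in c("FL", "FR", "HL", "HR")) {
    errs <- impact_errors(ev$impacts[[limb]], sim$truth$impacts[[limb]])
    expect_lt(max(errs), 0.005)
    expect_gte(length(ev$impacts[[limb]]), 7)
  }
})

test_that("a stationary horse raises an insufficient-strides error", {
  sim <- sim_clean_baseline()
  tr <- sim$trial
  n <- nrow(tr$markers$hoof_HL$xyz)
  for (limb in c("FL", "FR", "HL", "HR")) {
    nm <- paste0("hoof_", limb)
    tr$markers[[nm]]$xyz <- matrix(rep(c(0, 150, 2), each = n), n, 3)
  }
  expect_error(detect_hindlimb_impacts(tr), class = "emgait_strides_error")
})

test_that("impact rate scales inversely with stride period", {
  fast <- simulate_trial(scenario_preset("baseline", stride_duration_mean = 0.4,
                                         stride_duration_cv = 0, n_strides = 16,
                                         kinematic_noise_sd = 0, seed = 5))
  slow <- simulate_trial(scenario_preset("baseline", stride_duration_mean = 0.8,
                                         stride_duration_cv = 0, n_strides = 8,
                                         kinematic_noise_sd = 0, seed = 5))
  rate <- function(sim) {
    im <- detect_hindlimb_impacts(sim$trial)$impacts$HR
    (length(im) - 1) / (max(im) - min(im))
  }
  expect_equal(rate(fast) / rate(slow), 2, tolerance = 0.05)
})

test_that("stride speed reads the tubera sacrale horizontal velocity", {
  sim <- sim_clean_baseline()
  tr <- sim$trial
  ev <- events_of(sim)
  n <- nrow(tr$markers$tubera_sacrale$xyz)
  t <- (seq_len(n) - 1) / 200

  tr$markers$tubera_sacrale$xyz <- cbind(3500 * t, 0, 1450)
  expect_equal(stride_speed(tr, ev), rep(3.5, length(stride_windows(ev)$start)),
               tolerance = 1e-6)

  tr$markers$tubera_sacrale$xyz <- cbind(0, 0, 1450 + 40 * sin(2 * pi * t))
  expect_lt(max(stride_speed(tr, ev)), 1e-6)

  # horizontal wobble with stride-matched period averages out per stride
  T_str <- mean(diff(ev$impacts$HR))
  tr$markers$tubera_sacrale$xyz <- cbind(3300 * t + 30 * sin(2 * pi * t / T_str), 0, 1450)
  sp <- stride_speed(tr, ev)
  expect_equal(mean(sp), 3.3, tolerance = 0.01)
})

test_that("asymmetry indices read out constructed extrema differences", {
  # inject a pelvis MinDiff of -15 mm: per-stride minima differ by exactly
  # 15 mm between the two halves, left-associated deeper
  sc <- scenario_preset("baseline", kinematic_noise_sd = 0,
                        stride_duration_cv = 0, n_strides = 6,
                        min_diff_inject = c(poll = 0, withers = 0, pelvis = -15))
  sim <- simulate_trial(sc)
  ai <- asymmetry_indices(sim$trial, events_of(sim))
  expect_equal(mean(ai$min_diff_pelvis[!ai$excluded]), -15, tolerance = 0.1)
})

test_that("moderate hindlimb preset injections are recovered within 5 %", {
  sim <- sim_clean_iHL()
  ai <- asymmetry_indices(sim$trial, events_of(sim))
  ok <- !ai$excluded
  expect_equal(mean(ai$min_diff_pelvis[ok]), -22.25, tolerance = 0.05 * 22.25)
  expect_equal(mean(ai$max_diff_pelvis[ok]), -27.87, tolerance = 0.05 * 27.87)
  expect_equal(mean(ai$hip_hike[ok]), -61.73, tolerance = 0.05 * 61.73)
})

test_that("indices flip sign under left-right relabeling of the input", {
  sim <- sim_clean_iFL()
  tr <- sim$trial
  swap <- function(nm) {
    nm2 <- chartr("LR", "RL", gsub("left", "RIGHT", gsub("right", "left", nm)))
    gsub("RIGHT", "right", nm2)
  }
  mirrored <- tr
  names(mirrored$markers) <- vapply(names(tr$markers), function(nm) {
    if (grepl("_(L|R)$", nm)) sub("_(L|R)$", ifelse(grepl("_L$", nm), "_R", "_L"), nm)
    else if (grepl("hoof_[FH][LR]$", nm)) chartr("LR", "RL", nm)
    else nm
  }, character(1))
  for (nm in names(mirrored$markers)) mirrored$markers[[nm]]$name <- nm
  # flip the lateral axis so the mirrored trial is a true reflection
  for (nm in names(mirrored$markers)) {
    mirrored$markers[[nm]]$xyz[, 2] <- -mirrored$markers[[nm]]$xyz[, 2]
  }
  ai <- asymmetry_indices(tr, detect_hindlimb_impacts(tr), "HR")
  am <- asymmetry_indices(mirrored, detect_hindlimb_impacts(mirrored), "HL")
  ok <- !ai$excluded & !am$excluded
  for (v in c("min_diff_poll", "max_diff_poll", "min_diff_pelvis",
              "max_diff_pelvis", "hip_hike")) {
    expect_equal(am[[v]][ok], -ai[[v]][ok], tolerance = 1e-6,
                 info = v)
  }
})

test_that("stride durations from events tile the covered time span", {
  sim <- sim_noisy_baseline()
  ev <- events_of(sim)
  win <- stride_windows(ev, "HR")
  expect_equal(sum(win$end - win$start),
               max(ev$impacts$HR) - min(ev$impacts$HR), tolerance = 1e-9)
  ai <- asymmetry_indices(sim$trial, ev)
  expect_equal(ai$duration, win$end - win$start, tolerance = 1e-9)
})

test_that("time normalization yields exactly 101 nodes and is exact on lines", {
  fs <- 200
  x_const <- rep(7.5, 400)
  v <- time_normalize(x_const, fs, 0.2, 1.4)
  expect_length(v, 101)
  expect_equal(as.numeric(v), rep(7.5, 101))

  t <- (0:399) / fs
  ramp <- 3 * t + 1
  v2 <- time_normalize(ramp, fs, 0.25, 1.25)
  expect_equal(as.numeric(v2), 3 * seq(0.25, 1.25, length.out = 101) + 1,
               tolerance = 1e-12)

  zs <- sin(2 * pi * 2 * t)
  v3 <- time_normalize(zs, fs, 0.1, 1.6)
  expect_lt(max(abs(as.numeric(v3) - sin(2 * pi * 2 * seq(0.1, 1.6, length.out = 101)))),
            1e-3)

  expect_error(time_normalize(x_const, fs, -1, 0.5), class = "emgait_config_error")
})

test_that("joint angles follow plane geometry and static self-reference", {
  # constant-pose trial with known joint geometry on every chain
  n <- 20
  pos <- list(
    # forelimb L: collinear chain (180 deg at shoulder and elbow)
    spina_scapulae_L = c(0, 140, 1400), shoulder_L = c(0, 140, 1200),
    elbow_L = c(0, 140, 1000), carpus_L = c(0, 140, 700), mcp_L = c(0, 140, 500),
    # forelimb R: right angle at the shoulder
    spina_scapulae_R = c(0, -140, 1400), shoulder_R = c(0, -140, 1200),
    elbow_R = c(200, -140, 1200), carpus_R = c(200, -140, 900), mcp_R = c(200, -140, 700),
    # hindlimb chains collinear
    tuber_coxae_L = c(-500, 120, 1300), greater_trochanter_L = c(-500, 120, 1100),
    stifle_L = c(-500, 120, 900), tarsus_L = c(-500, 120, 600), mtp_L = c(-500, 120, 400),
    tuber_coxae_R = c(-500, -120, 1300), greater_trochanter_R = c(-500, -120, 1100),
    stifle_R = c(-500, -120, 900), tarsus_R = c(-500, -120, 600), mtp_R = c(-500, -120, 400),
    withers_T6 = c(300, 0, 1500), tubera_sacrale = c(-600, 0, 1500))
  markers <- lapply(names(pos), function(nm) {
    marker_trajectory(nm, matrix(rep(pos[[nm]], each = n), n, 3))
  })
  names(markers) <- names(pos)
  meta <- trial_meta("S1", "baseline1")
  tr <- structure(list(meta = meta, markers = markers, emg = list(),
                       duration = n / 200), class = "emgait_trial")
  res <- joint_and_limb_angles(tr, tr)
  expect_equal(mean(res$angles$shoulder_L), 180, tolerance = 1e-6)
  expect_equal(mean(res$angles$elbow_L), 180, tolerance = 1e-6)
  expect_equal(mean(res$angles$shoulder_R), 90, tolerance = 1e-6)
  expect_equal(mean(res$angles$hip_L), 180, tolerance = 1e-6)
  # static evaluated on itself: joints equal their static reference,
  # pro-retraction is zero by construction
  expect_equal(mean(res$angles$shoulder_L), res$static[["shoulder_L"]])
  expect_lt(max(abs(res$angles$fore_proretraction_L)), 1e-9)
  expect_lt(max(abs(res$angles$hind_proretraction_R)), 1e-9)
})

test_that("pro-retraction is invariant to global translation and rotation", {
  sim <- sim_clean_baseline()
  tr <- sim$trial
  st <- simulate_static(scenario_preset("baseline", kinematic_noise_sd = 0,
                                        stride_duration_cv = 0, n_strides = 4))
  base <- joint_and_limb_angles(tr, st)
  th <- 17 * pi / 180
  rot <- function(xyz) {
    cbind(cos(th) * xyz[, 1] - sin(th) * xyz[, 3] + 1234, xyz[, 2],
          sin(th) * xyz[, 1] + cos(th) * xyz[, 3] - 567)
  }
  tr2 <- tr
  for (nm in names(tr2$markers)) tr2$markers[[nm]]$xyz <- rot(tr2$markers[[nm]]$xyz)
  moved <- joint_and_limb_angles(tr2, st)
  for (v in c("fore_proretraction_L", "hind_proretraction_R", "shoulder_L", "stifle_R")) {
    expect_equal(moved$angles[[v]], base$angles[[v]], tolerance = 1e-6, info = v)
  }
})
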
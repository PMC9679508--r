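# Synthetic trot + induced-lameness trial generator.
#
# Every analysis stage in the package can be exercised against this
# generator's known ground truth: impact times, injected minima/maxima
# asymmetries, hip-hike magnitude, and per-burst EMG activation timings.

#' Define a lameness simulation scenario
#'
#' A scenario fully determines one synthetic trial: stride timing, landmark
#' displacement amplitudes, injected asymmetries (MinDiff / MaxDiff per
#' landmark, hip hike), per muscle-side burst specifications, and noise
#' levels. Asymmetries are injected by scaling alternate half-cycles of a
#' two-oscillations-per-stride vertical displacement waveform, which is
#' exactly how the indices are defined on real signals.
#'
#' @param stride_duration_mean mean stride duration, s.
#' @param stride_duration_cv coefficient of variation of stride duration
#'   (lognormal jitter; 0 = perfectly periodic).
#' @param n_strides number of strides (>= 3).
#' @param speed forward speed, m/s.
#' @param displacement_amp named vector, half-cycle lobe amplitude in mm for
#'   poll, withers, pelvis.
#' @param min_diff_inject,max_diff_inject named vectors (poll, withers,
#'   pelvis), injected per-stride MinDiff / MaxDiff in mm (left minus right).
#' @param hip_hike_inject injected hip hike, mm (left minus right swing
#'   excursion of the tubera coxae).
#' @param hike_base baseline swing-phase tuber coxae excursion, mm.
#' @param burst_spec named list (`muscle_side`) of burst definitions:
#'   `list(onset, offset, amplitude[, onset2, offset2, amplitude2])`,
#'   onset/offset in % of the muscle's segmentation stride (contralateral
#'   hindlimb impact to impact), amplitude in mV.
#' @param emg_noise_floor baseline EMG activity as a fraction of the burst
#'   amplitude.
#' @param kinematic_noise_sd additive marker noise, mm.
#' @param duty_factor stance duration as a fraction of stride duration.
#' @param seed integer RNG seed.
#' @return a `lameness_scenario` list.
#' @export
lameness_scenario <- function(stride_duration_mean = 0.77,
                              stride_duration_cv = 0.02,
                              n_strides = 10L,
                              speed = 3.3,
                              displacement_amp = c(poll = 60, withers = 35, pelvis = 45),
                              min_diff_inject = c(poll = 0, withers = 0, pelvis = 0),
                              max_diff_inject = c(poll = 0, withers = 0, pelvis = 0),
                              hip_hike_inject = 0,
                              hike_base = 70,
                              burst_spec = default_burst_spec(),
                              emg_noise_floor = 0.05,
                              kinematic_noise_sd = 1,
                              duty_factor = 0.45,
                              seed = 1L) {
  lm <- c("poll", "withers", "pelvis")
  stopifnot(all(lm %in% names(displacement_amp)),
            all(lm %in% names(min_diff_inject)),
            all(lm %in% names(max_diff_inject)))
  if (n_strides < 3L) err("n_strides must be >= 3", "emgait_config_error")
  if (any(displacement_amp <= 0)) err("displacement amplitudes must be > 0", "emgait_config_error")
  for (nm in names(burst_spec)) {
    b <- burst_spec[[nm]]
    chk <- function(on, off, amp) {
      if (is.null(on)) return(invisible())
      if (!(on >= 0 && on < off && off <= 100)) {
        err(paste0("burst for ", nm, ": need 0 <= onset < offset <= 100"),
            "emgait_config_error")
      }
      if (amp <= 0) err(paste0("burst amplitude for ", nm, " must be > 0"),
                        "emgait_config_error")
    }
    chk(b$onset, b$offset, b$amplitude)
    chk(b$onset2, b$offset2, b$amplitude2)
  }
  # lobe amplitudes must stay positive after injection
  for (l in lm) {
    if (displacement_amp[[l]] <= max(abs(min_diff_inject[[l]]),
                                     abs(max_diff_inject[[l]])) / 2) {
      err(paste0("displacement_amp for ", l,
                 " too small for the injected asymmetry"), "emgait_config_error")
    }
  }
  if (hike_base <= abs(hip_hike_inject) / 2) {
    err("hike_base too small for hip_hike_inject", "emgait_config_error")
  }
  structure(list(stride_duration_mean = stride_duration_mean,
                 stride_duration_cv = stride_duration_cv,
                 n_strides = as.integer(n_strides), speed = speed,
                 displacement_amp = displacement_amp,
                 min_diff_inject = min_diff_inject,
                 max_diff_inject = max_diff_inject,
                 hip_hike_inject = hip_hike_inject, hike_base = hike_base,
                 burst_spec = burst_spec,
                 emg_noise_floor = emg_noise_floor,
                 kinematic_noise_sd = kinematic_noise_sd,
                 duty_factor = duty_factor, seed = as.integer(seed)),
            class = "lameness_scenario")
}

#' Default per muscle-side burst specification
#'
#' Burst windows follow the qualitative trot activity pattern of the studied
#' appendicular muscles: a main burst from late swing into stance of the
#' muscle's limb, with the semitendinosus carrying a second burst around
#' hindlimb lift-off to mid-swing, so multi-burst detection is exercised.
#' Onset/offset are in % of the contralateral-hindlimb segmentation stride.
#'
#' @return named list of burst definitions.
#' @export
default_burst_spec <- function() {
  base <- list(
    triceps        = list(onset = 10, offset = 40, amplitude = 0.40),
    latissimus     = list(onset = 5,  offset = 30, amplitude = 0.30),
    gluteal        = list(onset = 15, offset = 50, amplitude = 0.50),
    biceps         = list(onset = 20, offset = 55, amplitude = 0.45),
    semitendinosus = list(onset = 12, offset = 42, amplitude = 0.50,
                          onset2 = 60, offset2 = 80, amplitude2 = 0.25))
  out <- list()
  for (m in names(base)) {
    out[[paste0(m, "_left")]] <- base[[m]]
    out[[paste0(m, "_right")]] <- base[[m]]
  }
  out
}

#' Scenario presets for baseline and moderate induced lameness
#'
#' `baseline` is a symmetric trot; `iFL_moderate` injects a head-dominant
#' asymmetry (poll MinDiff -53.73 mm, withers MinDiff -13.14 mm, among
#' others); `iHL_moderate` a pelvis-dominant one (pelvis MinDiff -22.25 mm,
#' MaxDiff -27.87 mm, hip hike -61.73 mm). The injected magnitudes are the
#' estimated marginal mean differences reported for mild induced lameness in
#' trotting horses; stride durations likewise (0.77 s baseline, 0.75 s
#' forelimb induction, 0.71 s hindlimb induction). Induction side is left.
#' Burst amplitude scalings for induced conditions are illustrative,
#' proportional to reported ARV changes.
#'
#' @param name "baseline", "iFL_moderate" or "iHL_moderate".
#' @param ... overrides passed on to [lameness_scenario()].
#' @return a `lameness_scenario`.
#' @export
scenario_preset <- function(name = c("baseline", "iFL_moderate", "iHL_moderate"),
                            ...) {
  name <- tryCatch(match.arg(name),
                   error = function(e) err(paste0("unknown scenario preset: ", name[1L]),
                                           "emgait_config_error"))
  zero <- c(poll = 0, withers = 0, pelvis = 0)
  args <- switch(name,
    baseline = list(stride_duration_mean = 0.77,
                    min_diff_inject = zero, max_diff_inject = zero,
                    hip_hike_inject = 0),
    iFL_moderate = list(stride_duration_mean = 0.75,
                        min_diff_inject = c(poll = -53.73, withers = -13.14, pelvis = 2.22),
                        max_diff_inject = c(poll = -22.29, withers = 0, pelvis = 5.61),
                        hip_hike_inject = 13.17,
                        burst_spec = scale_bursts(default_burst_spec(),
                          c(triceps_left = 1.24, triceps_right = 0.90,
                            latissimus_left = 1.11, latissimus_right = 0.92,
                            gluteal_left = 1.27, gluteal_right = 1.45,
                            biceps_left = 1.08, biceps_right = 1.31,
                            semitendinosus_left = 1.22, semitendinosus_right = 1.41))),
    iHL_moderate = list(stride_duration_mean = 0.71,
                        min_diff_inject = c(poll = -8.13, withers = 13.04, pelvis = -22.25),
                        max_diff_inject = c(poll = -9.08, withers = 0, pelvis = -27.87),
                        hip_hike_inject = -61.73,
                        burst_spec = scale_bursts(default_burst_spec(),
                          c(triceps_left = 1.06, triceps_right = 1.34,
                            latissimus_left = 1.19, latissimus_right = 1.06,
                            gluteal_left = 1.41, gluteal_right = 1.15,
                            biceps_left = 1.44, biceps_right = 2.60,
                            semitendinosus_left = 1.88, semitendinosus_right = 1.95))))
  utils::modifyList(do.call(lameness_scenario, args), list(), keep.null = TRUE)
  do.call(lameness_scenario, utils::modifyList(args, list(...)))
}

scale_bursts <- function(spec, scales) {
  for (nm in names(scales)) {
    spec[[nm]]$amplitude <- spec[[nm]]$amplitude * scales[[nm]]
    if (!is.null(spec[[nm]]$amplitude2)) {
      spec[[nm]]$amplitude2 <- spec[[nm]]$amplitude2 * scales[[nm]]
    }
  }
  spec
}

#' Raised-cosine-edged burst envelope
#'
#' Builds a smooth activation envelope over one stride: zero outside
#' `[onset_pct, offset_pct]`, raised-cosine tapers of width `ramp_pct` just
#' inside both edges, flat plateau at `amplitude` in between. Sample k
#' (1-based) corresponds to stride phase `100 * (k - 1) / stride_samples` %.
#' If `offset_pct > 100` the burst wraps across the stride boundary.
#'
#' @param onset_pct,offset_pct burst edges in % stride (onset < offset).
#' @param amplitude peak envelope value (> 0), mV.
#' @param stride_samples number of samples in the stride.
#' @param ramp_pct taper width, % stride.
#' @return numeric envelope of length `stride_samples`.
#' @export
make_burst_envelope <- function(onset_pct, offset_pct, amplitude,
                                stride_samples, ramp_pct = 2) {
  if (amplitude <= 0) err("burst amplitude must be > 0", "emgait_config_error")
  if (!(onset_pct >= 0 && onset_pct < offset_pct)) {
    err("need 0 <= onset_pct < offset_pct", "emgait_config_error")
  }
  u <- 100 * (seq_len(stride_samples) - 1L) / stride_samples
  width <- offset_pct - onset_pct
  r <- min(ramp_pct, width / 2)
  # phase relative to onset, wrapped to [0, 100)
  rel <- (u - onset_pct) %% 100
  env <- numeric(stride_samples)
  inb <- rel <= width
  rise <- inb & rel < r
  fall <- inb & rel > width - r
  flat <- inb & !rise & !fall
  env[flat] <- amplitude
  env[rise] <- amplitude * 0.5 * (1 - cos(pi * rel[rise] / r))
  env[fall] <- amplitude * 0.5 * (1 - cos(pi * (width - rel[fall]) / r))
  env
}

# local phase in [0,1) of each time point given reference impacts
stride_phase <- function(t, impacts) {
  n <- length(impacts) - 1L
  dur <- diff(impacts)
  k <- findInterval(t, impacts)
  u <- numeric(length(t))
  inside <- k >= 1L & k <= n
  u[inside] <- (t[inside] - impacts[k[inside]]) / dur[pmin(k[inside], n)]
  before <- k < 1L
  u[before] <- ((t[before] - impacts[1L]) / dur[1L]) %% 1
  after <- k > n
  u[after] <- ((t[after] - impacts[n + 1L]) / dur[n]) %% 1
  u %% 1
}

# biphasic vertical displacement with per-half lobe amplitudes
biphasic_z <- function(u, P1, N1, P2, N2) {
  s <- sin(4 * pi * u)
  half1 <- u < 0.5
  P <- ifelse(half1, P1, P2)
  N <- ifelse(half1, N1, N2)
  P * pmax(s, 0) - N * pmax(-s, 0)
}

#' Simulate one synchronized trial with ground truth
#'
#' Generates marker trajectories at 200 Hz and sEMG at 2,000 Hz for a
#' trotting quadruped. The reference stride runs from right-hindlimb impact
#' to right-hindlimb impact; the right hind and left fore land together
#' (diagonal trot), so the first half-stride carries right-hind / left-fore
#' stance. Landmark vertical displacement is a two-oscillations-per-stride
#' waveform whose alternate half-cycle lobes are scaled to produce exactly
#' the injected MinDiff / MaxDiff; tubera coxae markers carry a swing-phase
#' elevation bump sized to produce the injected hip hike; hoof trajectories
#' touch ground at the true impact times; each EMG channel is 20-450 Hz
#' band-limited Gaussian noise amplitude-modulated by its burst envelope
#' plus a noise floor. The same seed always yields the identical trial.
#'
#' @param scenario a [lameness_scenario()].
#' @param condition,induction_side,subject_id,trial_id metadata for the
#'   generated trial.
#' @return list with elements `trial` (an `emgait_trial`) and `truth`
#'   (impact/lift-off times per limb, injected indices, burst timings).
#' @export
simulate_trial <- function(scenario, condition = "baseline1",
                           induction_side = "none", subject_id = "S1",
                           trial_id = "sim1") {
  stopifnot(inherits(scenario, "lameness_scenario"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(scenario$seed)

  fs_kin <- 200; fs_emg <- 2000
  ns <- scenario$n_strides
  cv <- scenario$stride_duration_cv
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    Tk <- stats::rlnorm(ns, log(scenario$stride_duration_mean) - sdlog^2 / 2, sdlog)
  } else {
    Tk <- rep(scenario$stride_duration_mean, ns)
  }
  margin <- 0.30
  rh <- margin + cumsum(c(0, Tk))          # ns+1 right-hind impacts
  lh <- rh[1:ns] + Tk / 2                  # left hind lands mid-stride
  lh <- c(lh, rh[ns + 1L] + Tk[ns] / 2)    # one extra for segmentation
  impacts <- list(FL = rh, FR = lh, HL = lh, HR = rh)   # diagonal pairs
  total <- rh[ns + 1L] + margin
  nk <- as.integer(round(total * fs_kin))
  tkin <- (seq_len(nk) - 1L) / fs_kin
  ne <- as.integer(nk * fs_emg / fs_kin)
  temg <- (seq_len(ne) - 1L) / fs_emg
  u <- stride_phase(tkin, rh)
  duty <- scenario$duty_factor
  noise_sd <- scenario$kinematic_noise_sd
  kn <- function(n) if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)

  # --- upper-body landmarks ------------------------------------------------
  # half 1 = right-hind + left-fore stance: fore landmarks left-associated,
  # pelvis right-associated.  MinDiff/MaxDiff = left minus right extremum.
  lobes <- function(landmark) {
    A <- scenario$displacement_amp[[landmark]]
    dmin <- scenario$min_diff_inject[[landmark]]
    dmax <- scenario$max_diff_inject[[landmark]]
    if (landmark == "pelvis") {
      list(P1 = A - dmax / 2, N1 = A + dmin / 2,
           P2 = A + dmax / 2, N2 = A - dmin / 2)
    } else {
      list(P1 = A + dmax / 2, N1 = A - dmin / 2,
           P2 = A - dmax / 2, N2 = A + dmin / 2)
    }
  }
  base_z <- c(poll = 1700, withers_T6 = 1500, tubera_sacrale = 1450)
  lm_marker <- c(poll = "poll", withers = "withers_T6", pelvis = "tubera_sacrale")
  x_fwd <- scenario$speed * 1000 * tkin     # mm
  markers <- list()
  for (l in names(lm_marker)) {
    lb <- lobes(l)
    z <- base_z[[lm_marker[[l]]]] +
      biphasic_z(u, lb$P1, lb$N1, lb$P2, lb$N2) + kn(nk)
    x <- x_fwd + switch(l, poll = 900, withers = 300, pelvis = -600) + kn(nk)
    markers[[lm_marker[[l]]]] <- marker_trajectory(
      lm_marker[[l]], cbind(x, kn(nk), z), fs = fs_kin)
  }

  # --- tubera coxae: swing-phase hike bump ---------------------------------
  liftoffs <- lapply(impacts, function(im) im[-length(im)] + duty * diff(im))
  hike_bump <- function(lift, next_imp, B) {
    z <- numeric(nk)
    for (k in seq_along(lift)) {
      inw <- tkin >= lift[k] & tkin < next_imp[k]
      s <- (tkin[inw] - lift[k]) / (next_imp[k] - lift[k])
      z[inw] <- B * sin(pi * s)^2
    }
    z
  }
  BL <- scenario$hike_base + scenario$hip_hike_inject / 2
  BR <- scenario$hike_base - scenario$hip_hike_inject / 2
  tc_z_L <- 1430 + hike_bump(liftoffs$HL, impacts$HL[-1L], BL) + kn(nk)
  tc_z_R <- 1430 + hike_bump(liftoffs$HR, impacts$HR[-1L], BR) + kn(nk)
  markers$tuber_coxae_L <- marker_trajectory(
    "tuber_coxae_L", cbind(x_fwd - 550 + kn(nk), 120 + kn(nk), tc_z_L), fs = fs_kin)
  markers$tuber_coxae_R <- marker_trajectory(
    "tuber_coxae_R", cbind(x_fwd - 550 + kn(nk), -120 + kn(nk), tc_z_R), fs = fs_kin)

  # --- hooves --------------------------------------------------------------
  arc_h <- 120
  for (limb in c("FL", "FR", "HL", "HR")) {
    im <- impacts[[limb]]
    lo <- liftoffs[[limb]]
    z <- numeric(nk); x <- numeric(nk)
    x0 <- switch(limb, FL = 700, FR = 700, HL = -700, HR = -700)
    # foot placement advances one stride length per stride
    placements <- scenario$speed * 1000 * im
    xcur <- rep(placements[1L], nk)
    for (k in seq_along(lo)) {
      swing <- tkin >= lo[k] & tkin < im[k + 1L]
      s <- (tkin[swing] - lo[k]) / (im[k + 1L] - lo[k])
      z[swing] <- arc_h * sin(pi * s)^2
      xcur[swing] <- placements[k] +
        (placements[k + 1L] - placements[k]) * (s - sin(2 * pi * s) / (2 * pi))
      if (k < length(lo)) {
        stance_next <- tkin >= im[k + 1L] & tkin < lo[k + 1L]
        xcur[stance_next] <- placements[k + 1L]
      } else {
        xcur[tkin >= im[k + 1L]] <- placements[k + 1L]
      }
    }
    y <- switch(limb, FL = 150, HL = 150, FR = -150, HR = -150)
    markers[[paste0("hoof_", limb)]] <- marker_trajectory(
      paste0("hoof_", limb), cbind(x0 + xcur + kn(nk), y + kn(nk),
                                   z + kn(nk)), fs = fs_kin)
  }

  # --- appendicular chains (sagittal, for joint/pro-retraction angles) -----
  markers <- c(markers, limb_chain_markers(tkin, u, x_fwd, kn, fs_kin))

  # --- sEMG ----------------------------------------------------------------
  emg <- list()
  truth_bursts <- list()
  for (nm in names(scenario$burst_spec)) {
    b <- scenario$burst_spec[[nm]]
    side <- sub("^.*_", "", nm)
    seg <- if (side == "left") impacts$HR else impacts$HL  # contralateral hind
    env <- numeric(ne)
    for (k in seq_len(length(seg) - 1L)) {
      inw <- which(temg >= seg[k] & temg < seg[k + 1L])
      if (!length(inw)) next
      e1 <- make_burst_envelope(b$onset, b$offset, b$amplitude, length(inw))
      env[inw] <- e1
      if (!is.null(b$onset2)) {
        env[inw] <- env[inw] +
          make_burst_envelope(b$onset2, b$offset2, b$amplitude2, length(inw))
      }
    }
    carrier <- zerophase_butter(stats::rnorm(ne), c(20, 450), fs_emg, "pass")
    carrier <- carrier / stats::sd(carrier)
    amp_max <- max(b$amplitude, if (!is.null(b$amplitude2)) b$amplitude2 else 0)
    floor_lvl <- scenario$emg_noise_floor * amp_max
    sig <- (env + floor_lvl) * carrier + 0.02
    emg[[nm]] <- emg_channel(sub("_.*$", "", nm), side, sig, fs = fs_emg)
    # detectable timings: activation timing is defined on the 10 Hz envelope,
    # whose smoothing widens every burst edge; the honest timing ground
    # truth is therefore the threshold crossing of the ideal (noise-free)
    # envelope under the same smoothing
    ideal10 <- pmax(0, zerophase_butter(env + floor_lvl, 10, fs_emg, "low"))
    seg_win <- data.frame(start = seg[-length(seg)], end = seg[-1L])
    detectable <- detect_activation(ideal10, fs_emg, seg_win,
                                    scenario$stride_duration_mean)
    truth_bursts[[nm]] <- list(
      onset = b$onset, offset = b$offset,
      onset2 = b$onset2, offset2 = b$offset2,
      amplitude = b$amplitude, segmentation = if (side == "left") "HR" else "HL",
      detectable = detectable)
  }

  meta <- trial_meta(subject_id, condition, induction_side,
                     fs_kin, fs_emg, trial_id)
  trial <- new_trial(meta, markers, emg)
  truth <- list(impacts = lapply(impacts, function(v) v[v <= total]),
                liftoffs = liftoffs,
                stride_durations = Tk,
                min_diff = scenario$min_diff_inject,
                max_diff = scenario$max_diff_inject,
                hip_hike = scenario$hip_hike_inject,
                bursts = truth_bursts,
                speed = scenario$speed)
  list(trial = trial, truth = truth)
}

# simple sagittal fore/hind limb chains driven by a pro-retraction oscillation
limb_chain_markers <- function(tkin, u, x_fwd, kn, fs_kin) {
  nk <- length(tkin)
  deg <- pi / 180
  out <- list()
  chains <- list(
    list(side = "L", fore = TRUE,  phase = 0.0),   # LF moves with half 1
    list(side = "R", fore = TRUE,  phase = 0.5),
    list(side = "L", fore = FALSE, phase = 0.5),
    list(side = "R", fore = FALSE, phase = 0.0))
  for (ch in chains) {
    pro <- 15 * deg * sin(2 * pi * (u - ch$phase))   # pro-retraction, rad
    flex <- 8 * deg * (1 - cos(2 * pi * (u - ch$phase)))
    y <- if (ch$side == "L") 140 else -140
    if (ch$fore) {
      top <- cbind(x_fwd + 450, y, 1450)
      segs <- c(shoulder = 280, elbow = 300, carpus = 350, mcp = 250)
      names_out <- c("spina_scapulae", "shoulder", "elbow", "carpus", "mcp")
    } else {
      top <- cbind(x_fwd - 550, y, 1400)
      segs <- c(greater_trochanter = 250, stifle = 330, tarsus = 360, mtp = 260)
      names_out <- c("tuber_coxae2", "greater_trochanter", "stifle", "tarsus", "mtp")
    }
    # chain: successive segments rotated by pro-retraction plus growing flexion
    pos <- top
    if (names_out[1L] == "spina_scapulae") {
      out[[paste0("spina_scapulae_", ch$side)]] <- marker_trajectory(
        paste0("spina_scapulae_", ch$side),
        cbind(pos[, 1] + kn(nk), pos[, 2] + kn(nk), pos[, 3] + kn(nk)),
        fs = fs_kin)
    }
    ang <- pro
    for (j in seq_along(segs)) {
      L <- segs[[j]]
      ang <- ang + (j - 1L) * 0.35 * flex * (-1)^j
      pos <- cbind(pos[, 1] + L * sin(ang), pos[, 2], pos[, 3] - L * cos(ang))
      nm <- paste0(names_out[j + 1L], "_", ch$side)
      out[[nm]] <- marker_trajectory(
        nm, cbind(pos[, 1] + kn(nk), rep(y, nk) + kn(nk), pos[, 3] + kn(nk)),
        fs = fs_kin)
    }
  }
  out
}

#' Simulate a standing (static) reference trial
#'
#' A short recording of the same marker set in a square standing pose with
#' all limbs vertical, used as the reference pose for joint and
#' pro-retraction angle computation.
#'
#' @param scenario a [lameness_scenario()] (noise level and seed are reused).
#' @param duration_s length of the static trial, s.
#' @return an `emgait_trial`.
#' @export
simulate_static <- function(scenario, duration_s = 1) {
  static <- scenario
  static$kinematic_noise_sd <- 0
  sim <- simulate_trial(static, trial_id = "static")
  tr <- sim$trial
  nk <- max(13L, as.integer(duration_s * tr$meta$fs_kin))
  ne <- as.integer(nk * tr$meta$fs_emg / tr$meta$fs_kin)
  for (nm in names(tr$markers)) {
    first <- tr$markers[[nm]]$xyz[1L, , drop = FALSE]
    tr$markers[[nm]]$xyz <- first[rep(1L, nk), , drop = FALSE]
    tr$markers[[nm]]$missing <- rep(FALSE, nk)
  }
  # freeze limbs vertical: rebuild chains at phase with zero pro-retraction
  frozen <- limb_chain_markers(rep(0, nk), rep(0, nk), rep(0, nk),
                               function(n) numeric(n), tr$meta$fs_kin)
  for (nm in names(frozen)) tr$markers[[nm]] <- frozen[[nm]]
  for (nm in names(tr$emg)) tr$emg[[nm]]$samples <- rep(0.0, ne)
  tr$duration <- nk / tr$meta$fs_kin
  tr$meta$trial_id <- "static"
  tr
}
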
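# Gait event detection, stride segmentation, asymmetry indices, joint and
# pro-retraction angles, and 101-node time normalization.

#' Detect hoof impact (and lift-off) events
#'
#' Impacts are located per hoof from the 10 Hz low-passed vertical hoof
#' trajectory: within each run of samples below a height threshold (minimum
#' plus 5 % of the hoof's vertical range), the local height minimum is
#' found and the impact placed at the downward zero-crossing of vertical
#' velocity nearest before it (linearly interpolated). Lift-off is the
#' matching upward threshold crossing at the end of the stance run.
#'
#' @param trial an `emgait_trial` with hoof markers.
#' @param height_frac stance height threshold as a fraction of the vertical
#'   range.
#' @return a `gait_events` list: `impacts` and `liftoffs` per limb (s).
#' @export
detect_hindlimb_impacts <- function(trial, height_frac = 0.05) {
  stopifnot(inherits(trial, "emgait_trial"))
  fs <- trial$meta$fs_kin
  out_imp <- list(); out_lift <- list()
  for (limb in c("FL", "FR", "HL", "HR")) {
    m <- trial$markers[[paste0("hoof_", limb)]]
    if (is.null(m)) err(paste0("missing hoof marker for limb ", limb),
                        "emgait_schema_error")
    z <- lowpass_kinematics(interpolate_gaps(m))$xyz[, 3L]
    rng <- max(z) - min(z)
    if (rng < 10) {   # essentially flat: no locomotion
      err(paste0("limb ", limb, ": fewer than 3 impacts detected"),
          "emgait_strides_error")
    }
    thr <- min(z) + height_frac * rng
    below <- z < thr
    runs <- mask_runs(below)
    nz <- length(z)
    v <- (z[c(2:nz, nz)] - z[c(1L, 1:(nz - 1L))]) * fs / c(1, rep(2, nz - 2L), 1)
    t <- (seq_along(z) - 1L) / fs
    imps <- c(); lifts <- c()
    for (r in seq_len(nrow(runs))) {
      s <- runs$start[r]; e <- runs$end[r]
      if (s <= 2L) next                       # touchdown not observed
      kmin <- s - 1L + which.min(z[s:e])
      # steepest descent within the swing preceding this stance
      prev_end <- if (r > 1L) runs$end[r - 1L] else 1L
      back <- max(prev_end + 1L, kmin - as.integer(fs)):kmin
      ipk <- back[which.min(v[back])]
      vmin <- v[ipk]
      if (vmin >= 0) next
      # the low-pass smears the velocity kink at touchdown; the descent
      # itself is preserved, so extrapolate its straight mid-section
      # (40-80 % of peak descent speed) to the zero crossing
      fitw <- ipk:min(nz, ipk + as.integer(fs))
      fitw <- fitw[v[fitw] <= 0.4 * vmin & v[fitw] >= 0.8 * vmin & fitw >= ipk]
      fitw <- fitw[fitw <= kmin]
      if (length(fitw) >= 3L) {
        b <- stats::coef(stats::lm.fit(cbind(1, t[fitw]), v[fitw]))
        if (b[2L] > 0) {
          imps <- c(imps, as.numeric(-b[1L] / b[2L]))
        }
      } else {
        # too few points (short swing): fall back to the first non-negative
        # velocity sample after the descent
        j <- ipk
        while (j < nz && v[j + 1L] < 0) j <- j + 1L
        frac <- if (j < nz && v[j + 1L] != v[j]) v[j] / (v[j] - v[j + 1L]) else 0
        imps <- c(imps, t[j] + frac / fs)
      }
      if (e < nz) lifts <- c(lifts, t[e] + 0.5 / fs)
    }
    if (length(imps) < 3L) {
      err(paste0("limb ", limb, ": fewer than 3 impacts detected"),
          "emgait_strides_error")
    }
    out_imp[[limb]] <- imps
    out_lift[[limb]] <- lifts
  }
  structure(list(impacts = out_imp, liftoffs = out_lift, fs = fs),
            class = "gait_events")
}

#' Stride windows from gait events
#'
#' Half-open impact-to-impact windows of the reference limb.
#'
#' @param events a `gait_events`.
#' @param limb reference limb ("HR", "HL", "FR", "FL").
#' @return data.frame with `start`, `end` (s), one row per stride.
#' @export
stride_windows <- function(events, limb = "HR") {
  im <- events$impacts[[limb]]
  if (length(im) < 2L) err("not enough impacts for stride windows",
                           "emgait_strides_error")
  data.frame(start = im[-length(im)], end = im[-1L])
}

#' Per-stride forward speed
#'
#' Speed of the tubera sacrale marker: horizontal (x, y) coordinates are
#' 10 Hz low-passed, differentiated by central differences, and the speed
#' magnitude averaged over each stride window.
#'
#' @param trial an `emgait_trial`.
#' @param events a `gait_events`.
#' @param limb reference limb for stride windows.
#' @return numeric vector, m/s per stride (NA where the marker is masked
#'   throughout the stride).
#' @export
stride_speed <- function(trial, events, limb = "HR") {
  m <- trial$markers$tubera_sacrale
  if (is.null(m)) err("tubera_sacrale marker required for stride speed",
                      "emgait_schema_error")
  fs <- trial$meta$fs_kin
  sm <- lowpass_kinematics(interpolate_gaps(m))
  xy <- sm$xyz[, 1:2] / 1000           # m
  n <- nrow(xy)
  vx <- (xy[c(2:n, n), 1] - xy[c(1, 1:(n - 1)), 1]) * fs / c(1, rep(2, n - 2), 1)
  vy <- (xy[c(2:n, n), 2] - xy[c(1, 1:(n - 1)), 2]) * fs / c(1, rep(2, n - 2), 1)
  sp <- sqrt(vx^2 + vy^2)
  sp[sm$missing] <- NA
  t <- (seq_len(n) - 1L) / fs
  win <- stride_windows(events, limb)
  vapply(seq_len(nrow(win)), function(k) {
    sel <- t >= win$start[k] & t < win$end[k]
    v <- sp[sel]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
}

#' Per-stride movement asymmetry indices
#'
#' Computes MinDiff and MaxDiff of poll, withers and pelvis (tubera
#' sacrale) vertical displacement, hip hike, stride duration and stride
#' speed for every stride. Displacements are gap-interpolated and high-pass
#' filtered with the stride-frequency-adaptive filter before the per-stride
#' extrema are read out. Each stride is split at the contralateral hindlimb
#' impact into its two diagonal stance halves; MinDiff / MaxDiff is the
#' left-limb-associated extremum minus the right-limb-associated one
#' (forelimb stance halves for poll and withers, hindlimb halves for the
#' pelvis). Hip hike is the left tuber coxae upward excursion during left
#' hindlimb swing minus the right during right hindlimb swing. Strides
#' overlapping masked samples, or missing an extremum, are flagged
#' `excluded` rather than dropped silently.
#'
#' @param trial an `emgait_trial`.
#' @param events a `gait_events`.
#' @param limb reference hindlimb for stride segmentation ("HR" or "HL").
#' @return data.frame, one row per stride: stride id, window, duration,
#'   speed, `min_diff_*` / `max_diff_*` for poll, withers, pelvis (mm),
#'   `hip_hike` (mm), `excluded` flag.
#' @export
asymmetry_indices <- function(trial, events, limb = "HR") {
  stopifnot(limb %in% c("HR", "HL"))
  fs <- trial$meta$fs_kin
  win <- stride_windows(events, limb)
  nstr <- nrow(win)
  durs <- win$end - win$start
  stride_freq <- 1 / mean(durs)
  contra <- if (limb == "HR") "HL" else "HR"
  # association of half 1 (reference-limb stance): diagonal trot couples the
  # reference hind with the contralateral fore.
  half1_assoc_pelvis <- if (limb == "HR") "right" else "left"
  half1_assoc_fore <- if (limb == "HR") "left" else "right"

  lm_marker <- c(poll = "poll", withers = "withers_T6", pelvis = "tubera_sacrale")
  filt <- list(); masked <- list()
  for (l in names(lm_marker)) {
    m <- interpolate_gaps(trial$markers[[lm_marker[[l]]]])
    if (is.null(m)) err(paste0("missing marker ", lm_marker[[l]]), "emgait_schema_error")
    filt[[l]] <- adaptive_highpass(ifelse(m$missing, NA, m$xyz[, 3L])
                                   |> fill_na_linear(),
                                   stride_freq, fs)
    masked[[l]] <- m$missing
  }
  tcL <- lowpass_kinematics(interpolate_gaps(trial$markers$tuber_coxae_L))
  tcR <- lowpass_kinematics(interpolate_gaps(trial$markers$tuber_coxae_R))
  t <- (seq_along(filt$poll) - 1L) / fs

  res <- data.frame(stride = seq_len(nstr), t_start = win$start, t_end = win$end,
                    duration = durs,
                    speed = stride_speed(trial, events, limb))
  for (l in names(lm_marker)) {
    res[[paste0("min_diff_", l)]] <- NA_real_
    res[[paste0("max_diff_", l)]] <- NA_real_
  }
  res$hip_hike <- NA_real_
  res$excluded <- FALSE

  contra_imp <- events$impacts[[contra]]
  for (k in seq_len(nstr)) {
    s <- win$start[k]; e <- win$end[k]
    split <- contra_imp[contra_imp > s & contra_imp < e]
    split <- if (length(split)) split[1L] else (s + e) / 2
    h1 <- t >= s & t < split
    h2 <- t >= split & t < e
    if (!any(h1) || !any(h2)) { res$excluded[k] <- TRUE; next }
    for (l in names(lm_marker)) {
      if (any(masked[[l]][t >= s & t < e])) { res$excluded[k] <- TRUE; next }
      z <- filt[[l]]
      m1 <- min(z[h1]); m2 <- min(z[h2])
      M1 <- max(z[h1]); M2 <- max(z[h2])
      assoc1 <- if (l == "pelvis") half1_assoc_pelvis else half1_assoc_fore
      if (assoc1 == "left") {
        res[[paste0("min_diff_", l)]][k] <- m1 - m2
        res[[paste0("max_diff_", l)]][k] <- M1 - M2
      } else {
        res[[paste0("min_diff_", l)]][k] <- m2 - m1
        res[[paste0("max_diff_", l)]][k] <- M2 - M1
      }
    }
    # hip hike: ipsilateral swing windows inside this stride
    excL <- swing_excursion(tcL, events, "HL", s, e, fs)
    excR <- swing_excursion(tcR, events, "HR", s, e, fs)
    if (is.na(excL) || is.na(excR)) res$excluded[k] <- res$excluded[k] | is.na(excL) | is.na(excR)
    res$hip_hike[k] <- excL - excR
  }
  attr(res, "ref_limb") <- limb
  attr(res, "stride_frequency") <- stride_freq
  res
}

fill_na_linear <- function(z) {
  if (!anyNA(z)) return(z)
  idx <- which(!is.na(z))
  if (length(idx) < 2L) return(z)
  stats::approx(idx, z[idx], xout = seq_along(z), rule = 2)$y
}

# upward excursion (max - min) of a tuber coxae trace during the ipsilateral
# hindlimb swing phase that falls inside [s, e)
swing_excursion <- function(tc, events, hind, s, e, fs) {
  lo <- events$liftoffs[[hind]]
  im <- events$impacts[[hind]]
  t <- (seq_len(nrow(tc$xyz)) - 1L) / fs
  # swing = lift-off to next impact; pick the swing starting inside [s, e)
  for (k in seq_along(lo)) {
    nxt <- im[im > lo[k]]
    if (!length(nxt)) next
    if (lo[k] >= s - 1e-9 && lo[k] < e) {
      sel <- t >= lo[k] & t < nxt[1L]
      if (!any(sel) || any(tc$missing[sel])) return(NA_real_)
      z <- tc$xyz[sel, 3L]
      return(max(z) - min(z))
    }
  }
  NA_real_
}

#' Time-normalize a series onto 101 stride nodes
#'
#' Linear interpolation of a regularly sampled series onto 101 equally
#' spaced nodes spanning one stride window (node 0 = window start, node 100
#' = window end).
#'
#' @param x numeric series.
#' @param fs sampling rate of `x`, Hz.
#' @param start,end stride window, s (half-open in segmentation; the final
#'   node sits on `end`).
#' @return numeric vector of length 101; attribute `flagged` is TRUE when
#'   the window contains non-finite data.
#' @export
time_normalize <- function(x, fs, start, end) {
  t <- (seq_along(x) - 1L) / fs
  if (start < t[1L] - 1e-9 || end > t[length(t)] + 1e-9 || end <= start) {
    err("stride window outside series span", "emgait_config_error")
  }
  nodes <- seq(start, end, length.out = 101L)
  y <- stats::approx(t, x, xout = nodes, rule = 2)$y
  structure(y, flagged = anyNA(x[t >= start & t <= end]))
}

#' Sagittal joint and limb pro-retraction angles
#'
#' Interior sagittal-plane (x-z) angles at the shoulder, elbow (forelimb)
#' and hip, stifle, tarsus (hindlimb) for both sides, plus signed limb
#' pro-retraction angles: the forelimb line (spina scapulae to
#' metacarpophalangeal joint) and hindlimb line (tuber coxae to
#' metatarsophalangeal joint) measured against the trunk line (T6 marker to
#' tubera sacrale), protraction positive, referenced to the static-trial
#' pose so a square stance reads 0 degrees.
#'
#' @param trial dynamic `emgait_trial`.
#' @param static_trial standing reference `emgait_trial` with the same
#'   marker set.
#' @return list with `angles` (named list of series, deg), `static`
#'   (named static reference values, deg) and `fs`.
#' @export
joint_and_limb_angles <- function(trial, static_trial) {
  defs <- list(
    shoulder = c("spina_scapulae", "shoulder", "elbow"),
    elbow    = c("shoulder", "elbow", "carpus"),
    hip      = c("tuber_coxae", "greater_trochanter", "stifle"),
    stifle   = c("greater_trochanter", "stifle", "tarsus"),
    tarsus   = c("stifle", "tarsus", "mtp"))
  angles <- list(); static_ref <- c()
  for (side in c("L", "R")) {
    for (j in names(defs)) {
      mk <- paste0(defs[[j]], "_", side)
      dyn <- interior_angle(trial, mk)
      st <- mean(interior_angle(static_trial, mk), na.rm = TRUE)
      nm <- paste0(j, "_", side)
      angles[[nm]] <- dyn
      static_ref[nm] <- st
    }
    for (limb in c("fore", "hind")) {
      mk <- if (limb == "fore") c(paste0("spina_scapulae_", side), paste0("mcp_", side))
            else c(paste0("tuber_coxae_", side), paste0("mtp_", side))
      dyn <- proretraction_angle(trial, mk)
      st <- mean(proretraction_angle(static_trial, mk), na.rm = TRUE)
      nm <- paste0(limb, "_proretraction_", side)
      angles[[nm]] <- dyn - st
      static_ref[nm] <- 0
    }
  }
  list(angles = angles, static = static_ref, fs = trial$meta$fs_kin)
}

get_marker <- function(trial, name) {
  m <- trial$markers[[name]]
  if (is.null(m)) err(paste0("missing marker ", name), "emgait_schema_error")
  m
}

# interior angle (deg) at the middle of three markers, x-z plane;
# masked samples give NA
interior_angle <- function(trial, names3) {
  a <- get_marker(trial, names3[1L]); b <- get_marker(trial, names3[2L])
  c_ <- get_marker(trial, names3[3L])
  v1 <- a$xyz[, c(1, 3)] - b$xyz[, c(1, 3)]
  v2 <- c_$xyz[, c(1, 3)] - b$xyz[, c(1, 3)]
  dotp <- rowSums(v1 * v2)
  nrm <- sqrt(rowSums(v1^2) * rowSums(v2^2))
  ang <- acos(pmin(1, pmax(-1, dotp / nrm))) * 180 / pi
  ang[a$missing | b$missing | c_$missing] <- NA
  ang
}

# signed angle (deg) between the proximal->distal limb line and the
# downward trunk normal; positive = distal end cranial (protraction)
proretraction_angle <- function(trial, names2) {
  p <- get_marker(trial, names2[1L]); d <- get_marker(trial, names2[2L])
  t6 <- get_marker(trial, "withers_T6"); ts <- get_marker(trial, "tubera_sacrale")
  limb <- d$xyz[, c(1, 3)] - p$xyz[, c(1, 3)]
  trunk <- ts$xyz[, c(1, 3)] - t6$xyz[, c(1, 3)]   # points caudal (-x)
  # downward normal of the trunk line: rotate the caudal trunk unit vector
  # 90 degrees so that for a level trunk it is (0, -1)
  nx <- -trunk[, 2L]; nz <- trunk[, 1L]
  flip <- nz > 0                                   # keep the normal downward
  nx[flip] <- -nx[flip]; nz[flip] <- -nz[flip]
  lx <- limb[, 1L]; lz <- limb[, 2L]
  ang <- atan2(nx * lz - nz * lx, nx * lx + nz * lz) * 180 / pi
  ang[p$missing | d$missing | t6$missing | ts$missing] <- NA
  ang
}
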
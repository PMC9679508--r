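# sEMG conditioning chain, stride ARV with outlier rejection and RVC
# normalization, and double-threshold activation timing detection.

#' Condition a raw sEMG channel
#'
#' DC offset (channel mean) removal, zero-phase 4th-order Butterworth
#' high-pass at 40 Hz, full-wave rectification, and two linear envelopes of
#' the rectified signal: 25 Hz low-pass (amplitude normalization and
#' continuous analysis) and 10 Hz low-pass (activation timing detection).
#' Envelopes are clipped at zero, since zero-phase low-passing a rectified
#' signal can undershoot slightly near sharp burst edges.
#'
#' @param raw an [emg_channel()].
#' @param hp_cutoff high-pass cutoff, Hz.
#' @return a `processed_emg` list: `filtered`, `rectified`, `envelope25`,
#'   `envelope10`, `fs`, `muscle`, `side`.
#' @export
preprocess_emg <- function(raw, hp_cutoff = 40) {
  stopifnot(inherits(raw, "emg_channel"))
  fs <- attr(raw, "fs")
  if (fs < 2 * 25 * 2) err("sampling rate too low for the envelope cutoffs",
                           "emgait_config_error")
  x <- raw$samples - mean(raw$samples)
  filtered <- zerophase_butter(x, hp_cutoff, fs, "high")
  rectified <- abs(filtered)
  structure(list(filtered = filtered, rectified = rectified,
                 envelope25 = pmax(0, zerophase_butter(rectified, 25, fs, "low")),
                 envelope10 = pmax(0, zerophase_butter(rectified, 10, fs, "low")),
                 fs = fs, muscle = raw$muscle, side = raw$side),
            class = "processed_emg")
}

#' Stride-wise average rectified value
#'
#' ARV = mean of the full-wave rectified signal over each stride window.
#' Stride windows must come from the hindlimb contralateral to the
#' channel's side (left-sided muscles are segmented on right hind impacts).
#'
#' @param proc a `processed_emg`.
#' @param windows data.frame with `start`, `end` (s), as from
#'   [stride_windows()].
#' @return data.frame: stride, muscle, side, arv_raw (mV), outlier flag
#'   (initialized FALSE).
#' @export
stride_arv <- function(proc, windows) {
  stopifnot(inherits(proc, "processed_emg"))
  t <- (seq_along(proc$rectified) - 1L) / proc$fs
  arv <- vapply(seq_len(nrow(windows)), function(k) {
    sel <- t >= windows$start[k] & t < windows$end[k]
    if (!any(sel)) err("empty stride window in ARV computation", "emgait_strides_error")
    mean(proc$rectified[sel])
  }, numeric(1))
  data.frame(stride = seq_len(nrow(windows)), muscle = proc$muscle,
             side = proc$side, arv_raw = arv, outlier = FALSE)
}

#' Flag ARV outlier strides (2-SD rule)
#'
#' Within each group (subject x muscle-side x condition), values strictly
#' outside mean +/- `n_sd` standard deviations (n-1 denominator) are
#' flagged. A single pass only - limits are not re-estimated after
#' exclusion - and values exactly on a limit are kept. Groups smaller than
#' 3 are left unflagged with a warning.
#'
#' @param records data.frame with a `value` column (or `arv_raw`) and
#'   grouping columns.
#' @param group character vector of grouping column names.
#' @param n_sd number of standard deviations (default 2).
#' @param value_col column to screen.
#' @return `records` with the `outlier` column updated.
#' @export
flag_arv_outliers <- function(records, group = c("muscle", "side", "condition"),
                              n_sd = 2, value_col = "arv_raw") {
  group <- intersect(group, names(records))
  key <- interaction(records[group], drop = TRUE)
  out <- rep(FALSE, nrow(records))
  for (g in levels(key)) {
    idx <- which(key == g)
    v <- records[[value_col]][idx]
    if (length(idx) < 3L) {
      warning("outlier screening skipped for group ", g, " (fewer than 3 strides)")
      next
    }
    mu <- mean(v); sdv <- stats::sd(v)
    out[idx] <- v < mu - n_sd * sdv | v > mu + n_sd * sdv
  }
  records$outlier <- out
  records
}

#' Reference-voluntary-contraction normalization
#'
#' Expresses amplitudes as a percentage of a baseline-condition reference:
#' the maximum non-outlier baseline value (the maximum stride ARV for ARV
#' data, the maximum stride envelope peak for envelope data). Induced
#' conditions may legitimately exceed 100 %.
#'
#' @param values numeric amplitudes to normalize.
#' @param baseline_values baseline-condition amplitudes (same units).
#' @param baseline_outlier logical outlier flags aligned with
#'   `baseline_values`.
#' @return list: `pct` (normalized values, %) and `rvc` (the reference).
#' @export
rvc_normalize <- function(values, baseline_values,
                          baseline_outlier = rep(FALSE, length(baseline_values))) {
  keep <- baseline_values[!baseline_outlier]
  if (!length(keep)) err("no surviving baseline strides for RVC normalization",
                         "emgait_norm_error")
  rvc <- max(keep)
  if (rvc <= 0) err("baseline RVC is not positive", "emgait_norm_error")
  list(pct = 100 * values / rvc, rvc = rvc)
}

#' Double-threshold muscle activation detection
#'
#' Candidate active regions are samples where the 10 Hz envelope strictly
#' exceeds `amp_fraction` of the signal's peak envelope value. Sub-threshold
#' dips shorter than the timing threshold (`timing_fraction` of the baseline
#' mean stride duration) are merged into the surrounding burst, and bursts
#' shorter than the timing threshold are discarded. Onsets and offsets are
#' reported in % of the containing stride (linearly interpolated threshold
#' crossings). The amplitude fraction may be adjusted by +/- 0.05 per
#' channel where visual inspection warrants it; it is never auto-adjusted.
#'
#' @param envelope10 non-negative envelope series.
#' @param fs sampling rate, Hz.
#' @param windows stride windows data.frame (`start`, `end`, s).
#' @param baseline_mean_stride_duration mean stride duration of the control
#'   condition, s.
#' @param amp_fraction amplitude threshold as a fraction of the envelope
#'   peak (default 0.10).
#' @param timing_fraction minimum burst (and maximum mergeable dip)
#'   duration as a fraction of the baseline mean stride duration (default
#'   0.05).
#' @return data.frame of bursts: stride, burst index within stride,
#'   onset_pct, offset_pct, duration_pct; zero rows when nothing is active.
#' @export
detect_activation <- function(envelope10, fs, windows,
                              baseline_mean_stride_duration,
                              amp_fraction = 0.10, timing_fraction = 0.05) {
  stopifnot(all(envelope10 >= 0))
  empty <- data.frame(stride = integer(), burst = integer(),
                      onset_pct = numeric(), offset_pct = numeric(),
                      duration_pct = numeric())
  peak <- max(envelope10)
  if (peak <= 0) return(empty)
  thr <- amp_fraction * peak
  min_len <- timing_fraction * baseline_mean_stride_duration      # s
  active <- envelope10 > thr
  if (!any(active)) return(empty)
  runs <- mask_runs(active)
  # merge bursts separated by dips shorter than the timing threshold
  if (nrow(runs) > 1L) {
    merged <- runs[1L, ]
    for (r in 2:nrow(runs)) {
      gap <- (runs$start[r] - merged$end[nrow(merged)] - 1L) / fs
      if (gap < min_len) {
        merged$end[nrow(merged)] <- runs$end[r]
      } else {
        merged <- rbind(merged, runs[r, ])
      }
    }
    runs <- merged
  }
  dur_s <- (runs$end - runs$start + 1L) / fs
  runs <- runs[dur_s >= min_len, , drop = FALSE]
  if (!nrow(runs)) return(empty)

  t <- (seq_along(envelope10) - 1L) / fs
  cross <- function(i0, i1) {
    # linear interpolation of the threshold crossing between samples i0, i1
    if (i1 < 1L || i1 > length(envelope10) || envelope10[i1] == envelope10[i0]) {
      return(t[i0])
    }
    t[i0] + (thr - envelope10[i0]) / (envelope10[i1] - envelope10[i0]) / fs
  }
  res <- empty
  for (r in seq_len(nrow(runs))) {
    on_t <- if (runs$start[r] > 1L) cross(runs$start[r] - 1L, runs$start[r]) else t[1L]
    off_t <- if (runs$end[r] < length(envelope10)) cross(runs$end[r], runs$end[r] + 1L)
             else t[length(t)]
    # locate the containing stride (by burst midpoint)
    mid <- (on_t + off_t) / 2
    k <- which(windows$start <= mid & mid < windows$end)
    if (!length(k)) next
    k <- k[1L]
    w <- windows$end[k] - windows$start[k]
    res <- rbind(res, data.frame(
      stride = k, burst = sum(res$stride == k) + 1L,
      onset_pct = 100 * (on_t - windows$start[k]) / w,
      offset_pct = 100 * (off_t - windows$start[k]) / w,
      duration_pct = 100 * (off_t - on_t) / w))
  }
  res
}

#' Full per-channel sEMG stride analysis
#'
#' Convenience wrapper: condition the channel, segment it on the
#' contralateral hindlimb, compute stride ARV, and detect activation
#' events.
#'
#' @param trial an `emgait_trial`.
#' @param channel channel name (`muscle_side`).
#' @param events a `gait_events`.
#' @param baseline_mean_stride_duration control-condition mean stride
#'   duration, s.
#' @param amp_fraction,timing_fraction see [detect_activation()].
#' @return list: `proc`, `windows`, `arv`, `activation`.
#' @export
analyze_emg_channel <- function(trial, channel, events,
                                baseline_mean_stride_duration,
                                amp_fraction = 0.10, timing_fraction = 0.05) {
  ch <- trial$emg[[channel]]
  if (is.null(ch)) err(paste0("no EMG channel ", channel), "emgait_schema_error")
  seg_limb <- if (ch$side == "left") "HR" else "HL"
  win <- stride_windows(events, seg_limb)
  proc <- preprocess_emg(ch)
  arv <- stride_arv(proc, win)
  act <- detect_activation(proc$envelope10, proc$fs, win,
                           baseline_mean_stride_duration,
                           amp_fraction, timing_fraction)
  list(proc = proc, windows = win, arv = arv, activation = act)
}
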
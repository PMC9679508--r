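#' Zero-phase Butterworth filtering
#'
#' Applies a 4th-order Butterworth filter forward and backward (zero phase)
#' with odd-reflection padding at both ends so that edge transients do not
#' leak into the analysed span. Zero-phase filtering is used throughout the
#' package because activation-timing comparisons across signals require zero
#' group delay.
#'
#' @param x numeric vector (regularly sampled).
#' @param fc cutoff frequency in Hz (length 1 for low/high, length 2 for pass).
#' @param fs sampling rate in Hz.
#' @param type one of "low", "high", "pass".
#' @param order filter order of the underlying design (default 4).
#' @return filtered numeric vector, same length as `x`.
#' @keywords internal
zerophase_butter <- function(x, fc, fs, type = c("low", "high", "pass"),
                             order = 4L) {
  type <- match.arg(type)
  if (any(fc <= 0) || any(fc >= fs / 2)) {
    stop("emgait configuration error: cutoff must lie in (0, Nyquist); got ",
         paste(fc, collapse = "-"), " Hz at fs = ", fs, " Hz")
  }
  n <- length(x)
  # settling length: ~3 time constants of the slowest pole
  pad <- min(n - 1L, as.integer(ceiling(3 * fs / min(fc))))
  if (n < 3L * pad / 3) stop("emgait filtering error: signal too short for filter settling")
  if (n <= 12L) stop("emgait filtering error: signal shorter than 3x filter settling length")
  bf <- signal::butter(order, fc / (fs / 2), type = type)
  # odd (point-symmetric) reflection padding, scipy-style
  left <- 2 * x[1L] - x[(pad + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xp <- c(left, x, right)
  y <- signal::filter(bf, xp)
  y <- rev(signal::filter(bf, rev(y)))
  y[(pad + 1L):(pad + n)]
}

#' Low-pass filter marker trajectories
#'
#' Smooths each coordinate of a marker trajectory with a zero-phase 4th-order
#' Butterworth low-pass at 10 Hz, the standard cut-off that retains the great
#' majority of trot kinematic signal content while suppressing marker jitter.
#' Gaps must have been interpolated or left masked beforehand; masked samples
#' stay masked and are excluded from filtering (each present run is filtered
#' separately when long enough).
#'
#' @param traj a `marker_trajectory` (see [marker_trajectory()]).
#' @param fc cutoff frequency, Hz.
#' @param fs sampling rate, Hz; defaults to the trajectory's own rate.
#' @return a `marker_trajectory` with filtered coordinates.
#' @export
lowpass_kinematics <- function(traj, fc = 10, fs = attr(traj, "fs")) {
  stopifnot(inherits(traj, "marker_trajectory"))
  xyz <- traj$xyz
  present <- !traj$missing
  runs <- mask_runs(present)
  for (r in seq_len(nrow(runs))) {
    idx <- runs$start[r]:runs$end[r]
    if (length(idx) <= 12L) next   # too short to filter; leave as-is
    for (j in 1:3) xyz[idx, j] <- zerophase_butter(xyz[idx, j], fc, fs, "low")
  }
  out <- traj
  out$xyz <- xyz
  out
}

#' Stride-frequency-adaptive high-pass for upper-body displacement
#'
#' Removes drift and DC from a vertical displacement series with a zero-phase
#' 4th-order Butterworth high-pass whose cut-off adapts to the measured stride
#' frequency (cut-off = `ratio` x stride frequency, default 0.5). The factor
#' 0.5 passes the stride fundamental and its asymmetry-bearing two-per-stride
#' harmonic essentially untouched while suppressing inter-stride drift.
#'
#' @param z vertical displacement series (mm).
#' @param stride_frequency strides per second (Hz), > 0.
#' @param fs sampling rate, Hz.
#' @param ratio cut-off as a fraction of stride frequency.
#' @return filtered series, mm.
#' @export
adaptive_highpass <- function(z, stride_frequency, fs = 200, ratio = 0.5) {
  if (!is.numeric(stride_frequency) || stride_frequency <= 0) {
    stop("emgait configuration error: stride_frequency must be > 0")
  }
  fc <- ratio * stride_frequency
  if (fc >= fs / 2) stop("emgait configuration error: adaptive cutoff at or above Nyquist")
  # The cutoff sits far below the signal band, so reflective padding would
  # leave transients that decay over seconds. Gait displacement is
  # quasi-periodic at the stride frequency: periodic padding (one stride
  # period wrapped) continues the signal almost exactly and keeps the
  # filter edges clean.
  n <- length(z)
  P <- max(2L, min(n, as.integer(round(fs / stride_frequency))))
  reps <- ceiling(3 * fs / fc / P)
  pad <- min(10L, reps) * P
  left <- z[((-(pad:1)) %% P) + 1L]
  right <- z[n - P + ((seq_len(pad) - 1L) %% P) + 1L]
  y <- zerophase_butter(c(left, z, right), fc, fs, "high")
  y[(pad + 1L):(pad + n)]
}

# contiguous runs of TRUE in a logical vector -> data.frame(start, end)
mask_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}
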
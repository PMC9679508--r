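# Core domain objects: trial metadata, marker trajectories, sEMG channels,
# and the plain-text trial bundle (meta.json + markers.csv + emg.csv).

#' Marker and muscle registries
#'
#' Fixed registries of anatomical marker labels and sEMG muscle labels.
#' Markers follow the usual upper-body + appendicular set for over-ground
#' trot analysis: poll, withers (T6), tubera sacrale, left/right tubera
#' coxae, four hooves, and per-side forelimb (spina scapulae, shoulder,
#' elbow, carpus, metacarpophalangeal joint) and hindlimb (greater
#' trochanter, stifle, tarsus, metatarsophalangeal joint) chains.
#'
#' @return character vector of valid labels.
#' @export
marker_registry <- function() {
  sides <- c("L", "R")
  c("poll", "withers_T6", "tubera_sacrale",
    paste0("tuber_coxae_", sides),
    paste0("hoof_", c("FL", "FR", "HL", "HR")),
    paste0("spina_scapulae_", sides),
    paste0("shoulder_", sides),
    paste0("elbow_", sides),
    paste0("carpus_", sides),
    paste0("mcp_", sides),
    paste0("greater_trochanter_", sides),
    paste0("stifle_", sides),
    paste0("tarsus_", sides),
    paste0("mtp_", sides))
}

#' @rdname marker_registry
#' @export
muscle_registry <- function() {
  c("triceps", "latissimus", "gluteal", "biceps", "semitendinosus")
}

conditions_registry <- function() c("baseline1", "baseline2", "iFL", "iHL")

err <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "emgait_error")))
}

#' Trial metadata
#'
#' @param subject_id subject identifier.
#' @param condition one of baseline1, baseline2, iFL, iHL.
#' @param induction_side "left", "right", or "none" (baselines must be "none").
#' @param fs_kin kinematic sampling rate, Hz.
#' @param fs_emg sEMG sampling rate, Hz (integer multiple of `fs_kin`).
#' @param trial_id trial identifier.
#' @return a `trial_meta` list.
#' @export
trial_meta <- function(subject_id, condition, induction_side = "none",
                       fs_kin = 200, fs_emg = 2000, trial_id = "trial1") {
  condition <- match.arg(condition, conditions_registry())
  induction_side <- match.arg(induction_side, c("none", "left", "right"))
  if (grepl("^baseline", condition) && induction_side != "none") {
    err("baseline condition requires induction_side = 'none'", "emgait_schema_error")
  }
  if (fs_emg %% fs_kin != 0) {
    err("fs_emg must be an integer multiple of fs_kin", "emgait_schema_error")
  }
  structure(list(subject_id = subject_id, condition = condition,
                 induction_side = induction_side, fs_kin = fs_kin,
                 fs_emg = fs_emg, trial_id = trial_id),
            class = "trial_meta")
}

#' Marker trajectory
#'
#' @param name label from [marker_registry()].
#' @param xyz n x 3 matrix of coordinates in mm (x cranial +, y left lateral,
#'   z up +); rows with any NA are treated as missing.
#' @param fs sampling rate, Hz.
#' @param missing optional logical mask (TRUE = missing sample).
#' @return a `marker_trajectory`.
#' @export
marker_trajectory <- function(name, xyz, fs = 200, missing = NULL) {
  if (!name %in% marker_registry()) {
    err(paste0("unknown marker label: ", name), "emgait_schema_error")
  }
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3)
  if (is.null(missing)) missing <- apply(xyz, 1L, function(r) any(is.na(r)))
  if (any(!missing & !is.finite(xyz))) {
    err("non-finite coordinates at samples marked present", "emgait_schema_error")
  }
  structure(list(name = name, xyz = xyz, missing = as.logical(missing)),
            fs = fs, class = "marker_trajectory")
}

#' sEMG channel
#'
#' @param muscle label from [muscle_registry()].
#' @param side "left" or "right".
#' @param samples raw voltage series, mV.
#' @param fs sampling rate, Hz.
#' @return an `emg_channel`.
#' @export
emg_channel <- function(muscle, side, samples, fs = 2000) {
  muscle <- match.arg(muscle, muscle_registry())
  side <- match.arg(side, c("left", "right"))
  if (!all(is.finite(samples))) err("EMG samples must be finite", "emgait_schema_error")
  structure(list(muscle = muscle, side = side, samples = as.numeric(samples)),
            fs = fs, class = "emg_channel")
}

#' Assemble a synchronized trial
#'
#' Kinematic and sEMG records must share t = 0 and cover the same span
#' (tolerance: one kinematic frame).
#'
#' @param meta a [trial_meta()].
#' @param markers named list of [marker_trajectory()] objects.
#' @param emg named list of [emg_channel()] objects (names `muscle_side`).
#' @return an `emgait_trial`.
#' @export
new_trial <- function(meta, markers, emg) {
  stopifnot(inherits(meta, "trial_meta"))
  nk <- unique(vapply(markers, function(m) nrow(m$xyz), integer(1)))
  if (length(nk) != 1L) err("marker trajectories differ in length", "emgait_schema_error")
  ne <- unique(vapply(emg, function(e) length(e$samples), integer(1)))
  if (length(ne) != 1L) err("EMG channels differ in length", "emgait_schema_error")
  dur_kin <- nk / meta$fs_kin
  dur_emg <- ne / meta$fs_emg
  if (abs(dur_kin - dur_emg) > 1 / meta$fs_kin + 1e-9) {
    err(sprintf("kinematic (%.4f s) and EMG (%.4f s) spans disagree",
                dur_kin, dur_emg), "emgait_sync_error")
  }
  structure(list(meta = meta, markers = markers, emg = emg,
                 duration = dur_kin),
            class = "emgait_trial")
}

#' @exportS3Method base::print
print.emgait_trial <- function(x, ...) {
  cat("<emgait_trial> subject", x$meta$subject_id, "| trial", x$meta$trial_id,
      "| condition", x$meta$condition, "\n")
  cat(sprintf("  %.2f s, %d markers @ %g Hz, %d EMG channels @ %g Hz\n",
              x$duration, length(x$markers), x$meta$fs_kin,
              length(x$emg), x$meta$fs_emg))
  invisible(x)
}

fmt_num <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))

#' Write a trial bundle
#'
#' Serializes a trial as plain text: `meta.json`, `markers.csv` (header
#' `time,<marker>_x,<marker>_y,<marker>_z,...`, empty cell = missing sample)
#' and `emg.csv` (header `time,<muscle>_<side>,...`, mV). Numeric fields are
#' written with 17 significant digits so a write/load roundtrip is exact and
#' repeated writes are byte-identical.
#'
#' @param trial an `emgait_trial`.
#' @param bundle_path directory to create/fill.
#' @return `bundle_path`, invisibly.
#' @export
write_trial <- function(trial, bundle_path) {
  stopifnot(inherits(trial, "emgait_trial"))
  ok <- dir.exists(bundle_path) || dir.create(bundle_path, recursive = TRUE, showWarnings = FALSE)
  if (!ok) err(paste0("cannot create bundle directory: ", bundle_path), "emgait_io_error")
  meta <- trial$meta
  jsonlite::write_json(unclass(meta), file.path(bundle_path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)

  nk <- nrow(trial$markers[[1L]]$xyz)
  tkin <- (seq_len(nk) - 1L) / meta$fs_kin
  cols <- list(time = fmt_num(tkin))
  for (m in trial$markers) {
    xyz <- m$xyz
    xyz[m$missing, ] <- NA_real_
    for (j in 1:3) {
      cols[[paste0(m$name, "_", c("x", "y", "z")[j])]] <- fmt_num(xyz[, j])
    }
  }
  write_text_csv(cols, file.path(bundle_path, "markers.csv"))

  ne <- length(trial$emg[[1L]]$samples)
  temg <- (seq_len(ne) - 1L) / meta$fs_emg
  ecols <- list(time = fmt_num(temg))
  for (e in trial$emg) {
    ecols[[paste0(e$muscle, "_", e$side)]] <- fmt_num(e$samples)
  }
  write_text_csv(ecols, file.path(bundle_path, "emg.csv"))
  invisible(bundle_path)
}

write_text_csv <- function(cols, path) {
  header <- paste(names(cols), collapse = ",")
  body <- do.call(paste, c(cols, sep = ","))
  con <- file(path, "wb")   # binary mode: identical bytes on any platform
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
}

#' Load a trial bundle
#'
#' Inverse of [write_trial()]; validates the synchronization and schema
#' invariants and carries missing marker samples as a mask rather than
#' filling them.
#'
#' @param bundle_path directory holding `meta.json`, `markers.csv`, `emg.csv`.
#' @return an `emgait_trial`.
#' @export
load_trial <- function(bundle_path) {
  for (f in c("meta.json", "markers.csv", "emg.csv")) {
    if (!file.exists(file.path(bundle_path, f))) {
      err(paste0("bundle is missing required file: ", f), "emgait_ingest_error")
    }
  }
  mj <- jsonlite::read_json(file.path(bundle_path, "meta.json"), simplifyVector = TRUE)
  meta <- trial_meta(mj$subject_id, mj$condition, mj$induction_side,
                     mj$fs_kin, mj$fs_emg, mj$trial_id)

  mk <- utils::read.csv(file.path(bundle_path, "markers.csv"), check.names = FALSE)
  mnames <- unique(sub("_[xyz]$", "", setdiff(names(mk), "time")))
  markers <- list()
  for (nm in mnames) {
    need <- paste0(nm, "_", c("x", "y", "z"))
    if (!all(need %in% names(mk))) {
      err(paste0("marker ", nm, " lacks x/y/z columns"), "emgait_ingest_error")
    }
    xyz <- as.matrix(mk[, need])
    colnames(xyz) <- c("x", "y", "z")
    markers[[nm]] <- marker_trajectory(nm, xyz, fs = meta$fs_kin)
  }

  eg <- utils::read.csv(file.path(bundle_path, "emg.csv"), check.names = FALSE)
  emg <- list()
  for (nm in setdiff(names(eg), "time")) {
    parts <- strsplit(nm, "_")[[1L]]
    if (length(parts) != 2L) err(paste0("malformed EMG column: ", nm), "emgait_ingest_error")
    emg[[nm]] <- emg_channel(parts[1L], parts[2L], eg[[nm]], fs = meta$fs_emg)
  }
  new_trial(meta, markers, emg)
}

#' Interpolate short marker gaps
#'
#' Fills missing runs of length at most `max_gap` frames by cubic-spline
#' interpolation of each coordinate (exact on polynomials up to degree 3);
#' longer runs, and runs touching the sequence boundary, remain masked so
#' that downstream stride processing can flag the strides they overlap.
#' Present samples are never altered.
#'
#' @param traj a [marker_trajectory()].
#' @param max_gap largest gap length (frames) that is filled; default 10.
#' @return a `marker_trajectory` with short gaps filled.
#' @export
interpolate_gaps <- function(traj, max_gap = 10L) {
  stopifnot(inherits(traj, "marker_trajectory"))
  miss <- traj$missing
  if (!any(miss)) return(traj)
  n <- length(miss)
  runs <- mask_runs(miss)
  xyz <- traj$xyz
  present <- which(!miss)
  if (length(present) < 4L) return(traj)  # not enough flanking data anywhere
  for (r in seq_len(nrow(runs))) {
    s <- runs$start[r]; e <- runs$end[r]
    if (e - s + 1L > max_gap) next
    if (s == 1L || e == n) next           # boundary gap: no flanking data
    idx <- s:e
    for (j in 1:3) {
      sf <- stats::splinefun(present, xyz[present, j], method = "fmm")
      xyz[idx, j] <- sf(idx)
    }
    miss[idx] <- FALSE
  }
  out <- traj
  out$xyz <- xyz
  out$missing <- miss
  out
}
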
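# End-to-end study runner: load/simulate -> events -> kinematics -> sEMG ->
# discrete and SPM statistics -> report bundle.

#' Analysis run configuration
#'
#' Houses every analysis constant in one place: the double-threshold
#' detector fractions, the ARV outlier width, significance levels, the
#' Bonferroni family size for SPM, and the induction-sufficiency reference
#' values (13 mm head, 5 mm pelvis).
#'
#' @param baseline,induced lists (one element per subject) of trial bundle
#'   paths or `emgait_trial` objects.
#' @param out_dir output directory for report artifacts.
#' @param amp_fraction amplitude threshold fraction for activation detection.
#' @param timing_fraction timing threshold fraction.
#' @param outlier_sd ARV outlier width in standard deviations.
#' @param alpha two-tailed significance level.
#' @param bonferroni_m SPM Bonferroni family size; `NULL` (default) uses the
#'   panel convention: the family is the set of variables jointly tested in
#'   the variable's limb panel (forelimb muscles together, hindlimb muscles
#'   together, per side role).
#' @param poll_threshold_mm,pelvis_threshold_mm sufficiency reference values.
#' @param ref_limb reference hindlimb for kinematic stride segmentation.
#' @param seed RNG seed recorded in the run log.
#' @param make_plots write the per-variable stride-band PDF.
#' @return a `run_config` list.
#' @export
run_config <- function(baseline, induced, out_dir,
                       amp_fraction = 0.10, timing_fraction = 0.05,
                       outlier_sd = 2, alpha = 0.05, bonferroni_m = NULL,
                       poll_threshold_mm = 13, pelvis_threshold_mm = 5,
                       ref_limb = "HR", seed = 1L, make_plots = TRUE) {
  if (alpha <= 0 || alpha >= 1) err("alpha must lie in (0,1)", "emgait_config_error")
  for (v in c(amp_fraction, timing_fraction, outlier_sd,
              poll_threshold_mm, pelvis_threshold_mm)) {
    if (v <= 0) err("all thresholds must be positive", "emgait_config_error")
  }
  if (!is.list(baseline)) baseline <- list(baseline)
  if (!is.list(induced)) induced <- list(induced)
  if (length(baseline) != length(induced)) {
    err("baseline and induced must pair up subject-for-subject", "emgait_config_error")
  }
  structure(list(baseline = baseline, induced = induced, out_dir = out_dir,
                 amp_fraction = amp_fraction, timing_fraction = timing_fraction,
                 outlier_sd = outlier_sd, alpha = alpha,
                 bonferroni_m = if (is.null(bonferroni_m)) NULL else as.integer(bonferroni_m),
                 poll_threshold_mm = poll_threshold_mm,
                 pelvis_threshold_mm = pelvis_threshold_mm,
                 ref_limb = ref_limb, seed = as.integer(seed),
                 make_plots = make_plots),
            class = "run_config")
}

resolve_trial <- function(x) {
  if (inherits(x, "emgait_trial")) x else load_trial(x)
}

#' Run a full baseline-vs-induced study
#'
#' Orchestrates the complete analysis: gait events and stride segmentation,
#' per-stride asymmetry indices (mirrored to lame side / non-lame side for
#' right-sided inductions), the sEMG chain with ARV outlier rejection, RVC
#' normalization and activation detection, the induction-sufficiency
#' verdict, mixed-model condition contrasts with FDR correction, and
#' paired SPM of the amplitude-normalized envelopes. Writes
#' `asymmetry.csv`, `emg_discrete.csv`, `emg_norm_strides.csv`,
#' `table1_like.csv`, `spm_results.csv`, `run_log.json` and (optionally)
#' `stride_bands.pdf` into the output directory.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with all result tables and the run log.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  n_sub <- length(config$baseline)
  log <- list(seed = config$seed,
              thresholds = config[c("amp_fraction", "timing_fraction",
                                    "outlier_sd", "alpha", "bonferroni_m",
                                    "poll_threshold_mm", "pelvis_threshold_mm")],
              package_version = as.character(utils::packageVersion("emgait")),
              subjects = n_sub, strides = list(), excluded = list(),
              warnings = character())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("emgait pipeline failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }

  asym_all <- NULL; arv_all <- NULL; act_all <- NULL; env_rows <- NULL
  env_fields <- list()   # env_fields[[variable]][[condition]][subject, node]
  base_durs <- c()
  subjects <- character(n_sub)
  trials <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    tb <- stage("ingest", resolve_trial(config$baseline[[s]]))
    ti <- stage("ingest", resolve_trial(config$induced[[s]]))
    subjects[s] <- tb$meta$subject_id
    trials[[s]] <- list(baseline = tb, induced = ti)
    evb <- stage("events", detect_hindlimb_impacts(tb))
    base_durs <- c(base_durs, diff(evb$impacts[[config$ref_limb]]))
  }
  baseline_mean_dur <- mean(base_durs)

  for (s in seq_len(n_sub)) {
    tb <- trials[[s]]$baseline; ti <- trials[[s]]$induced
    side <- ti$meta$induction_side
    if (side == "none") side <- "left"
    for (cond in c("baseline", "induced")) {
      tr <- if (cond == "baseline") tb else ti
      ev <- stage("events", detect_hindlimb_impacts(tr))
      ai <- stage("kinematics", asymmetry_indices(tr, ev, config$ref_limb))
      ai <- mirror_for_side(ai, side)
      ai$subject <- subjects[s]; ai$condition <- cond
      ai$trial_id <- tr$meta$trial_id
      asym_all <- rbind(asym_all, ai)
      log$strides[[paste(subjects[s], cond, sep = ".")]] <- nrow(ai)
      log$excluded[[paste(subjects[s], cond, sep = ".")]] <- ai$stride[ai$excluded]

      for (ch in names(tr$emg)) {
        res <- stage("semg", analyze_emg_channel(
          tr, ch, ev, baseline_mean_dur,
          config$amp_fraction, config$timing_fraction))
        arv <- res$arv
        arv$subject <- subjects[s]; arv$condition <- cond
        arv$side_role <- side_role(arv$side, side)
        arv_all <- rbind(arv_all, arv)
        if (nrow(res$activation)) {
          act <- res$activation
          act$subject <- subjects[s]; act$condition <- cond
          act$muscle <- res$proc$muscle; act$side <- res$proc$side
          act$side_role <- side_role(res$proc$side, side)
          act_all <- rbind(act_all, act)
        }
        # 101-node envelope strides (raw mV for now; normalized below)
        win <- res$windows
        for (k in seq_len(nrow(win))) {
          v <- time_normalize(res$proc$envelope25, res$proc$fs,
                              win$start[k], win$end[k])
          env_rows <- rbind(env_rows, data.frame(
            subject = subjects[s], condition = cond, muscle = res$proc$muscle,
            side = res$proc$side, side_role = side_role(res$proc$side, side),
            stride = k, t(as.numeric(v))))
        }
      }
    }
  }

  # --- ARV outliers and RVC normalization ----------------------------------
  arv_all <- stage("outliers", flag_arv_outliers(
    arv_all, group = c("subject", "muscle", "side", "condition"),
    n_sd = config$outlier_sd))
  arv_all$arv_norm_pct <- NA_real_
  node_cols <- paste0("X", 1:101)
  env_rows$peak <- apply(env_rows[, node_cols], 1L, max)
  env_rows$arv_outlier <- FALSE
  env_rows$peak_outlier <- FALSE
  for (s in subjects) for (m in unique(arv_all$muscle)) for (sd_ in c("left", "right")) {
    selb <- arv_all$subject == s & arv_all$muscle == m & arv_all$side == sd_ &
      arv_all$condition == "baseline"
    seli <- arv_all$subject == s & arv_all$muscle == m & arv_all$side == sd_
    nz <- stage("normalize", rvc_normalize(arv_all$arv_raw[seli],
                                           arv_all$arv_raw[selb],
                                           arv_all$outlier[selb]))
    arv_all$arv_norm_pct[seli] <- nz$pct
    # envelope RVC: extra 2-SD pass on baseline stride peak amplitudes
    esel <- env_rows$subject == s & env_rows$muscle == m & env_rows$side == sd_
    eb <- which(esel & env_rows$condition == "baseline")
    # align ARV outliers onto envelope strides via stride index
    akey <- arv_all[selb, c("stride", "outlier")]
    env_rows$arv_outlier[eb] <- akey$outlier[match(env_rows$stride[eb], akey$stride)]
    pk <- env_rows$peak[eb]
    keep0 <- !env_rows$arv_outlier[eb]
    if (sum(keep0) >= 3L) {
      mu <- mean(pk[keep0]); sdv <- stats::sd(pk[keep0])
      env_rows$peak_outlier[eb] <- keep0 & (pk < mu - config$outlier_sd * sdv |
                                              pk > mu + config$outlier_sd * sdv)
    }
    ervc <- max(pk[keep0 & !env_rows$peak_outlier[eb]])
    env_rows[esel, node_cols] <- 100 * env_rows[esel, node_cols] / ervc
  }

  # --- subject-level median envelope fields for SPM ------------------------
  spm_rows <- NULL
  fore_muscles <- c("triceps", "latissimus")
  for (m in unique(env_rows$muscle)) for (role in c("LS", "NLS")) {
    key <- paste(m, role, sep = "_")
    # Bonferroni family = variables jointly tested in this limb panel
    m_bonf <- if (!is.null(config$bonferroni_m)) config$bonferroni_m else {
      panel <- if (m %in% fore_muscles) fore_muscles
               else setdiff(unique(env_rows$muscle), fore_muscles)
      length(panel)
    }
    fields <- list(baseline = NULL, induced = NULL)
    for (cond in c("baseline", "induced")) {
      M <- NULL
      for (s in subjects) {
        sel <- env_rows$muscle == m & env_rows$side_role == role &
          env_rows$condition == cond & env_rows$subject == s &
          !env_rows$arv_outlier & !env_rows$peak_outlier
        if (!any(sel)) next
        M <- rbind(M, median_stride(as.matrix(env_rows[sel, node_cols])))
      }
      fields[[cond]] <- M
    }
    A <- fields$induced; B <- fields$baseline
    if (is.null(A) || is.null(B)) next
    if (nrow(A) >= 3L && nrow(A) == nrow(B)) {
      sp <- spm_paired(A, B, config$alpha, m_bonf, key)
    } else {
      # single/few subjects: pair stride-level fields by stride index
      selA <- env_rows$muscle == m & env_rows$side_role == role &
        env_rows$condition == "induced" & !env_rows$arv_outlier & !env_rows$peak_outlier
      selB <- env_rows$muscle == m & env_rows$side_role == role &
        env_rows$condition == "baseline" & !env_rows$arv_outlier & !env_rows$peak_outlier
      nA <- sum(selA); nB <- sum(selB)
      npair <- min(nA, nB)
      if (npair < 3L) next
      sp <- spm_paired(as.matrix(env_rows[which(selA)[1:npair], node_cols]),
                       as.matrix(env_rows[which(selB)[1:npair], node_cols]),
                       config$alpha, m_bonf, key)
    }
    env_fields[[key]] <- sp
    cl <- sp$clusters
    if (nrow(cl)) {
      spm_rows <- rbind(spm_rows, data.frame(
        variable = m, side_role = role, df = sp$df, fwhm = sp$fwhm,
        threshold = sp$threshold, cluster_start_pct = cl$start_pct,
        cluster_end_pct = cl$end_pct, p_value = cl$p))
    } else {
      spm_rows <- rbind(spm_rows, data.frame(
        variable = m, side_role = role, df = sp$df, fwhm = sp$fwhm,
        threshold = sp$threshold, cluster_start_pct = NA_real_,
        cluster_end_pct = NA_real_, p_value = NA_real_))
    }
  }

  # --- discrete contrasts and sufficiency ----------------------------------
  disc <- NULL
  keep <- !asym_all$excluded
  for (v in c("duration", signed_asymmetry_vars())) {
    disc <- rbind(disc, data.frame(
      subject = asym_all$subject[keep], condition = asym_all$condition[keep],
      variable = ifelse(v == "duration", "stride_duration", v),
      value = asym_all[[v]][keep], speed = asym_all$speed[keep]))
  }
  aok <- !arv_all$outlier
  disc <- rbind(disc, data.frame(
    subject = arv_all$subject[aok], condition = arv_all$condition[aok],
    variable = paste0("arv_", arv_all$muscle[aok], "_", arv_all$side_role[aok]),
    value = arv_all$arv_norm_pct[aok],
    speed = NA_real_))
  table1 <- stage("contrasts", contrast_conditions(disc, speed_correction = FALSE))

  suff <- stage("sufficiency", induction_sufficiency(
    asym_all[asym_all$condition == "baseline" & keep, ],
    asym_all[asym_all$condition == "induced" & keep, ],
    config$poll_threshold_mm, config$pelvis_threshold_mm))
  log$induction_sufficiency <- suff[c("forelimb", "hindlimb")]

  # --- artifacts -----------------------------------------------------------
  wcsv <- function(df, name) {
    num <- vapply(df, is.numeric, logical(1))
    for (j in which(num)) df[[j]] <- fmt_num(df[[j]])
    utils::write.csv(df, file.path(config$out_dir, name), row.names = FALSE,
                     quote = FALSE)
  }
  wcsv(asym_all, "asymmetry.csv")
  emg_disc <- merge(arv_all,
                    act_all[, c("subject", "condition", "muscle", "side",
                                "stride", "burst", "onset_pct", "offset_pct",
                                "duration_pct")],
                    by = c("subject", "condition", "muscle", "side", "stride"),
                    all.x = TRUE, sort = TRUE)
  emg_disc <- emg_disc[order(emg_disc$subject, emg_disc$condition,
                             emg_disc$muscle, emg_disc$side, emg_disc$stride,
                             emg_disc$burst), ]
  wcsv(emg_disc, "emg_discrete.csv")
  wcsv(env_rows, "emg_norm_strides.csv")
  wcsv(table1, "table1_like.csv")
  if (!is.null(spm_rows)) wcsv(spm_rows, "spm_results.csv")
  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  if (config$make_plots && length(env_fields)) {
    grDevices::pdf(file.path(config$out_dir, "stride_bands.pdf"), width = 7, height = 5)
    on.exit(grDevices::dev.off(), add = TRUE)
    for (key in names(env_fields)) {
      plot_stride_band(env_rows, key, env_fields[[key]], node_cols)
    }
  }
  invisible(list(asymmetry = asym_all, emg_discrete = emg_disc,
                 emg_norm_strides = env_rows, table1 = table1,
                 spm = env_fields, spm_results = spm_rows,
                 sufficiency = suff, log = log))
}

# median +/- SD stride band per condition with significant clusters shaded
plot_stride_band <- function(env_rows, key, spm, node_cols) {
  parts <- strsplit(key, "_")[[1L]]
  m <- parts[1L]; role <- parts[2L]
  nodes <- 0:100
  sel <- env_rows$muscle == m & env_rows$side_role == role &
    !env_rows$arv_outlier & !env_rows$peak_outlier
  if (!any(sel)) return(invisible())
  cols <- c(baseline = "blue", induced = "red")
  graphics::plot(NULL, xlim = c(0, 100),
                 ylim = range(env_rows[sel, node_cols]),
                 xlab = "% stride", ylab = "envelope (% RVC)",
                 main = paste0(m, " (", role, ")"))
  if (nrow(spm$clusters)) {
    for (i in seq_len(nrow(spm$clusters))) {
      graphics::rect(spm$clusters$start_pct[i], graphics::par("usr")[3L],
                     spm$clusters$end_pct[i], graphics::par("usr")[4L],
                     col = grDevices::adjustcolor("gray", 0.5), border = NA)
    }
  }
  for (cond in c("baseline", "induced")) {
    M <- as.matrix(env_rows[sel & env_rows$condition == cond, node_cols])
    if (!nrow(M)) next
    med <- apply(M, 2L, stats::median)
    sdv <- apply(M, 2L, stats::sd)
    graphics::polygon(c(nodes, rev(nodes)), c(med + sdv, rev(med - sdv)),
                      col = grDevices::adjustcolor(cols[cond], 0.2), border = NA)
    graphics::lines(nodes, med, col = cols[cond], lwd = 2)
  }
  invisible()
}
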
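# Mirroring of right-sided inductions, mixed-model condition contrasts,
# FDR adjustment, and the induction-sufficiency classifier.

signed_asymmetry_vars <- function() {
  c("min_diff_poll", "max_diff_poll", "min_diff_withers", "max_diff_withers",
    "min_diff_pelvis", "max_diff_pelvis", "hip_hike")
}

#' Mirror indices for right-sided inductions
#'
#' Signed motion asymmetry indices from right-sided inductions are
#' multiplied by -1 so that all subjects can be pooled as if the lame side
#' were the left, and left/right labels are mapped to lame side (LS) /
#' non-lame side (NLS). Left-sided inductions keep their values and are
#' only relabeled. Mirroring twice restores the input.
#'
#' @param values numeric vector of a signed asymmetry variable, or a
#'   data.frame containing the standard asymmetry columns.
#' @param induction_side "left" or "right".
#' @return mirrored values (same shape as the input).
#' @export
mirror_for_side <- function(values, induction_side) {
  induction_side <- match.arg(induction_side, c("left", "right"))
  flip <- if (induction_side == "right") -1 else 1
  if (is.data.frame(values)) {
    for (v in intersect(signed_asymmetry_vars(), names(values))) {
      values[[v]] <- flip * values[[v]]
    }
    values
  } else {
    flip * values
  }
}

#' Map a muscle/joint side label to its side role
#'
#' @param side "left" or "right" (the anatomical side of the variable).
#' @param induction_side side of lameness induction.
#' @return "LS" (lame side) or "NLS".
#' @export
side_role <- function(side, induction_side) {
  ifelse(side == induction_side, "LS", "NLS")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1.
#'
#' @param p numeric p-values in \[0, 1\].
#' @return adjusted p-values.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) err("p-values must lie in [0,1]",
                                            "emgait_config_error")
  stats::p.adjust(p, method = "BH")
}

#' Mixed-model condition contrasts for discrete stride variables
#'
#' For each variable in a stride-level table, fits a linear mixed model
#' with lameness condition as fixed effect and subject as random intercept
#' (optionally a per-subject random slope on stride speed to correct for
#' speed differences between conditions), then extracts estimated marginal
#' means, the baseline-vs-induced difference, percentage difference and
#' contrast p-value, with FDR adjustment across the variable family.
#' Signed asymmetry variables report `NA` percentage difference (a signed
#' index has no meaningful baseline denominator). Non-convergence falls
#' back to a paired t contrast on subject means, with a warning recorded.
#'
#' @param table data.frame: `subject`, `condition` (two levels, baseline
#'   first), `variable`, `value`, `speed`.
#' @param speed_correction add a per-subject random slope on speed.
#' @return data.frame, one row per variable: EM means and SEs, difference,
#'   percentage difference, raw and FDR-adjusted p, convergence note.
#' @export
contrast_conditions <- function(table, speed_correction = FALSE) {
  stopifnot(all(c("subject", "condition", "variable", "value") %in% names(table)))
  conds <- unique(as.character(table$condition))
  if (length(conds) != 2L) err("need exactly two conditions", "emgait_config_error")
  baseline <- conds[grepl("^baseline", conds)][1L]
  if (is.na(baseline)) baseline <- conds[1L]
  induced <- setdiff(conds, baseline)
  table$condition <- factor(table$condition, levels = c(baseline, induced))
  single_subject <- length(unique(table$subject)) < 2L
  out <- NULL
  for (v in unique(table$variable)) {
    d <- table[table$variable == v & is.finite(table$value), ]
    row <- tryCatch({
      if (single_subject) stop("single subject: no random effect identifiable")
      # speed correction: common (fixed) speed effect plus a per-subject
      # random slope; EM means are then evaluated at the mean speed
      form <- if (speed_correction && "speed" %in% names(d) &&
                  any(is.finite(d$speed))) {
        value ~ condition + speed + (1 | subject) + (0 + speed | subject)
      } else {
        value ~ condition + (1 | subject)
      }
      fit <- lmerTest::lmer(form, data = d,
                            control = lme4::lmerControl(check.conv.singular = "ignore"))
      em <- emmeans::emmeans(fit, "condition", lmer.df = "satterthwaite")
      es <- as.data.frame(em)
      ct <- as.data.frame(emmeans::contrast(em, method = "revpairwise"))
      data.frame(variable = v,
                 em_baseline = es$emmean[1L], se_baseline = es$SE[1L],
                 em_induced = es$emmean[2L], se_induced = es$SE[2L],
                 difference = ct$estimate[1L], se_difference = ct$SE[1L],
                 p_raw = ct$p.value[1L],
                 note = "lmm")
    }, error = function(e) {
      # fallback: paired contrast of subject means
      mb <- tapply(d$value[d$condition == baseline], d$subject[d$condition == baseline], mean)
      mi <- tapply(d$value[d$condition == induced], d$subject[d$condition == induced], mean)
      common <- intersect(names(mb), names(mi))
      p <- if (length(common) >= 2L) stats::t.test(mi[common], mb[common], paired = TRUE)$p.value
           else if (length(common) == 1L) {
             stats::t.test(d$value[d$condition == induced],
                           d$value[d$condition == baseline])$p.value
           } else NA_real_
      data.frame(variable = v,
                 em_baseline = mean(mb[if (length(common)) common else names(mb)]),
                 se_baseline = NA_real_,
                 em_induced = mean(mi[if (length(common)) common else names(mi)]),
                 se_induced = NA_real_,
                 difference = mean(mi[if (length(common)) common else names(mi)]) -
                   mean(mb[if (length(common)) common else names(mb)]),
                 se_difference = NA_real_,
                 p_raw = p, note = paste("fallback:", conditionMessage(e)))
    })
    out <- rbind(out, row)
  }
  out$pct_difference <- ifelse(out$variable %in% signed_asymmetry_vars() |
                                 abs(out$em_baseline) < 1e-12,
                               NA_real_,
                               100 * abs(out$difference) / abs(out$em_baseline))
  out$p_fdr <- fdr_adjust(out$p_raw)
  rownames(out) <- NULL
  out
}

#' Induction-sufficiency classification
#'
#' Classifies whether an induced lameness produced enough movement
#' asymmetry to count as a successful induction, against the standard
#' reference values: forelimb induction is sufficient when the
#' baseline-to-induced change in head asymmetry (MinDiff or MaxDiff of the
#' poll) strictly exceeds 13 mm in magnitude; hindlimb induction when the
#' pelvic change (MinDiff and/or MaxDiff of the pelvis) strictly exceeds
#' 5 mm. In both cases the induced-condition standard deviation of the
#' qualifying index must be smaller than the magnitude of its mean.
#'
#' @param baseline,induced per-stride asymmetry tables (as from
#'   [asymmetry_indices()], excluded strides removed by the caller or
#'   flagged).
#' @param poll_threshold_mm,pelvis_threshold_mm reference values, mm.
#' @return list with verdicts `forelimb` and `hindlimb`
#'   ("sufficient" / "insufficient" / "indeterminate") and the per-index
#'   deltas.
#' @export
induction_sufficiency <- function(baseline, induced,
                                  poll_threshold_mm = 13,
                                  pelvis_threshold_mm = 5) {
  idx <- list(forelimb = c("min_diff_poll", "max_diff_poll"),
              hindlimb = c("min_diff_pelvis", "max_diff_pelvis"))
  thr <- c(forelimb = poll_threshold_mm, hindlimb = pelvis_threshold_mm)
  deltas <- list()
  verdict <- list()
  for (mech in names(idx)) {
    vs <- idx[[mech]]
    if (!all(vs %in% names(baseline)) || !all(vs %in% names(induced))) {
      verdict[[mech]] <- "indeterminate"
      next
    }
    ok <- FALSE; any_val <- FALSE
    for (v in vs) {
      b <- baseline[[v]]; i <- induced[[v]]
      if ("excluded" %in% names(baseline)) b <- b[!baseline$excluded]
      if ("excluded" %in% names(induced)) i <- i[!induced$excluded]
      b <- b[is.finite(b)]; i <- i[is.finite(i)]
      if (!length(b) || !length(i)) next
      any_val <- TRUE
      delta <- mean(i) - mean(b)
      deltas[[paste0(mech, ".", v)]] <- delta
      if (abs(delta) > thr[[mech]] && stats::sd(i) < abs(mean(i))) ok <- TRUE
    }
    verdict[[mech]] <- if (!any_val) "indeterminate"
                       else if (ok) "sufficient" else "insufficient"
  }
  list(forelimb = verdict$forelimb, hindlimb = verdict$hindlimb,
       deltas = deltas)
}
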
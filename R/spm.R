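# One-dimensional statistical parametric mapping: paired t-fields over 101
# stride nodes, random-field-theory (RFT) family-wise thresholds,
# suprathreshold cluster reporting, and a sign-flip permutation oracle.

#' Node-wise paired t statistic field
#'
#' Computes the paired t statistic at each of the 101 stride nodes from two
#' matched sets of subject-level fields (typically median strides per
#' subject and condition). Residuals are the subject-centered differences,
#' used downstream for smoothness estimation.
#'
#' @param A,B numeric matrices, subjects x nodes, same dimensions and
#'   subject order.
#' @return list: `t` (length-Q field), `df` (n - 1), `residuals`
#'   (subjects x nodes centered differences).
#' @export
paired_t_field <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) err("paired field sets must match in dimension",
                                  "emgait_pairing_error")
  n <- nrow(A)
  if (n < 3L) err("paired t field needs at least 3 subjects", "emgait_pairing_error")
  D <- A - B
  mu <- colMeans(D)
  sdv <- apply(D, 2L, stats::sd)
  if (any(sdv == 0 & mu != 0)) {
    err("zero variance at a node with nonzero mean difference",
        "emgait_degenerate_error")
  }
  tt <- ifelse(sdv == 0, 0, mu / (sdv / sqrt(n)))
  list(t = tt, df = n - 1L, residuals = sweep(D, 2L, mu))
}

#' Estimate field smoothness (FWHM)
#'
#' Kiebel-style estimator: the full width at half maximum of the effective
#' Gaussian smoothing kernel is obtained from the variance of the
#' node-to-node gradients of the normalized residual fields,
#' FWHM = sqrt(4 log 2) / sqrt(mean squared normalized gradient), in node
#' units. Constant residuals return `Inf`, a sentinel meaning "use the
#' pointwise t threshold".
#'
#' @param residuals matrix, fields x nodes.
#' @return FWHM in nodes (possibly `Inf`).
#' @export
estimate_fwhm <- function(residuals) {
  R <- as.matrix(residuals)
  if (nrow(R) < 2L) err("need at least 2 residual fields", "emgait_config_error")
  ssq <- colSums(R^2)
  if (all(ssq < 1e-24)) return(Inf)
  Q <- ncol(R)
  # central-difference gradient along nodes (unit node spacing)
  G <- t(apply(R, 1L, function(r) {
    c(r[2L] - r[1L], (r[3:Q] - r[1:(Q - 2L)]) / 2, r[Q] - r[Q - 1L])
  }))
  gsq <- colSums(G^2)
  v <- gsq / pmax(ssq, 1e-24)
  rpn <- sqrt(v / (4 * log(2)))           # resels per node
  m <- mean(rpn)
  if (m <= 0) return(Inf)
  1 / m
}

# 1D Euler characteristic density of a t field (unit-FWHM resel count)
rho1_t <- function(u, df) {
  sqrt(4 * log(2)) / (2 * pi) * (1 + u^2 / df)^(-(df - 1) / 2)
}

# expected Euler characteristic of the excursion set above u
expected_ec <- function(u, df, resels) {
  stats::pt(u, df, lower.tail = FALSE) + resels * rho1_t(u, df)
}

#' Random-field-theory critical t threshold
#'
#' Smallest t* at which the expected Euler characteristic of the excursion
#' set of a smooth 1D t field (resels = (n_nodes - 1) / FWHM) drops to the
#' per-tail error level alpha / (2 m) (two-tailed, Bonferroni-corrected
#' over m variables in the test family). Infinite FWHM collapses to the
#' ordinary Student t critical value.
#'
#' @param df degrees of freedom.
#' @param fwhm smoothness in nodes (`Inf` = pointwise threshold).
#' @param n_nodes field length (default 101).
#' @param alpha family-wise level (default 0.05).
#' @param two_tailed logical (default TRUE).
#' @param m_comparisons Bonferroni family size (default 1).
#' @return critical t value.
#' @export
rft_threshold <- function(df, fwhm, n_nodes = 101L, alpha = 0.05,
                          two_tailed = TRUE, m_comparisons = 1L) {
  if (alpha <= 0 || alpha >= 1) err("alpha must lie in (0,1)", "emgait_config_error")
  a_eff <- alpha / m_comparisons / (if (two_tailed) 2 else 1)
  if (!is.finite(fwhm)) return(stats::qt(1 - a_eff, df))
  if (fwhm <= 0) err("fwhm must be positive", "emgait_config_error")
  resels <- (n_nodes - 1) / fwhm
  lo <- stats::qt(1 - a_eff, df)   # EC >= pointwise tail prob, so t* >= lo
  hi <- lo + 20
  while (expected_ec(hi, df, resels) > a_eff) hi <- hi + 20
  stats::uniroot(function(u) expected_ec(u, df, resels) - a_eff,
                 c(lo * 0.5, hi), tol = 1e-10)$root
}

#' Suprathreshold clusters of a t field
#'
#' Maximal runs of nodes with |t| > t*, with endpoints linearly
#' interpolated to fractional % stride at the threshold crossings.
#' Cluster-level p-values use the RFT expected-cluster-extent
#' approximation (capped at `alpha`).
#'
#' @param t_field numeric field over 0..100 % stride.
#' @param threshold critical t from [rft_threshold()].
#' @param df degrees of freedom.
#' @param fwhm smoothness, nodes.
#' @param alpha level used for the p-value cap.
#' @return data.frame: start_pct, end_pct, extent_nodes, peak_t, p.
#' @export
suprathreshold_clusters <- function(t_field, threshold, df, fwhm,
                                    alpha = 0.05) {
  Q <- length(t_field)
  nodes <- seq(0, 100, length.out = Q)
  a <- abs(t_field) > threshold
  empty <- data.frame(start_pct = numeric(), end_pct = numeric(),
                      extent_nodes = numeric(), peak_t = numeric(),
                      p = numeric())
  if (!any(a)) return(empty)
  runs <- mask_runs(a)
  resels <- if (is.finite(fwhm)) (Q - 1) / fwhm else 0
  e_m <- 2 * expected_ec(threshold, df, resels)          # both tails
  e_n <- 2 * resels * stats::pt(threshold, df, lower.tail = FALSE)
  res <- empty
  for (r in seq_len(nrow(runs))) {
    s <- runs$start[r]; e <- runs$end[r]
    at <- abs(t_field)
    start_pct <- if (s > 1L) {
      nodes[s - 1L] + (threshold - at[s - 1L]) / (at[s] - at[s - 1L]) *
        (nodes[s] - nodes[s - 1L])
    } else nodes[1L]
    end_pct <- if (e < Q) {
      nodes[e] + (at[e] - threshold) / (at[e] - at[e + 1L]) *
        (nodes[e + 1L] - nodes[e])
    } else nodes[Q]
    extent <- (end_pct - start_pct) / (100 / (Q - 1))    # node units
    p <- if (is.finite(fwhm) && e_n > 0 && e_m > 0) {
      beta <- e_m / e_n
      min(alpha, 1 - exp(-e_m * exp(-beta * extent / fwhm)))
    } else alpha
    res <- rbind(res, data.frame(start_pct = start_pct, end_pct = end_pct,
                                 extent_nodes = extent,
                                 peak_t = t_field[s:e][which.max(abs(t_field[s:e]))],
                                 p = p))
  }
  res
}

#' Paired SPM analysis of two condition field sets
#'
#' Runs the full 1D SPM chain: paired t field, residual smoothness, RFT
#' critical threshold, suprathreshold clusters.
#'
#' @param A,B subjects x 101 matrices (e.g. median strides per subject).
#' @param alpha two-tailed family-wise level.
#' @param m_comparisons Bonferroni family size.
#' @param variable label carried into the result.
#' @return an `emgait_spm` object.
#' @export
spm_paired <- function(A, B, alpha = 0.05, m_comparisons = 1L,
                       variable = "field") {
  ft <- paired_t_field(A, B)
  fwhm <- estimate_fwhm(ft$residuals)
  thr <- rft_threshold(ft$df, fwhm, n_nodes = length(ft$t), alpha = alpha,
                       m_comparisons = m_comparisons)
  cl <- suprathreshold_clusters(ft$t, thr, ft$df, fwhm, alpha)
  structure(list(variable = variable, t = ft$t, df = ft$df, fwhm = fwhm,
                 threshold = thr, clusters = cl, alpha = alpha,
                 m_bonferroni = m_comparisons),
            class = "emgait_spm")
}

#' @exportS3Method base::print
print.emgait_spm <- function(x, ...) {
  cat(sprintf("<emgait_spm> %s: df = %d, FWHM = %.2f nodes, t* = %.3f (alpha = %g, m = %d)\n",
              x$variable, x$df, x$fwhm, x$threshold, x$alpha, x$m_bonferroni))
  if (nrow(x$clusters)) {
    cat(sprintf("  %d suprathreshold cluster(s):\n", nrow(x$clusters)))
    for (i in seq_len(nrow(x$clusters))) {
      cat(sprintf("    %5.1f - %5.1f %% stride, peak t = %.2f, p = %.4f\n",
                  x$clusters$start_pct[i], x$clusters$end_pct[i],
                  x$clusters$peak_t[i], x$clusters$p[i]))
    }
  } else cat("  no suprathreshold clusters\n")
  invisible(x)
}

#' @exportS3Method base::summary
summary.emgait_spm <- function(object, ...) {
  print(object)
  invisible(list(threshold = object$threshold, clusters = object$clusters))
}

#' @exportS3Method graphics::plot
plot.emgait_spm <- function(x, ...) {
  nodes <- seq(0, 100, length.out = length(x$t))
  graphics::plot(nodes, x$t, type = "l", xlab = "% stride", ylab = "SPM{t}",
                 main = x$variable, ...)
  graphics::abline(h = c(-x$threshold, x$threshold), lty = 2, col = "red")
  if (nrow(x$clusters)) {
    for (i in seq_len(nrow(x$clusters))) {
      graphics::rect(x$clusters$start_pct[i], graphics::par("usr")[3L],
                     x$clusters$end_pct[i], graphics::par("usr")[4L],
                     col = grDevices::adjustcolor("gray", 0.4), border = NA)
    }
  }
  invisible(x)
}

#' Sign-flip permutation threshold (oracle for the RFT threshold)
#'
#' (1 - alpha) quantile of the max-|t| distribution over sign-flip
#' permutations of the paired differences. Exhaustive (all 2^n flips, hence
#' deterministic) when 2^n <= n_perm; random sign vectors otherwise.
#'
#' @param A,B subjects x nodes matrices.
#' @param n_perm permutation budget.
#' @param seed RNG seed for the non-exhaustive case.
#' @param alpha level.
#' @return list: `threshold`, `max_t` (permutation distribution),
#'   `exhaustive`.
#' @export
permutation_spm <- function(A, B, n_perm = 10000L, seed = 1L, alpha = 0.05) {
  D <- as.matrix(A) - as.matrix(B)
  n <- nrow(D)
  if (n < 5L) warning("fewer than 5 subjects: permutation p-resolution is coarse")
  tstat <- function(M) {
    mu <- colMeans(M); sdv <- apply(M, 2L, stats::sd)
    max(abs(ifelse(sdv == 0, 0, mu / (sdv / sqrt(n)))))
  }
  exhaustive <- 2^n <= n_perm
  if (exhaustive) {
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  } else {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    set.seed(seed)
    signs <- matrix(sample(c(1, -1), n_perm * n, replace = TRUE), ncol = n)
  }
  mx <- apply(signs, 1L, function(s) tstat(D * s))
  list(threshold = stats::quantile(mx, 1 - alpha, names = FALSE, type = 7),
       max_t = mx, exhaustive = exhaustive)
}

#' Smooth Gaussian 1D noise fields
#'
#' Generates stationary unit-variance Gaussian fields with a specified
#' smoothness by convolving padded white noise with a Gaussian kernel of
#' FWHM `fwhm` nodes - the standard construction for validating 1D
#' random-field inference.
#'
#' @param n number of fields.
#' @param n_nodes nodes per field.
#' @param fwhm smoothness in nodes.
#' @return n x n_nodes matrix.
#' @export
smooth_gaussian_field <- function(n, n_nodes = 101L, fwhm = 20) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- as.integer(ceiling(4 * sigma))
  kern <- stats::dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sqrt(sum(kern^2))        # unit output variance
  npad <- n_nodes + 2L * half
  out <- matrix(0, n, n_nodes)
  for (i in seq_len(n)) {
    w <- stats::rnorm(npad + 2L * half)
    sm <- stats::convolve(w, kern, type = "filter")   # length npad
    out[i, ] <- sm[(half + 1L):(half + n_nodes)]
  }
  out
}

#' Median stride field per subject and condition
#'
#' Assembles subject-level 101-node fields as the node-wise median across
#' the subject's non-excluded strides - the aggregation used before paired
#' SPM.
#'
#' @param stride_matrix strides x 101 matrix for one subject/condition.
#' @return length-101 numeric vector.
#' @export
median_stride <- function(stride_matrix) {
  M <- as.matrix(stride_matrix)
  if (ncol(M) != 101L) err("stride matrix must have 101 nodes", "emgait_config_error")
  apply(M, 2L, stats::median)
}
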
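#' ROC curve of adjusted MoCA against PSCI
#'
#' Builds the full ROC curve of a demographically adjusted baseline MoCA
#' score against the PSCI reference. The test-positive orientation is
#' "adjusted score strictly below the threshold" (lower MoCA = worse
#' cognition). Candidate thresholds are the midpoints between consecutive
#' distinct observed values, plus sentinels one point below the minimum (no
#' one positive: Se = 0, Sp = 1) and one above the maximum (everyone
#' positive: Se = 1, Sp = 0); midpoints are why selected cut-offs typically
#' land between observed patient scores. The area under the curve is the
#' trapezoidal area over (1 - Sp, Se), which equals the Mann-Whitney
#' concordance probability P(score_PSCI < score_noPSCI) + 1/2 P(tie).
#'
#' @param adjusted Numeric vector of adjusted scores.
#' @param psci Logical vector of PSCI outcomes (both classes present,
#'   n >= 4).
#' @param norm Optional dataset name carried as a label.
#' @return Object of class `"psci_roc"`: list with `points` (data frame,
#'   ordered by decreasing threshold: `threshold`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `youden`, and the four counts `tp`, `fp`,
#'   `fn`, `tn`), `auc`, `n`, `n_psci`, `norm`, `orientation`.
#' @examples
#' r <- psci_roc(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE))
#' r$auc
#' @seealso [select_cutpoint()], [threshold_table()]
#' @export
psci_roc <- function(adjusted, psci, norm = NULL) {
  psci <- as.logical(psci)
  if (length(adjusted) != length(psci)) stop("length mismatch")
  ok <- !is.na(adjusted) & !is.na(psci)
  adjusted <- adjusted[ok]; psci <- psci[ok]
  if (length(psci) < 4) stop("need n >= 4")
  if (!any(psci) || all(psci)) stop("both outcome classes must be present")

  v <- sort(unique(adjusted))
  thr <- if (length(v) > 1) (v[-length(v)] + v[-1]) / 2 else numeric(0)
  thr <- c(min(v) - 1, thr, max(v) + 1)

  n_pos <- sum(psci); n_neg <- sum(!psci)
  pts <- do.call(rbind, lapply(thr, function(t) {
    test_pos <- adjusted < t
    tp <- sum(test_pos & psci); fp <- sum(test_pos & !psci)
    data.frame(threshold = t, tp = tp, fp = fp,
               fn = n_pos - tp, tn = n_neg - fp)
  }))
  pts$sensitivity <- pts$tp / n_pos
  pts$specificity <- pts$tn / n_neg
  pts$ppv <- ifelse(pts$tp + pts$fp > 0, pts$tp / (pts$tp + pts$fp), NA_real_)
  pts$npv <- ifelse(pts$tn + pts$fn > 0, pts$tn / (pts$tn + pts$fn), NA_real_)
  pts$youden <- pts$sensitivity + pts$specificity - 1
  pts <- pts[order(-pts$threshold), c("threshold", "sensitivity", "specificity",
                                      "ppv", "npv", "youden", "tp", "fp", "fn", "tn")]
  rownames(pts) <- NULL

  # trapezoid over (FPR, TPR), sorted by increasing FPR
  fpr <- rev(1 - pts$specificity); tpr <- rev(pts$sensitivity)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)

  structure(list(points = pts, auc = auc, n = length(psci), n_psci = n_pos,
                 norm = norm,
                 orientation = "test positive iff adjusted score < threshold"),
            class = "psci_roc")
}

#' @export
print.psci_roc <- function(x, ...) {
  cat("ROC of adjusted baseline MoCA vs PSCI",
      if (!is.null(x$norm)) paste0(" (", x$norm, " norms)"), "\n", sep = "")
  cat(sprintf("  n = %d (%d PSCI), %d thresholds, AUC = %.3f\n",
              x$n, x$n_psci, nrow(x$points), x$auc))
  cat(" ", x$orientation, "\n")
  invisible(x)
}

#' @export
plot.psci_roc <- function(x, ...) {
  graphics::plot(1 - x$points$specificity, x$points$sensitivity, type = "l",
       xlab = "1 - Specificity", ylab = "Sensitivity",
       main = sprintf("AUC = %.3f", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Threshold coordinate table
#'
#' Lists every ROC threshold with its sensitivity and specificity rendered as
#' half-up integer percentages, flagging the optimal cut-off selected by
#' [select_cutpoint()].
#'
#' @param curve A `"psci_roc"` object.
#' @param around Optional numeric length-2 range; only thresholds inside it
#'   are listed.
#' @param min_se,min_sp Adequacy bounds passed to [select_cutpoint()].
#' @return Data frame ordered by increasing threshold: `threshold`, `se_pct`,
#'   `sp_pct`, `optimal` (logical).
#' @export
threshold_table <- function(curve, around = NULL, min_se = 0.80, min_sp = 0.60) {
  stopifnot(inherits(curve, "psci_roc"))
  best <- select_cutpoint(curve, min_se = min_se, min_sp = min_sp)
  pts <- curve$points[order(curve$points$threshold), ]
  out <- data.frame(threshold = pts$threshold,
                    se_pct = round_half_up(100 * pts$sensitivity),
                    sp_pct = round_half_up(100 * pts$specificity),
                    optimal = pts$threshold == best$threshold)
  if (!is.null(around)) {
    stopifnot(length(around) == 2)
    out <- out[out$threshold >= min(around) & out$threshold <= max(around), ]
  }
  rownames(out) <- NULL
  out
}

#' Select the optimal predictive cut-off
#'
#' Among thresholds meeting the screening adequacy criterion (sensitivity >=
#' `min_se` and specificity >= `min_sp`), returns the one maximizing Youden's
#' J = Se + Sp - 1, breaking ties by higher sensitivity and then by lower
#' threshold (missing PSCI is the costlier error in screening). If no
#' threshold is adequate, the global Youden maximizer is returned with
#' `adequate = FALSE`.
#'
#' @param curve A `"psci_roc"` object.
#' @param min_se,min_sp Adequacy bounds (defaults 0.80 and 0.60).
#' @return Object of class `"psci_cutpoint"`: list with `threshold`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `youden`, `adequate`,
#'   `min_se`, `min_sp`, `norm`.
#' @export
select_cutpoint <- function(curve, min_se = 0.80, min_sp = 0.60) {
  stopifnot(inherits(curve, "psci_roc"))
  pts <- curve$points
  cand <- pts[pts$sensitivity >= min_se & pts$specificity >= min_sp, ]
  adequate <- nrow(cand) > 0
  if (!adequate) cand <- pts
  o <- order(-cand$youden, -cand$sensitivity, cand$threshold)
  row <- cand[o[1], ]
  structure(list(threshold = row$threshold, sensitivity = row$sensitivity,
                 specificity = row$specificity, ppv = row$ppv, npv = row$npv,
                 youden = row$youden, adequate = adequate,
                 min_se = min_se, min_sp = min_sp, norm = curve$norm),
            class = "psci_cutpoint")
}

#' @export
print.psci_cutpoint <- function(x, ...) {
  cat("Optimal predictive cut-off",
      if (!is.null(x$norm)) paste0(" (", x$norm, " norms)"), "\n", sep = "")
  cat(sprintf("  adjusted MoCA < %.2f: Se %.0f%%, Sp %.0f%%, PPV %s, NPV %s, Youden %.2f\n",
              x$threshold, round_half_up(100 * x$sensitivity),
              round_half_up(100 * x$specificity),
              .pct_or_undef(round_half_up(100 * x$ppv)),
              .pct_or_undef(round_half_up(100 * x$npv)), x$youden))
  cat(sprintf("  adequacy (Se >= %.0f%% and Sp >= %.0f%%): %s\n",
              100 * x$min_se, 100 * x$min_sp,
              if (x$adequate) "met" else "NOT met"))
  invisible(x)
}

#' Bootstrap confidence interval for the AUC
#'
#' Seeded nonparametric bootstrap (percentile interval) of the trapezoidal
#' AUC. Off by default throughout the package since the primary analysis
#' reports point AUCs only.
#'
#' @param adjusted,psci As in [psci_roc()].
#' @param n_boot Number of resamples.
#' @param conf_level Interval level.
#' @param seed Optional integer seed.
#' @return List with `auc`, `ci`, `n_boot`.
#' @export
auc_bootstrap_ci <- function(adjusted, psci, n_boot = 1000, conf_level = 0.95,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  psci <- as.logical(psci)
  base <- psci_roc(adjusted, psci)
  reps <- replicate(n_boot, {
    i <- sample.int(length(psci), replace = TRUE)
    if (length(unique(psci[i])) < 2) NA_real_ else psci_roc(adjusted[i], psci[i])$auc
  })
  a <- (1 - conf_level) / 2
  list(auc = base$auc,
       ci = unname(stats::quantile(reps, c(a, 1 - a), na.rm = TRUE)),
       n_boot = n_boot)
}
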
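#' Half-up rounding
#'
#' Rounds halves away from zero (2.5 -> 3), the convention that reproduces
#' published percentage cells (e.g. 46.75 -> 47, 97.56 -> 98), unlike base
#' [round()]'s round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Render a count as a percentage
#'
#' @param count,total Non-negative integers, `count <= total`, `total > 0`.
#' @param decimals Decimal places of the percentage (half-up).
#' @return `100 * count / total`, rounded half-up.
#' @examples
#' proportion_pct(118, 207)      # 57
#' proportion_pct(59, 207, 1)    # 28.5
#' @export
proportion_pct <- function(count, total, decimals = 0) {
  if (any(total <= 0)) stop("total must be > 0")
  if (any(count < 0) || any(count > total)) stop("count must be in [0, total]")
  round_half_up(100 * count / total, decimals)
}

#' Cross-classify baseline performance against PSCI outcome
#'
#' Builds the 2x2 contingency table of baseline MoCA performance
#' (impaired/normal, the "test") against PSCI at follow-up (the reference
#' diagnosis). Impaired + PSCI is a true positive.
#'
#' @param performance Factor/character vector, `impaired`/`normal`.
#' @param psci Logical vector of PSCI outcomes, same length.
#' @return Object of class `"contingency_2x2"`: a list with integer counts
#'   `tp`, `fp`, `fn`, `tn` and `n`.
#' @examples
#' tab <- contingency_2x2(c("impaired", "normal", "normal"), c(TRUE, TRUE, FALSE))
#' @export
contingency_2x2 <- function(performance, psci) {
  performance <- as.character(performance)
  if (length(performance) != length(psci)) stop("length mismatch")
  if (!length(psci)) stop("empty input")
  if (anyNA(performance) || anyNA(psci)) stop("missing values")
  if (!all(performance %in% c("impaired", "normal"))) stop("performance must be impaired/normal")
  psci <- as.logical(psci)
  imp <- performance == "impaired"
  structure(list(tp = sum(imp & psci), fp = sum(imp & !psci),
                 fn = sum(!imp & psci), tn = sum(!imp & !psci),
                 n = length(psci)),
            class = "contingency_2x2")
}

#' Construct a 2x2 table directly from counts
#'
#' @param tp,fp,fn,tn Non-negative integer counts: true/false positives,
#'   false/true negatives (positive test = impaired baseline performance;
#'   positive reference = PSCI).
#' @return A `"contingency_2x2"` object.
#' @export
contingency_counts <- function(tp, fp, fn, tn) {
  cnt <- c(tp = unname(tp), fp = unname(fp), fn = unname(fn), tn = unname(tn))
  if (any(cnt < 0) || any(cnt != as.integer(cnt))) stop("counts must be non-negative integers")
  if (sum(cnt) == 0) stop("empty table")
  structure(list(tp = as.integer(cnt[["tp"]]), fp = as.integer(cnt[["fp"]]),
                 fn = as.integer(cnt[["fn"]]), tn = as.integer(cnt[["tn"]]),
                 n = as.integer(sum(cnt))),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$fp, x$tp, x$tn, x$fn), 2, 2, byrow = TRUE,
              dimnames = list(c("Impaired", "Normal"), c("No PSCI", "PSCI")))
  print(m)
  invisible(x)
}

#' Diagnostic accuracy indices of a 2x2 table
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), positive predictive value
#' tp/(tp+fp) and negative predictive value tn/(tn+fn). An index whose
#' denominator is zero is undefined and returned as `NA` (never coerced to 0
#' or 1).
#'
#' @param table A `"contingency_2x2"` object.
#' @return Object of class `"accuracy_indices"`: list with `sensitivity`,
#'   `specificity`, `ppv`, `npv` (proportions in \[0, 1\] or NA) and `pct`
#'   (the four rendered as half-up integer percentages).
#' @examples
#' accuracy_indices(contingency_counts(tp = 36, fp = 2, fn = 41, tn = 39))
#' @export
accuracy_indices <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  out <- list(
    sensitivity = safe_div(table$tp, table$tp + table$fn),
    specificity = safe_div(table$tn, table$tn + table$fp),
    ppv         = safe_div(table$tp, table$tp + table$fp),
    npv         = safe_div(table$tn, table$tn + table$fn)
  )
  out$pct <- vapply(out, function(p) if (is.na(p)) NA_real_ else round_half_up(100 * p),
                    numeric(1))
  class(out) <- "accuracy_indices"
  out
}

#' @export
print.accuracy_indices <- function(x, ...) {
  cat(sprintf("SE %s  SP %s  PPV %s  NPV %s\n",
              .pct_or_undef(x$pct["sensitivity"]), .pct_or_undef(x$pct["specificity"]),
              .pct_or_undef(x$pct["ppv"]), .pct_or_undef(x$pct["npv"])))
  invisible(x)
}

.pct_or_undef <- function(p) if (is.na(p)) "undefined" else paste0(p, "%")

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson's X-squared without continuity correction, with the p-value from
#' the chi-square distribution with 1 df. A zero row or column marginal makes
#' the statistic inestimable.
#'
#' @param table A `"contingency_2x2"` object.
#' @param correct Apply the Yates continuity correction (default FALSE).
#' @return List with `statistic`, `p_value`, `df`.
#' @export
chi2_test <- function(table, correct = FALSE) {
  stopifnot(inherits(table, "contingency_2x2"))
  m <- matrix(c(table$tp, table$fp, table$fn, table$tn), 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("inestimable: a zero marginal")
  ht <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       df = unname(ht$parameter))
}

#' Per-point logistic risk of PSCI
#'
#' Maximum-likelihood logistic regression of PSCI on the adjusted baseline
#' MoCA score: \code{logit P(PSCI) = intercept + coefficient * adjusted}.
#' Because lower scores carry higher risk, the association is reported as the
#' odds ratio per point LOST, \code{exp(-coefficient)}, with its Wald 95\% CI.
#'
#' Fitting is Fisher-scoring IRLS via [stats::glm()] (convergence tolerance
#' `tol`, at most `max_iter` iterations). Complete separation is reported as
#' `converged = FALSE` (detected by non-convergence or a score coefficient
#' exceeding 50 in magnitude).
#'
#' @param adjusted Numeric vector of adjusted baseline MoCA scores.
#' @param psci Logical vector of PSCI outcomes.
#' @param max_iter,tol IRLS controls.
#' @param conf_level Wald confidence level (default 0.95).
#' @return Object of class `"psci_risk"`: list with `coefficient` (per point
#'   increase), `intercept`, `se`, `or_per_point_lost`, `ci95` (on the
#'   per-point-lost OR), `n`, `converged`, `message`, and the underlying
#'   `fit` (a `glm`).
#' @examples
#' set.seed(1)
#' x <- rnorm(200, 20, 5); y <- runif(200) < plogis(5 - 0.3 * x)
#' fit_psci_logit(x, y)
#' @export
fit_psci_logit <- function(adjusted, psci, max_iter = 100, tol = 1e-8,
                           conf_level = 0.95) {
  psci <- as.logical(psci)
  if (length(adjusted) != length(psci)) stop("length mismatch")
  ok <- !is.na(adjusted) & !is.na(psci)
  adjusted <- adjusted[ok]; psci <- psci[ok]
  if (length(psci) < 10) stop("need n >= 10")
  if (length(unique(psci)) < 2) stop("both outcome classes must be present")

  fit <- suppressWarnings(stats::glm(psci ~ adjusted, family = stats::binomial(),
             control = stats::glm.control(epsilon = tol, maxit = max_iter)))
  beta <- unname(stats::coef(fit)["adjusted"])
  se <- sqrt(diag(stats::vcov(fit)))[["adjusted"]]
  # complete separation: the two classes' score ranges do not overlap, so the
  # MLE diverges even when IRLS reports convergence
  separated <- max(adjusted[psci]) < min(adjusted[!psci]) ||
    max(adjusted[!psci]) < min(adjusted[psci])
  converged <- isTRUE(fit$converged) && is.finite(beta) && abs(beta) <= 50 &&
    !separated
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- sort(exp(-c(beta - z * se, beta + z * se)))
  structure(list(
    coefficient = beta, intercept = unname(stats::coef(fit)[1]), se = se,
    or_per_point_lost = exp(-beta), ci95 = ci, conf_level = conf_level,
    n = length(psci), converged = converged,
    message = if (converged) "converged" else
      "possible complete separation or non-convergence; estimates unreliable",
    fit = fit), class = "psci_risk")
}

#' @export
print.psci_risk <- function(x, digits = 3, ...) {
  cat("Logistic risk of PSCI per adjusted MoCA point lost\n")
  cat(sprintf("  OR = %.*f (%.0f%% CI %.*f-%.*f), n = %d%s\n", digits,
              x$or_per_point_lost, 100 * x$conf_level, digits, x$ci95[1],
              digits, x$ci95[2], x$n,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
coef.psci_risk <- function(object, ...) {
  c(intercept = object$intercept, coefficient = object$coefficient)
}

#' @export
confint.psci_risk <- function(object, ...) object$ci95

#' @export
predict.psci_risk <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$fit))
  stats::plogis(object$intercept + object$coefficient * newdata)
}

#' Compare a baseline variable between two groups
#'
#' Bivariate comparison as used for follow-up vs drop-out baseline tables:
#' numeric variables by a pooled-variance (Student) two-sided t-test (Welch
#' selectable), binary/categorical variables by a Pearson chi-square test
#' without continuity correction.
#'
#' @param x The variable (numeric, logical or factor).
#' @param group Two-level factor/vector splitting the cohort.
#' @param type `"auto"` (default), `"numeric"` or `"categorical"`.
#' @param pooled Use the pooled-variance t-test (default TRUE; FALSE = Welch).
#' @return List with per-group summaries (`mean`/`sd` or counts/`pct`),
#'   `statistic`, `p_value` and `test`.
#' @export
compare_groups <- function(x, group, type = c("auto", "numeric", "categorical"),
                           pooled = TRUE) {
  type <- match.arg(type)
  group <- factor(group)
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  if (any(!table(group))) stop("both groups must be non-empty")
  if (type == "auto")
    type <- if (is.numeric(x)) "numeric" else "categorical"

  if (type == "numeric") {
    s <- split(x, group)
    if (all(vapply(s, stats::sd, 1, na.rm = TRUE) == 0))
      stop("inestimable: zero variance in both groups")
    ht <- stats::t.test(x ~ group, var.equal = pooled)
    list(test = if (pooled) "t (pooled)" else "t (Welch)",
         summary = lapply(s, function(v) list(mean = mean(v, na.rm = TRUE),
                                              sd = stats::sd(v, na.rm = TRUE))),
         statistic = unname(ht$statistic), p_value = ht$p.value)
  } else {
    tab <- table(factor(x), group)
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    n_by_g <- colSums(tab)
    list(test = "chi-square",
         summary = lapply(colnames(tab), function(g)
           list(counts = setNames(as.integer(tab[, g]), rownames(tab)),
                pct = proportion_pct(as.integer(tab[, g]), n_by_g[[g]]))),
         statistic = unname(ht$statistic), p_value = unname(ht$p.value))
  }
}

#' Paper-style p-value rendering
#'
#' @param p Numeric p-value.
#' @param digits Decimals shown.
#' @return `"<0.001"` below 0.001, else the rounded value as character.
#' @export
format_pvalue <- function(p, digits = 3) {
  ifelse(p < 0.001, "<0.001", formatC(round_half_up(p, digits), format = "f", digits = digits))
}
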
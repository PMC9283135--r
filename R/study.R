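#' End-to-end MoCA / PSCI study analysis
#'
#' Orchestrates the full analysis on a cohort: demographic adjustment of the
#' baseline MoCA under each requested normative dataset, impaired/normal
#' classification at the ES = 0 cut-offs and impairment rates; baseline
#' comparisons between followed-up patients and drop-outs; PSCI outcome
#' adjudication at follow-up; adjusted-score comparisons by outcome;
#' diagnostic accuracy of the normative thresholds against PSCI (2x2 table,
#' Se/Sp/PPV/NPV, chi-square); the per-point logistic risk model; and ROC
#' analysis with optimal cut-off selection under the screening adequacy rule
#' (Se >= `min_se`, Sp >= `min_sp`).
#'
#' Patients without a baseline MoCA are excluded from all MoCA analyses but
#' retained in the cohort description (their number is reported). With
#' `exclude_tia = TRUE`, TIA patients leave every denominator.
#'
#' @param baseline Baseline data frame or CSV path (see [validate_inputs()]).
#' @param tests Follow-up test results (long) data frame or CSV path.
#' @param functional Per-patient functional status data frame or CSV path.
#' @param norms Character vector of normative datasets, or `"all"`.
#' @param exclude_tia Drop TIA patients from every analysis.
#' @param min_education Education clamp for the adjustment equations.
#' @param min_se,min_sp Cut-off adequacy bounds.
#' @return Object of class `"psci_study"`; components include `n`,
#'   `n_followed`, `adjusted` (per-norm `moca_adjusted` for the baseline
#'   cohort), `impairment` (per-norm rates), `outcomes` (category counts),
#'   `accuracy` (per-norm 2x2 + indices + chi-square), `risk` (per-norm
#'   [fit_psci_logit()] fits), `roc` and `cutpoint` (per-norm), and `tables`
#'   (report-shaped data frames `table2`, `table3`, `table4`).
#' @examples
#' sim <- simulate_cohort(sim_config(seed = 7, n = 120))
#' st <- psci_study(sim$baseline, sim$tests, sim$functional)
#' print(st)
#' @export
psci_study <- function(baseline, tests, functional,
                       norms = "all", exclude_tia = FALSE,
                       min_education = 1, min_se = 0.80, min_sp = 0.60) {
  if (is.character(baseline)) baseline <- read_cohort_csv(baseline)
  if (is.character(tests)) tests <- read_cohort_csv(tests)
  if (is.character(functional)) functional <- read_cohort_csv(functional)
  if (identical(norms, "all")) norms <- c("aiello", "conti", "santangelo")
  norms <- vapply(norms, function(n) moca_norm(n)$name, "")

  findings <- validate_inputs(baseline, tests, functional)
  errs <- findings[findings$severity == "error", , drop = FALSE]
  if (nrow(errs))
    stop("input validation failed:\n", paste(sprintf("  %s row %s [%s]: %s",
         errs$table, errs$row, errs$column, errs$message), collapse = "\n"))

  if (exclude_tia) {
    n_tia <- sum(baseline$event_type == "TIA", na.rm = TRUE)
    baseline <- baseline[is.na(baseline$event_type) | baseline$event_type != "TIA", ,
                         drop = FALSE]
    tests <- tests[tests$patient_id %in% baseline$id, , drop = FALSE]
    functional <- functional[functional$patient_id %in% baseline$id, , drop = FALSE]
    message("excluded ", n_tia, " TIA patient(s)")
  }
  if (all(is.na(baseline$moca_raw))) stop("no patient has a baseline MoCA score")

  has_fu <- if ("followed_up" %in% names(baseline)) isTRUE_vec(baseline$followed_up)
            else baseline$id %in% functional$patient_id
  diagnoses <- adjudicate_cohort(tests, functional)
  diagnoses <- diagnoses[diagnoses$patient_id %in% baseline$id[has_fu], , drop = FALSE]
  if (nrow(diagnoses) == 0) stop("no followed-up patient with an adjudicated outcome")
  outcomes <- outcome_table(diagnoses)

  # per-norm baseline adjustment + accuracy vs PSCI among the followed-up
  adjusted <- impairment <- accuracy <- risk <- roc <- cutpoint <- table3_rows <-
    setNames(vector("list", length(norms)), norms)
  for (nm in norms) {
    adj <- suppressWarnings(adjust_cohort(baseline, nm, min_education = min_education))
    adjusted[[nm]] <- adj
    impairment[[nm]] <- impairment_rate(adj, decimals = 1)

    m <- match(diagnoses$patient_id, adj$id)
    ok <- !is.na(m)
    perf <- adj$performance[m[ok]]
    val <- adj$value[m[ok]]
    psci <- diagnoses$psci[ok]
    cat3 <- diagnoses$category[ok]

    tab <- contingency_2x2(perf, psci)
    accuracy[[nm]] <- list(table = tab, indices = accuracy_indices(tab),
                           chi2 = tryCatch(chi2_test(tab), error = function(e) NULL))
    risk[[nm]] <- fit_psci_logit(val, psci)
    roc[[nm]] <- psci_roc(val, psci, norm = nm)
    cutpoint[[nm]] <- select_cutpoint(roc[[nm]], min_se = min_se, min_sp = min_sp)

    grp <- split(val, psci)
    tt <- stats::t.test(val ~ psci, var.equal = TRUE)
    aovp <- summary(stats::aov(val ~ cat3))[[1]][["Pr(>F)"]][1]
    table3_rows[[nm]] <- data.frame(
      norm = nm,
      mean_no_psci = mean(grp[["FALSE"]]), sd_no_psci = stats::sd(grp[["FALSE"]]),
      mean_psci = mean(grp[["TRUE"]]), sd_psci = stats::sd(grp[["TRUE"]]),
      p_ttest = tt$p.value,
      mean_mci = mean(val[cat3 == "mci"]), mean_dementia = mean(val[cat3 == "dementia"]),
      p_anova = aovp, stringsAsFactors = FALSE)
  }

  tables <- list(
    table2 = .table2(baseline, has_fu, adjusted),
    table3 = do.call(rbind, table3_rows),
    table4 = do.call(rbind, lapply(norms, function(nm) {
      a <- accuracy[[nm]]
      data.frame(norm = nm, tp = a$table$tp, fp = a$table$fp, fn = a$table$fn,
                 tn = a$table$tn,
                 se_pct = a$indices$pct[["sensitivity"]],
                 sp_pct = a$indices$pct[["specificity"]],
                 ppv_pct = a$indices$pct[["ppv"]],
                 npv_pct = a$indices$pct[["npv"]],
                 p_chi2 = if (is.null(a$chi2)) NA_real_ else a$chi2$p_value,
                 stringsAsFactors = FALSE)
    }))
  )
  rownames(tables$table3) <- rownames(tables$table4) <- NULL

  structure(list(
    n = nrow(baseline), n_followed = sum(has_fu), n_dropout = sum(!has_fu),
    n_missing_moca = sum(is.na(baseline$moca_raw)),
    n_analyzable = nrow(diagnoses),
    adjusted = adjusted, impairment = impairment,
    diagnoses = diagnoses, outcomes = outcomes,
    accuracy = accuracy, risk = risk, roc = roc, cutpoint = cutpoint,
    tables = tables, findings = findings,
    params = list(norms = norms, exclude_tia = exclude_tia,
                  min_education = min_education, min_se = min_se, min_sp = min_sp)),
    class = "psci_study")
}

# follow-up vs drop-out baseline comparison table
.table2 <- function(baseline, has_fu, adjusted) {
  grp <- factor(ifelse(has_fu, "followed", "dropout"), c("followed", "dropout"))
  both <- nlevels(droplevels(grp)) == 2
  row_num <- function(label, x) {
    cg <- if (both) tryCatch(compare_groups(x, grp), error = function(e) NULL) else NULL
    data.frame(variable = label,
               all_mean = mean(x, na.rm = TRUE), all_sd = stats::sd(x, na.rm = TRUE),
               followed_mean = mean(x[has_fu], na.rm = TRUE),
               dropout_mean = mean(x[!has_fu], na.rm = TRUE),
               p = if (is.null(cg)) NA_real_ else cg$p_value,
               stringsAsFactors = FALSE)
  }
  rows <- list(row_num("age", baseline$age),
               row_num("education_years", baseline$education_years))
  if ("nihss" %in% names(baseline)) rows <- c(rows, list(row_num("nihss", baseline$nihss)))
  rows <- c(rows, list(row_num("moca_raw", baseline$moca_raw)))
  if ("sex" %in% names(baseline)) {
    x <- as.integer(baseline$sex == "female")
    cg <- if (both) tryCatch(compare_groups(factor(x), grp, type = "categorical"),
                             error = function(e) NULL) else NULL
    rows <- c(rows, list(data.frame(variable = "female",
      all_mean = mean(x, na.rm = TRUE), all_sd = NA_real_,
      followed_mean = mean(x[has_fu], na.rm = TRUE),
      dropout_mean = mean(x[!has_fu], na.rm = TRUE),
      p = if (is.null(cg)) NA_real_ else cg$p_value, stringsAsFactors = FALSE)))
  }
  for (nm in names(adjusted)) {
    adj <- adjusted[[nm]]
    imp <- setNames(adj$performance == "impaired", adj$id)
    x <- as.integer(imp[match(baseline$id, names(imp))])
    cg <- if (both) tryCatch(compare_groups(factor(x), grp, type = "categorical"),
                             error = function(e) NULL) else NULL
    rows <- c(rows, list(data.frame(variable = paste0("impaired_", nm),
      all_mean = mean(x, na.rm = TRUE), all_sd = NA_real_,
      followed_mean = mean(x[has_fu], na.rm = TRUE),
      dropout_mean = mean(x[!has_fu], na.rm = TRUE),
      p = if (is.null(cg)) NA_real_ else cg$p_value, stringsAsFactors = FALSE)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.psci_study <- function(x, ...) {
  cat("MoCA / PSCI study\n")
  cat(sprintf("  cohort n = %d; followed-up %d (%s%%); missing baseline MoCA %d\n",
              x$n, x$n_followed, proportion_pct(x$n_followed, x$n), x$n_missing_moca))
  o <- x$outcomes
  cat(sprintf("  PSCI %d/%d (%s%%): %d MCI, %d dementia\n",
              attr(o, "psci"), x$n_analyzable,
              proportion_pct(attr(o, "psci"), x$n_analyzable),
              o[["mci"]], o[["dementia"]]))
  for (nm in names(x$roc)) {
    cp <- x$cutpoint[[nm]]
    cat(sprintf("  %-11s impaired %s%%  AUC %.3f  OR/point lost %.2f  cut-off %.2f (Se %.0f%%, Sp %.0f%%%s)\n",
                nm, format(x$impairment[[nm]]$pct), x$roc[[nm]]$auc,
                x$risk[[nm]]$or_per_point_lost, cp$threshold,
                100 * cp$sensitivity, 100 * cp$specificity,
                if (cp$adequate) ", adequate" else ""))
  }
  invisible(x)
}

#' @export
summary.psci_study <- function(object, ...) {
  x <- object
  print(x)
  cat("\nBaseline comparisons (followed-up vs drop-outs):\n")
  t2 <- x$tables$table2
  t2[, sapply(t2, is.numeric)] <- round(t2[, sapply(t2, is.numeric)], 3)
  print(t2, row.names = FALSE)
  cat("\nAdjusted scores by outcome:\n")
  t3 <- x$tables$table3
  t3[, sapply(t3, is.numeric)] <- round(t3[, sapply(t3, is.numeric)], 3)
  print(t3, row.names = FALSE)
  cat("\nAccuracy of the ES=0 normative thresholds vs PSCI:\n")
  print(x$tables$table4, row.names = FALSE)
  cat("\nLogistic risk per adjusted point lost:\n")
  for (nm in names(x$risk)) { cat(sprintf("  %-11s ", nm)); print(x$risk[[nm]]) }
  invisible(x)
}
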
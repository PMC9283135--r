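#' Read a cohort table from CSV
#'
#' Thin wrapper around [utils::read.csv()] (UTF-8, empty cells as NA) that
#' coerces the known logical columns (`followed_up`, `impaired`,
#' `adl_dependent`, `iadl_dependent`, `functional_loss_noncognitive`) from
#' TRUE/FALSE or 0/1 encodings.
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"),
                        fileEncoding = "UTF-8")
  for (col in intersect(c("followed_up", "impaired", "adl_dependent",
                          "iadl_dependent", "functional_loss_noncognitive"),
                        names(df))) {
    v <- df[[col]]
    if (!is.logical(v))
      df[[col]] <- as.logical(ifelse(v %in% c("1", 1), TRUE,
                              ifelse(v %in% c("0", 0), FALSE, v)))
  }
  df
}

.finding <- function(severity, table, row, column, message) {
  data.frame(severity = severity, table = table, row = row, column = column,
             message = message, stringsAsFactors = FALSE)
}

#' Validate study input tables
#'
#' Schema and range checks for the three study tables, distinguishing errors
#' (rows that cannot enter the analysis) from warnings (handled degeneracies
#' such as education 0, which is clamped downstream).
#'
#' @param baseline Baseline data frame (or CSV path): `id`, `age`,
#'   `education_years`, `sex`, `event_type`, `nihss`, `moca_raw`,
#'   `followed_up`, `follow_up_months`.
#' @param tests Optional follow-up test data frame (or path): `patient_id`,
#'   `test_name`, `domain`, `impaired`.
#' @param functional Optional functional-status data frame (or path):
#'   `patient_id`, `adl_dependent`, `iadl_dependent`, `mrs`,
#'   `functional_loss_noncognitive`.
#' @return Data frame of findings (`severity`, `table`, `row`, `column`,
#'   `message`); zero rows when the inputs are clean.
#' @export
validate_inputs <- function(baseline, tests = NULL, functional = NULL) {
  if (is.character(baseline)) baseline <- read_cohort_csv(baseline)
  if (is.character(tests)) tests <- read_cohort_csv(tests)
  if (is.character(functional)) functional <- read_cohort_csv(functional)
  f <- list()
  add <- function(...) f[[length(f) + 1L]] <<- .finding(...)

  need <- c("id", "age", "education_years", "moca_raw")
  for (col in setdiff(need, names(baseline)))
    add("error", "baseline", NA_integer_, col, "required column missing")
  if (all(need %in% names(baseline))) {
    if (anyDuplicated(baseline$id))
      add("error", "baseline", NA_integer_, "id", "duplicated patient id")
    for (i in seq_len(nrow(baseline))) {
      mr <- baseline$moca_raw[i]
      if (!is.na(mr) && (mr != round(mr) || mr < 0 || mr > 30))
        add("error", "baseline", i, "moca_raw", sprintf("value %s outside integer [0, 30]", mr))
      if (is.na(mr))
        add("warning", "baseline", i, "moca_raw", "missing; excluded from MoCA analyses")
      if (is.na(baseline$age[i]) || baseline$age[i] <= 18)
        add("error", "baseline", i, "age", "age must be > 18 years")
      ed <- baseline$education_years[i]
      if (is.na(ed))
        add("warning", "baseline", i, "education_years", "missing; clamped to minimum downstream")
      else if (ed < 0)
        add("error", "baseline", i, "education_years", "negative education")
      else if (ed < 1)
        add("warning", "baseline", i, "education_years", "education < 1 year; clamped downstream")
    }
    if ("followed_up" %in% names(baseline) && "follow_up_months" %in% names(baseline)) {
      bad <- which(xor(isTRUE_vec(baseline$followed_up), !is.na(baseline$follow_up_months)))
      for (i in bad)
        add("warning", "baseline", i, "follow_up_months",
            "follow_up_months should be present iff followed_up")
    }
  }
  if (!is.null(tests)) {
    for (col in setdiff(c("patient_id", "impaired"), names(tests)))
      add("error", "tests", NA_integer_, col, "required column missing")
    if (all(c("patient_id", "impaired") %in% names(tests))) {
      for (i in which(is.na(as.logical(tests$impaired))))
        add("error", "tests", i, "impaired", "not interpretable as logical")
      unknown <- which(!tests$patient_id %in% baseline$id)
      for (i in unknown)
        add("warning", "tests", i, "patient_id", "patient not in baseline table")
    }
  }
  if (!is.null(functional)) {
    need_f <- c("patient_id", "adl_dependent", "iadl_dependent",
                "functional_loss_noncognitive")
    for (col in setdiff(need_f, names(functional)))
      add("error", "functional", NA_integer_, col, "required column missing")
  }
  out <- if (length(f)) do.call(rbind, f) else
    .finding(character(0), character(0), integer(0), character(0), character(0))
  rownames(out) <- NULL
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Write the full study report to a directory
#'
#' Emits the report bundle: `report.md` plus CSVs shaped like the study
#' tables (`table2.csv` cohort comparisons, `table3.csv` adjusted-score group
#' comparisons, `table4.csv` accuracy of the normative thresholds,
#' `table5_<norm>.csv` threshold coordinate tables, `roc_<norm>.csv` ROC
#' points) and `meta.json` (effective configuration, for provenance).
#' Re-running on the same study object overwrites byte-identically.
#'
#' @param study A [psci_study()] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study_report <- function(study, dir) {
  stopifnot(inherits(study, "psci_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wcsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }

  wcsv(study$tables$table2, "table2.csv")
  wcsv(study$tables$table3, "table3.csv")
  wcsv(study$tables$table4, "table4.csv")
  for (nm in names(study$roc)) {
    wcsv(threshold_table(study$roc[[nm]], min_se = study$params$min_se,
                         min_sp = study$params$min_sp),
         sprintf("table5_%s.csv", nm))
    pts <- study$roc[[nm]]$points
    wcsv(data.frame(threshold = pts$threshold,
                    sensitivity = pts$sensitivity,
                    specificity = pts$specificity), sprintf("roc_%s.csv", nm))
  }

  meta <- list(package = "mocapsci",
               version = as.character(utils::packageVersion("mocapsci")),
               norms = names(study$roc), params = study$params,
               n = study$n, n_followed = study$n_followed)
  p <- file.path(dir, "meta.json")
  jsonlite::write_json(meta, p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths <- c(paths, p)

  md <- file.path(dir, "report.md")
  writeLines(format_study_md(study), md)
  invisible(c(paths, md))
}

format_study_md <- function(study) {
  s <- utils::capture.output(summary(study))
  c("# MoCA / PSCI study report", "", "```", s, "```")
}
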
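#' Flag cognitive impairment from a follow-up test battery
#'
#' A followed-up patient is cognitively impaired iff at least one test of the
#' battery is impaired (i.e. its demographically adjusted score fell below
#' the 5th centile of the normal population; that norming happens upstream,
#' this package consumes per-test boolean flags).
#'
#' @param impaired Logical vector of per-test impairment flags (non-empty,
#'   no NA).
#' @return Single logical.
#' @examples
#' flag_cognitive_impairment(c(FALSE, FALSE, TRUE))
#' @export
flag_cognitive_impairment <- function(impaired) {
  if (!length(impaired) || anyNA(impaired))
    stop("patient not assessable: no valid test results")
  any(as.logical(impaired))
}

#' Adjudicate PSCI outcome for one patient
#'
#' Classifies the 6-9-month outcome as `none`, `mci` or `dementia`:
#' no cognitive impairment (no impaired test) gives `none`; dementia requires
#' cognitive impairment plus functional dependence in ADL or IADL that is not
#' attributable to motor/sensory sequelae of the cerebrovascular event (or
#' other non-cognitive disease); every other cognitively impaired patient is
#' MCI. PSCI means `mci` or `dementia`.
#'
#' @param impaired Logical vector of per-test impairment flags.
#' @param adl_dependent,iadl_dependent Logical: dependence on the (instrumental)
#'   activities-of-daily-living scales.
#' @param functional_loss_noncognitive Logical: TRUE when the dependence is a
#'   motor/sensory sequela or due to another disease, so it does not count
#'   towards dementia.
#' @return List with `category` (factor: none/mci/dementia) and `psci`
#'   (logical).
#' @examples
#' adjudicate_psci(c(TRUE, FALSE), adl_dependent = FALSE, iadl_dependent = TRUE,
#'                 functional_loss_noncognitive = FALSE)
#' @export
adjudicate_psci <- function(impaired, adl_dependent, iadl_dependent,
                            functional_loss_noncognitive = FALSE) {
  ci <- flag_cognitive_impairment(impaired)
  dependent <- isTRUE(as.logical(adl_dependent)) || isTRUE(as.logical(iadl_dependent))
  category <- if (!ci) "none"
    else if (dependent && !isTRUE(as.logical(functional_loss_noncognitive))) "dementia"
    else "mci"
  list(category = factor(category, levels = c("none", "mci", "dementia")),
       psci = category != "none")
}

#' Adjudicate PSCI outcomes for a followed-up cohort
#'
#' Joins long-format test results with per-patient functional status and
#' adjudicates each patient with [adjudicate_psci()]. Patients present in the
#' functional table but with no test rows are not assessable; they are
#' dropped with a message.
#'
#' @param tests Data frame, one row per (patient, test): columns `patient_id`,
#'   `impaired` (logical); `test_name` and `domain` may be present and are
#'   ignored here.
#' @param functional Data frame, one row per patient: columns `patient_id`,
#'   `adl_dependent`, `iadl_dependent`, `functional_loss_noncognitive`
#'   (logical); `mrs` may be present (descriptive only, never used in
#'   adjudication).
#' @return Data frame with one row per assessable patient: `patient_id`,
#'   `category` (factor none/mci/dementia), `psci` (logical).
#' @export
adjudicate_cohort <- function(tests, functional) {
  stopifnot(is.data.frame(tests), is.data.frame(functional))
  need_t <- c("patient_id", "impaired"); need_f <- c("patient_id", "adl_dependent",
              "iadl_dependent", "functional_loss_noncognitive")
  if (length(m <- setdiff(need_t, names(tests)))) stop("tests: missing columns ", paste(m, collapse = ", "))
  if (length(m <- setdiff(need_f, names(functional)))) stop("functional: missing columns ", paste(m, collapse = ", "))
  if (anyDuplicated(functional$patient_id)) stop("functional: duplicated patient_id")

  ids <- functional$patient_id
  has_tests <- ids %in% tests$patient_id
  if (any(!has_tests))
    message(sum(!has_tests), " patient(s) not assessable (no test results); dropped")

  flags <- split(as.logical(tests$impaired), tests$patient_id)
  rows <- lapply(which(has_tests), function(i) {
    d <- adjudicate_psci(flags[[as.character(ids[i])]],
                         functional$adl_dependent[i],
                         functional$iadl_dependent[i],
                         functional$functional_loss_noncognitive[i])
    data.frame(patient_id = ids[i], category = d$category, psci = d$psci)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tabulate PSCI outcome categories
#'
#' @param diagnoses Data frame from [adjudicate_cohort()], or a factor of
#'   categories.
#' @return Named integer vector with counts for `none`, `mci`, `dementia`,
#'   plus attribute `"psci"` (count with PSCI = mci + dementia).
#' @export
outcome_table <- function(diagnoses) {
  cat_ <- if (is.data.frame(diagnoses)) diagnoses$category else diagnoses
  cat_ <- factor(as.character(cat_), levels = c("none", "mci", "dementia"))
  if (anyNA(cat_)) stop("unknown outcome category")
  counts <- table(cat_)
  out <- setNames(as.integer(counts), names(counts))
  attr(out, "psci") <- out[["mci"]] + out[["dementia"]]
  out
}
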
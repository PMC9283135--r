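#' Normative datasets for the Italian MoCA
#'
#' Three published normative datasets for the Italian version of the Montreal
#' Cognitive Assessment (MoCA) provide regression equations that adjust the
#' raw total score (0-30) for age and education, together with the adjusted
#' cut-off below which a performance is classified as impaired (equivalent
#' score ES = 0, i.e. below the outer tolerance limit of the 5th centile of
#' the normal population).
#'
#' The adjustment equations are, with `raw` the raw total, `age` in years and
#' `edu` years of education:
#' \describe{
#'   \item{conti}{\code{raw + 0.175 * (age - 70.08) + 24.3 * (1/edu - 0.126)},
#'     ES = 0 below 17.36, normative age range 60-80.}
#'   \item{santangelo}{\code{raw - 4.228 * (log10(100 - age) - 1.58) -
#'     3.201 * (sqrt(edu) - 3.25)}, ES = 0 below 15.50, age range 21-95.}
#'   \item{aiello}{\code{raw + 0.000008 * (age^3 - 297697.184801) -
#'     3.331407 * (log(edu) - 2.325648)}, ES = 0 below 18.58, age range 21-96.}
#' }
#'
#' Constants are shipped as a read-only JSON resource
#' (\code{system.file("extdata", "moca_norms.json", package = "mocapsci")})
#' so their provenance is auditable.
#'
#' @param name Dataset name: one of \code{"conti"}, \code{"santangelo"},
#'   \code{"aiello"}.
#' @return `moca_norms()` returns a named list of all three datasets;
#'   `moca_norm(name)` returns a single dataset as a list with elements
#'   `name`, `label`, `es0_cutoff`, `age_range`, `age` and `education`
#'   (each a list with `transform`, `coef`, `center`).
#' @examples
#' moca_norm("aiello")$es0_cutoff
#' names(moca_norms())
#' @export
moca_norms <- function() {
  norms <- get0(".moca_norms_cache", envir = .mocapsci_env)
  if (is.null(norms)) {
    path <- system.file("extdata", "moca_norms.json", package = "mocapsci")
    stopifnot(nzchar(path))
    norms <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    for (nm in names(norms)) norms[[nm]]$name <- nm
    assign(".moca_norms_cache", norms, envir = .mocapsci_env)
  }
  norms
}

.mocapsci_env <- new.env(parent = emptyenv())

#' @rdname moca_norms
#' @export
moca_norm <- function(name) {
  name <- match.arg(tolower(name), c("conti", "santangelo", "aiello"))
  moca_norms()[[name]]
}

# transform of the demographic variable used inside each equation
.norm_transform <- function(x, transform) {
  switch(transform,
    identity            = x,
    reciprocal          = 1 / x,
    sqrt                = sqrt(x),
    log                 = log(x),
    log10_100_minus_age = log10(100 - x),
    cube                = x^3,
    stop("unknown transform: ", transform)
  )
}

#' Demographically adjusted MoCA scores
#'
#' Converts raw MoCA totals into demographically adjusted scores under one of
#' the three normative datasets and classifies each performance as impaired
#' (ES = 0) or normal at the dataset's cut-off. The classification is strict:
#' a performance is impaired iff the adjusted value lies strictly below the
#' cut-off; ties at the cut-off are normal.
#'
#' Degenerate demographics are clamped rather than rejected, and flagged:
#' education below `min_education` (the reciprocal and logarithmic education
#' terms are undefined at 0) is raised to `min_education`, and ages of 100 or
#' more (for which the Santangelo age term `log10(100 - age)` is undefined)
#' are lowered to 99. Ages outside the dataset's normative age range are
#' evaluated anyway but flagged `extrapolated`. Adjusted values are not
#' clamped to the 0-30 raw-score range: the equations are additive
#' corrections, and truncating them would distort score ordering in
#' downstream ROC analyses.
#'
#' @param raw Integer vector of raw MoCA totals, each in 0-30. Missing values
#'   are an error here; use [adjust_cohort()] to skip patients without a
#'   baseline score.
#' @param age Numeric vector of ages in years (> 18).
#' @param education Numeric vector of years of education (>= 0).
#' @param norm A dataset name or a list from [moca_norm()].
#' @param min_education Minimum years of education used in the equations;
#'   lower values are clamped to it. Default 1.
#' @return A data frame of class `"moca_adjusted"` with one row per score:
#'   `value` (adjusted score), `performance` (factor, `impaired`/`normal`),
#'   `clamped_inputs` and `extrapolated` (logical flags), plus the dataset
#'   name in attribute `"norm"`.
#' @examples
#' adjust_moca(20, age = 80, education = 5, norm = "conti")
#' @seealso [classify_moca()], [adjust_cohort()], [impairment_rate()]
#' @export
adjust_moca <- function(raw, age, education, norm, min_education = 1) {
  if (is.character(norm)) norm <- moca_norm(norm)
  n <- max(length(raw), length(age), length(education))
  raw <- rep_len(raw, n); age <- rep_len(age, n); education <- rep_len(education, n)

  if (anyNA(raw)) stop("raw MoCA score unavailable (NA); see adjust_cohort() for cohorts with missing scores")
  if (any(raw != as.integer(raw)) || any(raw < 0 | raw > 30))
    stop("raw MoCA total must be an integer in [0, 30]")
  if (anyNA(age) || any(age <= 18)) stop("age must be > 18 years")
  if (anyNA(education) || any(education < 0)) stop("education must be >= 0 years")

  edu_used <- pmax(education, min_education)
  age_used <- age
  if (norm$age$transform == "log10_100_minus_age") age_used <- pmin(age, 99)
  clamped <- (edu_used != education) | (age_used != age)
  if (any(clamped))
    warning(sum(clamped), " record(s) had age/education clamped before adjustment")

  value <- raw +
    norm$age$coef * (.norm_transform(age_used, norm$age$transform) - norm$age$center) +
    norm$education$coef * (.norm_transform(edu_used, norm$education$transform) - norm$education$center)

  out <- data.frame(
    value = value,
    performance = classify_moca(value, norm),
    clamped_inputs = clamped,
    extrapolated = age < norm$age_range[1] | age > norm$age_range[2]
  )
  attr(out, "norm") <- norm$name
  class(out) <- c("moca_adjusted", "data.frame")
  out
}

#' Classify adjusted MoCA values as impaired or normal
#'
#' A performance is impaired (equivalent score ES = 0) iff the adjusted value
#' is strictly below the dataset's cut-off; values at or above the cut-off
#' are normal.
#'
#' @param value Numeric vector of adjusted MoCA scores (finite).
#' @param norm Dataset name or list from [moca_norm()].
#' @return Factor with levels `impaired`, `normal`.
#' @examples
#' classify_moca(c(18.0, 18.58), "aiello")
#' @export
classify_moca <- function(value, norm) {
  if (is.character(norm)) norm <- moca_norm(norm)
  if (anyNA(value) || any(!is.finite(value))) stop("adjusted values must be finite")
  factor(ifelse(value < norm$es0_cutoff, "impaired", "normal"),
         levels = c("impaired", "normal"))
}

#' Adjust a whole cohort
#'
#' Applies [adjust_moca()] to every patient record with a non-missing raw
#' MoCA total, in input order. Records with a missing score are skipped with
#' a message (they cannot enter any MoCA analysis).
#'
#' @param records Data frame of patient records with columns `id`,
#'   `moca_raw`, `age`, `education_years`.
#' @param norm Dataset name or list from [moca_norm()].
#' @param min_education Passed to [adjust_moca()].
#' @return A `"moca_adjusted"` data frame (see [adjust_moca()]) with an extra
#'   leading `id` column; one row per record with a non-missing `moca_raw`.
#' @export
adjust_cohort <- function(records, norm, min_education = 1) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("empty cohort")
  need <- c("id", "moca_raw", "age", "education_years")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))

  keep <- !is.na(records$moca_raw)
  if (any(!keep))
    message(sum(!keep), " record(s) skipped: raw MoCA score unavailable")
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no record has a baseline MoCA score")

  adj <- adjust_moca(rec$moca_raw, rec$age, rec$education_years, norm,
                     min_education = min_education)
  out <- cbind(id = rec$id, adj)
  attr(out, "norm") <- attr(adj, "norm")
  attr(out, "n_skipped") <- sum(!keep)
  class(out) <- class(adj)
  rownames(out) <- NULL
  out
}

#' Rate of impaired baseline performances
#'
#' Proportion of performances classified impaired (ES = 0) in a set of
#' adjusted scores from a single normative dataset.
#'
#' @param scores A `"moca_adjusted"` data frame, or a list of them (all from
#'   the same dataset).
#' @param decimals Decimals of the rendered percentage (half-up rounding).
#' @return List with `n_impaired`, `n`, `rate` (exact ratio) and `pct`
#'   (rounded percentage).
#' @examples
#' a <- adjust_moca(c(10, 25), age = c(80, 70), education = c(5, 13), norm = "aiello")
#' impairment_rate(a)
#' @export
impairment_rate <- function(scores, decimals = 0) {
  if (is.data.frame(scores)) scores <- list(scores)
  ds <- unique(vapply(scores, attr, "", which = "norm"))
  if (length(ds) != 1L) stop("scores mix normative datasets: ", paste(ds, collapse = ", "))
  perf <- unlist(lapply(scores, function(s) as.character(s$performance)))
  if (!length(perf)) stop("no scores")
  k <- sum(perf == "impaired")
  list(n_impaired = k, n = length(perf), rate = k / length(perf),
       pct = proportion_pct(k, length(perf), decimals))
}

#' @export
print.moca_adjusted <- function(x, ...) {
  cat("Demographically adjusted MoCA scores (", attr(x, "norm"),
      " norms, ES=0 cut-off ", moca_norm(attr(x, "norm"))$es0_cutoff, ")\n", sep = "")
  y <- x
  y$value <- round(y$value, 2)  # reports show two decimals; full precision kept internally
  print.data.frame(y, ...)
  invisible(x)
}
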
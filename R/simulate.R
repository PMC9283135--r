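#' Configuration of the synthetic stroke-cohort simulator
#'
#' Collects and validates the generative parameters of the synthetic acute
#' stroke cohort. Defaults reproduce the structure of a two-centre acute
#' stroke cohort: n = 207 patients, age 76 +/- 9.6 years, education 9.1 +/-
#' 4.5 years, 34\% female, raw MoCA 17.1 +/- 6.9, NIHSS 2.1 +/- 3.1, 57\%
#' follow-up with informative drop-out (drop-outs older and with lower
#' baseline MoCA), 65\% PSCI prevalence among the followed-up with 22/77
#' dementia, and a PSCI odds ratio of 1.39 per adjusted MoCA point lost.
#'
#' Raw MoCA is linked to demographics through a single latent cognitive
#' ability: \code{ability = age_loading * z(age) + edu_loading * z(edu) +
#' noise} (unit variance), so that demographic adjustment is exercised
#' non-trivially. The PSCI outcome model conditions on the Aiello-adjusted
#' baseline score only: \code{logit P(PSCI) = alpha - log(or) * adjusted},
#' with `alpha` calibrated by bisection so the expected prevalence among the
#' followed-up equals `psci_prevalence` (the per-point odds ratio is then the
#' directly recoverable generative parameter). Drop-out is likewise a
#' calibrated logistic model in age and raw MoCA.
#'
#' @param seed Integer seed (mandatory; all randomness flows from it).
#' @param n Cohort size.
#' @param age_mean,age_sd,age_range Age distribution, years (truncated
#'   normal, rejection sampling).
#' @param edu_mean,edu_sd,edu_range Education, years (truncated normal,
#'   rounded to integers after truncation).
#' @param p_female Proportion of females.
#' @param event_probs Named probabilities for `TIA`, `ischemic`,
#'   `hemorrhagic` (sum to 1).
#' @param nihss_mean,nihss_sd NIHSS (truncated at \[0, 42\], rounded).
#' @param moca_mean,moca_sd Raw MoCA total (truncated \[0, 30\], rounded).
#' @param ability_age_loading,ability_edu_loading Loadings of standardized
#'   age and education on the latent ability (their squared sum must be < 1).
#' @param followup_rate Expected follow-up fraction.
#' @param dropout_age_effect,dropout_moca_effect Retention log-odds per year
#'   of age / per raw MoCA point (negative age effect and positive MoCA
#'   effect produce older, lower-MoCA drop-outs).
#' @param psci_or_per_point_lost Generative odds ratio of PSCI per adjusted
#'   MoCA point lost.
#' @param psci_prevalence Target PSCI prevalence among the followed-up.
#' @param p_dementia_given_psci P(dementia | PSCI).
#' @param p_noncognitive_dependence Probability that an MCI patient carries
#'   ADL/IADL dependence attributable to motor/sensory sequelae.
#' @param followup_months_mean,followup_months_sd Follow-up interval, months
#'   (truncated to \[3, 15\]).
#' @param n_tests Number of follow-up neuropsychological tests.
#' @param test_noise_sd SD of per-test noise around the latent ability.
#' @return A validated list of class `"sim_config"`, with `rng` metadata
#'   (algorithm pinned for reproducibility).
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(seed,
                       n = 207,
                       age_mean = 76, age_sd = 9.6, age_range = c(45, 95),
                       edu_mean = 9.1, edu_sd = 4.5, edu_range = c(1, 21),
                       p_female = 0.34,
                       event_probs = c(TIA = 0.06, ischemic = 0.84, hemorrhagic = 0.10),
                       nihss_mean = 2.1, nihss_sd = 3.1,
                       moca_mean = 17.1, moca_sd = 6.9,
                       ability_age_loading = -0.35, ability_edu_loading = 0.25,
                       followup_rate = 0.57,
                       dropout_age_effect = -0.035, dropout_moca_effect = 0.05,
                       psci_or_per_point_lost = 1.39,
                       psci_prevalence = 0.65,
                       p_dementia_given_psci = 22 / 77,
                       p_noncognitive_dependence = 0.15,
                       followup_months_mean = 7.4, followup_months_sd = 1.7,
                       n_tests = 8, test_noise_sd = 0.8) {
  cfg <- as.list(environment())
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(is.numeric(seed) && length(seed) == 1 && seed == as.integer(seed), "seed must be a single integer")
  chk(n >= 1, "n must be >= 1")
  for (p in c("p_female", "psci_prevalence",
              "p_dementia_given_psci", "p_noncognitive_dependence"))
    chk(cfg[[p]] > 0 && cfg[[p]] < 1, paste(p, "must be in (0, 1)"))
  chk(followup_rate > 0 && followup_rate <= 1, "followup_rate must be in (0, 1]")
  for (p in c("age_sd", "edu_sd", "nihss_sd", "moca_sd", "followup_months_sd",
              "test_noise_sd"))
    chk(cfg[[p]] > 0, paste(p, "must be > 0"))
  chk(abs(sum(event_probs) - 1) < 1e-8 &&
        setequal(names(event_probs), c("TIA", "ischemic", "hemorrhagic")),
      "event_probs must be named TIA/ischemic/hemorrhagic and sum to 1")
  chk(psci_or_per_point_lost > 0, "psci_or_per_point_lost must be > 0")
  chk(ability_age_loading^2 + ability_edu_loading^2 < 1,
      "ability loadings: squared sum must be < 1")
  chk(n_tests >= 1, "n_tests must be >= 1")
  chk(age_range[1] < age_range[2] && age_range[1] > 18, "age_range invalid")
  if (length(problems)) stop("invalid config: ", paste(problems, collapse = "; "))
  cfg$seed <- as.integer(seed)
  cfg$rng <- list(algorithm = "Mersenne-Twister", package_rng_version = 1L)
  class(cfg) <- "sim_config"
  cfg
}

# truncated-normal draws by rejection sampling (mean may be a vector)
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  mean <- rep_len(mean, n)
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean[bad], sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

# bisection on the intercept c so that mean(plogis(c + eta)) = target
calibrate_intercept <- function(eta, target, tol = 1e-4) {
  f <- function(c) mean(stats::plogis(c + eta)) - target
  lo <- -50; hi <- 50
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol * 1e-2) break
  }
  (lo + hi) / 2
}

#' Generate a synthetic baseline cohort
#'
#' Draws `config$n` patient records (demographics, event type, NIHSS, raw
#' MoCA) plus the per-patient latent truth. Raw MoCA is drawn, conditionally
#' on age and education through the latent ability, from a truncated normal
#' on \[0, 30\] and rounded to an integer. Uses the current RNG state; for a
#' fully seeded run use [simulate_cohort()].
#'
#' @param config A [sim_config()] object.
#' @return List with `records` (data frame of patient records: `id`, `age`,
#'   `education_years`, `sex`, `event_type`, `nihss`, `moca_raw`, `centre`)
#'   and `truth` (data frame: `id`, `ability`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n
  age <- rtrunc_norm(n, config$age_mean, config$age_sd,
                     config$age_range[1], config$age_range[2])
  edu <- round(rtrunc_norm(n, config$edu_mean, config$edu_sd,
                           config$edu_range[1], config$edu_range[2]))
  z_age <- (age - config$age_mean) / config$age_sd
  z_edu <- (edu - config$edu_mean) / config$edu_sd
  la <- config$ability_age_loading; le <- config$ability_edu_loading
  resid_sd <- sqrt(1 - la^2 - le^2)

  # raw MoCA | demographics: truncated normal around the ability-implied mean
  mu_moca <- config$moca_mean + config$moca_sd * (la * z_age + le * z_edu)
  moca_cont <- rtrunc_norm(n, mu_moca, config$moca_sd * resid_sd, 0, 30)
  moca_raw <- as.integer(round(moca_cont))
  ability <- (moca_cont - config$moca_mean) / config$moca_sd

  records <- data.frame(
    id = sprintf("P%04d", seq_len(n)),
    age = age,
    education_years = as.numeric(edu),
    sex = factor(ifelse(stats::runif(n) < config$p_female, "female", "male"),
                 levels = c("female", "male")),
    event_type = factor(sample(names(config$event_probs), n, replace = TRUE,
                               prob = config$event_probs),
                        levels = c("TIA", "ischemic", "hemorrhagic")),
    nihss = as.integer(round(rtrunc_norm(n, config$nihss_mean, config$nihss_sd, 0, 42))),
    moca_raw = moca_raw,
    centre = sample(c("A", "B"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  list(records = records, truth = data.frame(id = records$id, ability = ability))
}

#' Apply informative drop-out
#'
#' Retains each patient with probability from a logistic model in age and raw
#' MoCA, \code{logit P(followed) = c + a * (age - mean age) + m * (moca -
#' mean moca)}, with the intercept `c` calibrated by bisection on the
#' realized cohort so the expected follow-up fraction equals
#' `config$followup_rate`. With the default negative age and positive MoCA
#' effects, drop-outs are older and have lower baseline MoCA. Retained
#' patients receive a follow-up interval draw.
#'
#' @param records Baseline records from [generate_cohort()].
#' @param config A [sim_config()] object.
#' @return `records` with added columns `followed_up` (logical),
#'   `follow_up_months` (NA for drop-outs) and attribute
#'   `"p_followup"` (the per-patient retention probabilities).
#' @export
apply_dropout <- function(records, config) {
  stopifnot(inherits(config, "sim_config"), nrow(records) > 0)
  eta <- config$dropout_age_effect * (records$age - mean(records$age)) +
    config$dropout_moca_effect * (records$moca_raw - mean(records$moca_raw))
  alpha <- calibrate_intercept(eta, config$followup_rate)
  p <- stats::plogis(alpha + eta)
  followed <- stats::runif(nrow(records)) < p
  records$followed_up <- followed
  records$follow_up_months <- NA_real_
  records$follow_up_months[followed] <-
    rtrunc_norm(sum(followed), config$followup_months_mean,
                config$followup_months_sd, 3, 15)
  attr(records, "p_followup") <- p
  records
}

#' Generate follow-up assessments with a known outcome model
#'
#' Draws PSCI status for each followed-up patient from
#' \code{logit P(PSCI) = alpha - log(psci_or_per_point_lost) * adjusted},
#' where `adjusted` is the Aiello-adjusted baseline MoCA and `alpha` is
#' calibrated by bisection so the expected prevalence among the followed-up
#' equals `config$psci_prevalence`. Per-test impairment flags are thresholded
#' noisy copies of the latent ability, then coerced consistent with the drawn
#' status (a PSCI patient always has at least one impaired test; a non-PSCI
#' patient has none), so that outcome adjudication round-trips the generated
#' labels exactly. Functional dependence is drawn so that P(dementia | PSCI)
#' equals `config$p_dementia_given_psci`, with a share of MCI patients
#' carrying dependence marked as motor/sensory (which adjudication must not
#' count as dementia).
#'
#' @param records Records from [apply_dropout()] (uses the followed-up subset).
#' @param truth Truth data frame from [generate_cohort()].
#' @param config A [sim_config()] object.
#' @return List with `tests` (long data frame: `patient_id`, `test_name`,
#'   `domain`, `impaired`), `functional` (per-patient: `patient_id`,
#'   `adl_dependent`, `iadl_dependent`, `mrs`,
#'   `functional_loss_noncognitive`) and `truth` (per followed patient:
#'   `patient_id`, `psci`, `category`, `p_psci`, `adjusted_aiello`).
#' @export
generate_followup <- function(records, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  fu <- records[records$followed_up, , drop = FALSE]
  if (nrow(fu) == 0) stop("no followed-up patients")
  adj <- adjust_cohort(fu, "aiello")$value
  beta <- -log(config$psci_or_per_point_lost)
  alpha <- calibrate_intercept(beta * adj, config$psci_prevalence)
  p_psci <- stats::plogis(alpha + beta * adj)
  psci <- stats::runif(nrow(fu)) < p_psci

  ability <- truth$ability[match(fu$id, truth$id)]
  domains <- rep_len(c("memory", "attention_executive", "language", "visuospatial"),
                     config$n_tests)
  # latent per-test scores; the noisiest-low test is forced impaired for PSCI
  test_scores <- matrix(ability, nrow(fu), config$n_tests) +
    matrix(stats::rnorm(nrow(fu) * config$n_tests, 0, config$test_noise_sd),
           nrow(fu), config$n_tests)
  thr <- stats::quantile(ability, config$psci_prevalence / 2)
  imp <- test_scores < thr
  imp[!psci, ] <- FALSE
  none_flagged <- psci & rowSums(imp) == 0
  if (any(none_flagged)) {
    worst <- apply(test_scores[none_flagged, , drop = FALSE], 1, which.min)
    imp[cbind(which(none_flagged), worst)] <- TRUE
  }

  dementia <- psci & stats::runif(nrow(fu)) < config$p_dementia_given_psci
  noncog <- !dementia & stats::runif(nrow(fu)) < config$p_noncognitive_dependence
  functional <- data.frame(
    patient_id = fu$id,
    adl_dependent = dementia | (noncog & stats::runif(nrow(fu)) < 0.5),
    iadl_dependent = dementia | noncog,
    mrs = pmin(6L, pmax(0L, as.integer(round(fu$nihss / 3 +
             stats::rnorm(nrow(fu), 0, 0.8))))),
    functional_loss_noncognitive = noncog,
    stringsAsFactors = FALSE
  )

  tests <- data.frame(
    patient_id = rep(fu$id, each = config$n_tests),
    test_name = rep(sprintf("test_%02d", seq_len(config$n_tests)), nrow(fu)),
    domain = rep(domains, nrow(fu)),
    impaired = as.logical(t(imp)),
    stringsAsFactors = FALSE
  )

  category <- ifelse(!psci, "none", ifelse(dementia, "dementia", "mci"))
  list(tests = tests, functional = functional,
       truth = data.frame(patient_id = fu$id, psci = psci,
                          category = factor(category, c("none", "mci", "dementia")),
                          p_psci = p_psci, adjusted_aiello = adj,
                          stringsAsFactors = FALSE))
}

#' Simulate a full synthetic stroke cohort
#'
#' Seeded end-to-end generation: baseline cohort, informative drop-out, and
#' follow-up assessments with a known PSCI outcome model. Identical seed and
#' config give bit-identical output (RNG algorithm pinned in the config).
#'
#' @param config A [sim_config()] object (carries the seed).
#' @return Object of class `"psci_sim"`: list with `baseline` (records
#'   including follow-up columns), `tests`, `functional`, `truth` (baseline
#'   ability joined with follow-up truth where available), and `config`.
#' @examples
#' sim <- simulate_cohort(sim_config(seed = 42, n = 60))
#' table(sim$truth$category)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed, kind = config$rng$algorithm)

  base <- generate_cohort(config)
  records <- apply_dropout(base$records, config)
  fu <- generate_followup(records, base$truth, config)

  truth <- merge(base$truth, fu$truth, by.x = "id", by.y = "patient_id",
                 all.x = TRUE, sort = FALSE)
  truth <- truth[match(base$truth$id, truth$id), ]
  rownames(truth) <- NULL
  structure(list(baseline = records, tests = fu$tests,
                 functional = fu$functional, truth = truth, config = config),
            class = "psci_sim")
}

#' @export
print.psci_sim <- function(x, ...) {
  n_fu <- sum(x$baseline$followed_up)
  cat(sprintf("Synthetic stroke cohort: n = %d, followed-up = %d (%.0f%%), seed = %d\n",
              nrow(x$baseline), n_fu, 100 * n_fu / nrow(x$baseline),
              x$config$seed))
  if (n_fu)
    cat(sprintf("  PSCI among followed-up: %d (%.0f%%)\n",
                sum(x$truth$psci, na.rm = TRUE),
                100 * mean(x$truth$psci, na.rm = TRUE)))
  invisible(x)
}
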
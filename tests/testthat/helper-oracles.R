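# Independent one-line evaluations of the three published adjustment
# equations, used as oracles against the package's table-driven path.
oracle_conti <- function(raw, age, edu)
  raw + 0.175 * (age - 70.08) + 24.3 * (1 / edu - 0.126)
oracle_santangelo <- function(raw, age, edu)
  raw - 4.228 * (log10(100 - age) - 1.58) - 3.201 * (sqrt(edu) - 3.25)
oracle_aiello <- function(raw, age, edu)
  raw + 0.000008 * (age^3 - 297697.184801) - 3.331407 * (log(edu) - 2.325648)

# all-pairs Mann-Whitney concordance: P(score_case < score_control) + 1/2 ties
oracle_concordance_auc <- function(scores, psci) {
  cases <- scores[psci]; controls <- scores[!psci]
  g <- expand.grid(case = cases, control = controls)
  mean((g$case < g$control) + 0.5 * (g$case == g$control))
}

# textbook Pearson chi-square from expected counts
oracle_chi2 <- function(tp, fp, fn, tn) {
  o <- matrix(c(tp, fp, fn, tn), 2, 2, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  sum((o - e)^2 / e)
}

# zooming grid-search maximizer of the Bernoulli log-likelihood; the grid is
# laid over (a, b) with x centred so the two axes are near-orthogonal
oracle_logit_grid <- function(x, y, rounds = 10, width_a = 10, width_b = 5) {
  xm <- mean(x); xc <- x - xm
  loglik <- function(a, b) {
    p <- plogis(a + b * xc)
    sum(y * log(p) + (1 - y) * log(1 - p))
  }
  a0 <- 0; b0 <- 0
  for (r in seq_len(rounds)) {
    as <- seq(a0 - width_a, a0 + width_a, length.out = 41)
    bs <- seq(b0 - width_b, b0 + width_b, length.out = 41)
    ll <- outer(as, bs, Vectorize(loglik))
    best <- arrayInd(which.max(ll), dim(ll))
    a0 <- as[best[1]]; b0 <- bs[best[2]]
    width_a <- width_a / 3; width_b <- width_b / 3
  }
  c(intercept = a0 - b0 * xm, coefficient = b0)
}

# brute-force Se/Sp recount at one threshold under "positive iff score < t"
oracle_se_sp <- function(scores, psci, t) {
  pos <- scores < t
  c(se = sum(pos & psci) / sum(psci), sp = sum(!pos & !psci) / sum(!psci))
}

# small deterministic baseline cohort data frame
make_baseline <- function(n = 6, moca = NULL, age = NULL, edu = NULL,
                          followed = TRUE) {
  data.frame(
    id = sprintf("S%02d", seq_len(n)),
    age = if (is.null(age)) seq(60, 90, length.out = n) else rep_len(age, n),
    education_years = if (is.null(edu)) rep_len(c(5, 8, 13), n) else rep_len(edu, n),
    sex = rep_len(c("female", "male"), n),
    event_type = rep_len(c("ischemic", "hemorrhagic", "TIA"), n),
    nihss = rep_len(0:4, n),
    moca_raw = if (is.null(moca)) rep_len(c(10, 14, 18, 22, 26, 28), n) else rep_len(moca, n),
    followed_up = rep_len(followed, n),
    follow_up_months = ifelse(rep_len(followed, n), 7, NA_real_),
    stringsAsFactors = FALSE
  )
}

# follow-up fixtures for one patient id
make_tests <- function(id, impaired) {
  data.frame(patient_id = id,
             test_name = sprintf("t%02d", seq_along(impaired)),
             domain = rep_len(c("memory", "attention_executive", "language",
                                "visuospatial"), length(impaired)),
             impaired = impaired, stringsAsFactors = FALSE)
}
make_functional <- function(id, adl = FALSE, iadl = FALSE, noncog = FALSE, mrs = 1) {
  data.frame(patient_id = id, adl_dependent = adl, iadl_dependent = iadl,
             mrs = mrs, functional_loss_noncognitive = noncog,
             stringsAsFactors = FALSE)
}
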
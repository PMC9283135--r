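test_that("contingency builder partitions n and matches hand counts", {
  perf <- c("impaired", "normal", "impaired", "normal")
  psci <- c(TRUE, TRUE, FALSE, FALSE)
  tab <- contingency_2x2(perf, psci)
  expect_equal(unlist(tab[c("tp", "fp", "fn", "tn")]),
               c(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  expect_equal(tab$n, 4L)

  all_imp <- contingency_2x2(rep("impaired", 5), rep(TRUE, 5))
  expect_equal(all_imp$tp, 5L)
  expect_equal(all_imp$fp + all_imp$fn + all_imp$tn, 0L)

  expect_error(contingency_2x2("impaired", c(TRUE, FALSE)), "mismatch")
  set.seed(3)
  perf <- sample(c("impaired", "normal"), 60, replace = TRUE)
  psci <- runif(60) < 0.5
  tab <- contingency_2x2(perf, psci)
  expect_equal(tab$tp + tab$fp + tab$fn + tab$tn, 60L)
})

test_that("accuracy indices reproduce the published normative-threshold cells", {
  # printed 2x2 tables of baseline performance vs PSCI in the source cohort
  rows <- list(
    aiello     = list(cnt = c(tp = 36, fp = 2, fn = 41, tn = 39), pct = c(47, 95, 95, 49)),
    conti      = list(cnt = c(tp = 31, fp = 2, fn = 46, tn = 39), pct = c(40, 95, 94, 46)),
    santangelo = list(cnt = c(tp = 27, fp = 1, fn = 50, tn = 40), pct = c(35, 98, 96, 44))
  )
  for (nm in names(rows)) {
    cnt <- rows[[nm]]$cnt
    idx <- accuracy_indices(contingency_counts(cnt["tp"], cnt["fp"], cnt["fn"], cnt["tn"]))
    expect_equal(unname(idx$pct), rows[[nm]]$pct, label = nm)
    # and the exact ratios behind them
    expect_equal(idx$sensitivity, cnt[["tp"]] / (cnt[["tp"]] + cnt[["fn"]]))
    expect_equal(idx$specificity, cnt[["tn"]] / (cnt[["tn"]] + cnt[["fp"]]))
  }
})

test_that("zero denominators give undefined indices, not 0 or 1", {
  idx <- accuracy_indices(contingency_counts(0, 0, 0, 5))
  expect_true(is.na(idx$sensitivity))
  expect_true(is.na(idx$ppv))
  expect_equal(idx$specificity, 1)
  expect_equal(idx$npv, 1)
})

test_that("index identities: label exchange and Bayes prevalence", {
  set.seed(9)
  for (i in 1:25) {
    cnt <- as.integer(rmultinom(1, 120, runif(4, 0.05, 1)))
    tab <- contingency_counts(cnt[1], cnt[2], cnt[3], cnt[4])
    idx <- accuracy_indices(tab)
    # relabelling both the test-positive and reference-positive classes
    sw <- accuracy_indices(contingency_counts(cnt[4], cnt[3], cnt[2], cnt[1]))
    expect_equal(sw$sensitivity, idx$specificity)
    expect_equal(sw$specificity, idx$sensitivity)
    expect_equal(sw$ppv, idx$npv)
    expect_equal(sw$npv, idx$ppv)
    # PPV/NPV from (Se, Sp, prevalence) via Bayes equal the direct ratios
    prev <- (tab$tp + tab$fn) / tab$n
    se <- idx$sensitivity; sp <- idx$specificity
    if (!anyNA(c(se, sp, idx$ppv, idx$npv))) {
      expect_equal(idx$ppv, se * prev / (se * prev + (1 - sp) * (1 - prev)))
      expect_equal(idx$npv, sp * (1 - prev) / (sp * (1 - prev) + (1 - se) * prev))
    }
    expect_true(all(unlist(idx[1:4]) >= 0 & unlist(idx[1:4]) <= 1, na.rm = TRUE))
  }
})

test_that("chi-square matches the textbook formula and degenerate cases", {
  same <- chi2_test(contingency_counts(5, 5, 5, 5))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  a <- chi2_test(contingency_counts(36, 2, 41, 39))
  expect_lt(a$p_value, 0.001)

  set.seed(21)
  for (i in 1:30) {
    cnt <- as.integer(rmultinom(1, 150, runif(4, 0.1, 1)))
    got <- chi2_test(contingency_counts(cnt[1], cnt[2], cnt[3], cnt[4]))
    expect_equal(got$statistic, oracle_chi2(cnt[1], cnt[2], cnt[3], cnt[4]),
                 tolerance = 1e-10)
    expect_equal(got$p_value, pchisq(got$statistic, 1, lower.tail = FALSE))
  }
  expect_error(chi2_test(contingency_counts(0, 0, 10, 10)), "marginal")
})

test_that("percent rendering is half-up at the requested precision", {
  expect_equal(proportion_pct(118, 207), 57)
  expect_equal(proportion_pct(77, 118), 65)
  expect_equal(proportion_pct(85, 207), 41)
  expect_equal(proportion_pct(59, 207, 1), 28.5)
  expect_equal(proportion_pct(0, 50), 0)
  # half-up, not banker's: 46.75 -> 47 at 0 decimals, 0.125 -> 0.13
  expect_equal(round_half_up(46.75), 47)
  expect_equal(round_half_up(97.56), 98)
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(-2.5), -3)
  expect_error(proportion_pct(1, 0), "total")
  expect_error(proportion_pct(5, 4), "count")
  expect_equal(format_pvalue(c(0.0004, 0.031)), c("<0.001", "0.031"))
})

test_that("logistic risk fit maximizes the likelihood (grid-search oracle)", {
  # tiny hand dataset
  x <- c(22, 25, 18, 15, 20, 27, 16, 24, 14, 26, 19, 23)
  y <- c(1, 0, 1, 1, 0, 0, 1, 0, 1, 0, 1, 0)
  fit <- fit_psci_logit(x, y)
  oracle <- oracle_logit_grid(x, y)
  expect_equal(fit$coefficient, unname(oracle["coefficient"]), tolerance = 1e-4)
  expect_equal(fit$intercept, unname(oracle["intercept"]), tolerance = 1e-3)
  expect_equal(fit$or_per_point_lost, exp(-fit$coefficient))
  expect_true(fit$converged)
  expect_true(fit$ci95[1] <= fit$or_per_point_lost &&
                fit$or_per_point_lost <= fit$ci95[2])
})

test_that("null association gives OR near 1 with covering CI", {
  set.seed(33)
  x <- rnorm(2000, 20, 5)
  y <- runif(2000) < 0.5
  fit <- fit_psci_logit(x, y)
  expect_equal(fit$or_per_point_lost, 1, tolerance = 0.05)
  expect_true(fit$ci95[1] < 1 && 1 < fit$ci95[2])
})

test_that("shifting all scores changes the intercept but not the OR", {
  set.seed(41)
  x <- rnorm(300, 20, 5)
  y <- runif(300) < plogis(6 - 0.3 * x)
  f1 <- fit_psci_logit(x, y)
  f2 <- fit_psci_logit(x + 10, y)
  expect_equal(f2$or_per_point_lost, f1$or_per_point_lost, tolerance = 1e-6)
  expect_equal(f2$intercept, f1$intercept - 10 * f1$coefficient, tolerance = 1e-4)
})

test_that("separation and degenerate inputs are reported, not silently fit", {
  x <- c(1:10, 21:30)
  y <- rep(c(TRUE, FALSE), each = 10)
  fit <- fit_psci_logit(x, y)
  expect_false(fit$converged)
  expect_match(fit$message, "separation")
  expect_error(fit_psci_logit(1:20, rep(TRUE, 20)), "classes")
  expect_error(fit_psci_logit(1:5, c(TRUE, FALSE, TRUE, FALSE, TRUE)), "n >= 10")
})

test_that("group comparison handles numeric and categorical variables", {
  g <- rep(c("a", "b"), each = 20)
  x <- rep(c(1, 2, 3, 4), 10)
  same <- compare_groups(x, g)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)
  expect_match(same$test, "pooled")

  bin <- compare_groups(factor(rep(c("f", "m"), 20)), g, type = "categorical")
  expect_equal(bin$p_value, 1, tolerance = 1e-12)

  # detects the direction of a generated age gap between groups
  set.seed(55)
  age <- c(rnorm(120, 74.7, 9), rnorm(90, 77.7, 10))
  grp <- rep(c("followed", "dropout"), c(120, 90))
  cmp <- compare_groups(age, grp)
  expect_gt(cmp$summary$dropout$mean, cmp$summary$followed$mean)

  # worked example against the hand-written pooled-t formula
  x1 <- c(19.8, 20.4, 19.6, 17.8, 18.5, 18.9, 18.3, 18.9, 19.5, 22.0)
  x2 <- c(28.2, 26.6, 20.1, 23.3, 25.2, 22.1, 17.7, 27.6, 20.6, 13.7,
          23.2, 17.5, 20.6, 18.0, 23.9, 21.6, 24.3, 20.4, 23.9, 13.3)
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2)
  t_hand <- (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p_hand <- 2 * pt(-abs(t_hand), n1 + n2 - 2)
  cmp2 <- compare_groups(c(x1, x2), rep(c("g1", "g2"), c(10, 20)))
  expect_equal(cmp2$statistic, t_hand, tolerance = 1e-10)
  expect_equal(cmp2$p_value, p_hand, tolerance = 1e-10)

  expect_error(compare_groups(rep(1, 10), rep(c("a", "b"), 5)), "inestimable")
})
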
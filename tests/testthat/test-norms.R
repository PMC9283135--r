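test_that("normative constants load from the shipped JSON resource", {
  norms <- moca_norms()
  expect_setequal(names(norms), c("conti", "santangelo", "aiello"))
  expect_equal(moca_norm("aiello")$es0_cutoff, 18.58)
  expect_equal(moca_norm("conti")$es0_cutoff, 17.36)
  expect_equal(moca_norm("santangelo")$es0_cutoff, 15.50)
  expect_equal(moca_norm("conti")$age_range, c(60, 80))
})

test_that("adjustment matches the published equations (independent oracles)", {
  # frozen spot checks (raw 20, age 80, 5 years of education)
  expect_equal(adjust_moca(20, 80, 5, "conti")$value, oracle_conti(20, 80, 5),
               tolerance = 1e-12)
  expect_equal(round(adjust_moca(20, 80, 5, "conti")$value, 2), 23.53)
  expect_equal(round(adjust_moca(20, 80, 5, "santangelo")$value, 2), 24.43)
  expect_equal(round(adjust_moca(20, 80, 5, "aiello")$value, 2), 24.10)

  # oracle equivalence on 10^4 random inputs per dataset
  set.seed(101)
  n <- 1e4
  raw <- sample(0:30, n, replace = TRUE)
  age <- runif(n, 19, 99)
  edu <- sample(1:21, n, replace = TRUE)
  expect_equal(adjust_moca(raw, age, edu, "conti")$value,
               oracle_conti(raw, age, edu), tolerance = 1e-12)
  expect_equal(adjust_moca(raw, age, edu, "santangelo")$value,
               oracle_santangelo(raw, age, edu), tolerance = 1e-12)
  expect_equal(adjust_moca(raw, age, edu, "aiello")$value,
               oracle_aiello(raw, age, edu), tolerance = 1e-12)
})

test_that("each equation returns the raw score at its centering demographics", {
  centers <- list(
    conti      = c(age = 70.08, edu = 1 / 0.126),
    santangelo = c(age = 100 - 10^1.58, edu = 3.25^2),
    aiello     = c(age = 297697.184801^(1 / 3), edu = exp(2.325648))
  )
  for (nm in names(centers)) {
    for (raw in c(0L, 17L, 30L)) {
      a <- adjust_moca(raw, centers[[nm]][["age"]], centers[[nm]][["edu"]], nm)
      expect_equal(a$value, raw, tolerance = 1e-9,
                   label = sprintf("%s fixed point at raw %d", nm, raw))
    }
  }
})

test_that("adjusted value increases with age and decreases with education", {
  set.seed(7)
  for (nm in c("conti", "santangelo", "aiello")) {
    ages <- sort(runif(25, 19, 99))
    edus <- sort(runif(25, 1, 21))
    v_age <- adjust_moca(15, ages, 10, nm)$value
    v_edu <- adjust_moca(15, 70, edus, nm)$value
    expect_true(all(diff(v_age) > 0), label = paste(nm, "increasing in age"))
    expect_true(all(diff(v_edu) < 0), label = paste(nm, "decreasing in education"))
  }
})

test_that("impaired/normal classification is strict at the cut-off", {
  expect_equal(as.character(classify_moca(18.00, "aiello")), "impaired")
  expect_equal(as.character(classify_moca(18.58, "aiello")), "normal")
  expect_equal(as.character(classify_moca(15.49, "santangelo")), "impaired")
  expect_equal(as.character(classify_moca(15.50, "santangelo")), "normal")
  expect_equal(as.character(classify_moca(17.36 - 1e-9, "conti")), "impaired")
})

test_that("degenerate demographics are clamped and flagged, never rejected", {
  # education 0: reciprocal and log terms undefined -> clamped to 1 year
  expect_warning(adjust_moca(20, 75, 0, "conti"), "clamped")
  a <- suppressWarnings(adjust_moca(20, 75, 0, "conti"))
  expect_true(a$clamped_inputs)
  expect_equal(a$value, oracle_conti(20, 75, 1), tolerance = 1e-12)
  b <- suppressWarnings(adjust_moca(20, 75, 0, "aiello"))
  expect_equal(b$value, oracle_aiello(20, 75, 1), tolerance = 1e-12)
  # age >= 100: Santangelo's log10(100 - age) undefined -> clamped to 99
  expect_warning(adjust_moca(20, 101, 8, "santangelo"), "clamped")
  s <- suppressWarnings(adjust_moca(20, 101, 8, "santangelo"))
  expect_true(s$clamped_inputs)
  expect_equal(s$value, oracle_santangelo(20, 99, 8), tolerance = 1e-12)
  expect_true(is.finite(s$value))
  # outside the normative age range: evaluated but flagged extrapolated
  e <- adjust_moca(20, 45, 8, "conti")
  expect_true(e$extrapolated)
  expect_false(e$clamped_inputs)
  expect_false(adjust_moca(20, 70, 8, "conti")$extrapolated)
})

test_that("invalid raw scores are rejected; missing raw is its own signal", {
  expect_error(adjust_moca(31, 70, 8, "conti"), "\\[0, 30\\]")
  expect_error(adjust_moca(-1, 70, 8, "conti"), "\\[0, 30\\]")
  expect_error(adjust_moca(17.5, 70, 8, "conti"), "\\[0, 30\\]")
  expect_error(adjust_moca(NA, 70, 8, "conti"), "unavailable")
  expect_error(adjust_moca(20, 18, 8, "conti"), "age")
})

test_that("adjust_cohort skips missing scores, preserves order, is deterministic", {
  rec <- make_baseline(3)
  rec$moca_raw[2] <- NA
  expect_message(adj <- adjust_cohort(rec, "aiello"), "1 record")
  expect_equal(nrow(adj), 2)
  expect_equal(adj$id, rec$id[c(1, 3)])
  expect_equal(attr(adj, "n_skipped"), 1)

  rec2 <- make_baseline(10, moca = 20, age = 70, edu = 8)
  adj2 <- adjust_cohort(rec2, "conti")
  expect_equal(nrow(adj2), 10)
  expect_true(all(adj2$value == adj2$value[1]))
  expect_identical(adj2, adjust_cohort(rec2, "conti"))
  expect_error(adjust_cohort(rec2[0, ], "conti"), "empty")
})

test_that("impairment rate is the impaired fraction with half-up percent", {
  mk <- function(k, n, norm = "aiello") {
    cut <- moca_norm(norm)$es0_cutoff
    v <- c(rep(cut - 1, k), rep(cut + 1, n - k))
    structure(data.frame(value = v, performance = classify_moca(v, norm)),
              norm = norm, class = c("moca_adjusted", "data.frame"))
  }
  expect_equal(impairment_rate(mk(85, 207))$pct, 41)
  expect_equal(impairment_rate(mk(59, 207), decimals = 1)$pct, 28.5)
  expect_equal(impairment_rate(mk(75, 207))$pct, 36)
  expect_equal(impairment_rate(mk(0, 50))$pct, 0)
  expect_equal(impairment_rate(mk(85, 207))$rate, 85 / 207)
  expect_error(impairment_rate(list(mk(1, 2), mk(1, 2, "conti"))), "mix")
})
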
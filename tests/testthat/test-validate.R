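test_that("expected counts under consensus scores match the closed form", {
  exp <- expected_counts(
    tibble::tibble(fm_id = "FM36_dose_calc", o = 5.7, d = 4.7),
    n_plans = dose_calc_plans
  )
  # p_occ = 0.0041, p_undet = 0.017, ce = 1 - sqrt(0.017)
  expect_equal(exp$p_occ, 0.0041)
  expect_equal(exp$p_undetected, 0.017)
  expect_equal(exp$ce, 1 - sqrt(0.017))
  expect_equal(exp$expected_n2, 1.096174, tolerance = 1e-6)
  # the first-check expectation computes to ~8.4 under linear interpolation
  expect_equal(exp$expected_n1, 8.407273, tolerance = 1e-6)
  expect_error(expected_counts(tibble::tibble(fm_id = "x", o = 12, d = 4),
                               n_plans = 100),
               "1, 10")
})

test_that("expected counts back-compose through the estimator", {
  # feeding consensus-implied expected counts into the count estimator
  # must recover the consensus-implied CE and N0 exactly
  grid <- tidyr::expand_grid(o = c(3, 5.7, 7.2), d = c(2.5, 4.7, 6))
  for (i in seq_len(nrow(grid))) {
    exp <- expected_counts(
      tibble::tibble(fm_id = "x", o = grid$o[i], d = grid$d[i]),
      n_plans = 10000
    )
    ce_back <- 1 - exp$expected_n2 / exp$expected_n1
    n0_back <- exp$expected_n1^2 / (exp$expected_n1 - exp$expected_n2)
    expect_equal(ce_back, exp$ce, tolerance = 1e-9)
    expect_equal(n0_back, exp$n0, tolerance = 1e-9)
  }
})

test_that("tail probability flags implausible consensus scores", {
  tp <- tail_probability(o = 4.4, d = 4.7, n1 = 8, n2 = 2,
                         n_plans = dose_calc_plans, n_reps = 1e5, seed = 7)
  expect_lt(tp, 0.05)
  # exact binomial oracle: total catches ~ Binomial(plans, p_occ * p_catch);
  # the two-sided distance region reduces to the upper tail here
  p_eff <- 0.0014 * (1 - 0.017)
  exact <- stats::pbinom(9, dose_calc_plans, p_eff, lower.tail = FALSE)
  expect_equal(tp, exact, tolerance = 0.003)
  # identical seeds are bit-reproducible; an observation sitting exactly at
  # its expectation can never be extreme
  expect_identical(tp, tail_probability(4.4, 4.7, 8, 2, dose_calc_plans,
                                        n_reps = 1e5, seed = 7))
  fit <- estimate_risk(dose_calc_counts(), n_plans = dose_calc_plans)
  tp_self <- tail_probability(fit$o_continuous, fit$d_continuous, 8, 2,
                              dose_calc_plans, n_reps = 1e4, seed = 7)
  expect_equal(tp_self, 1)
})

test_that("tail probability agrees with exhaustive enumeration on a toy clinic", {
  # 20 plans, occurrence score 9 (5%), detectability score 8 (15% undetected)
  p_eff <- 0.05 * 0.85
  expected <- 20 * p_eff
  observed <- 3  # |3 - 0.85| >= 2.15 only in the upper tail
  exact <- sum(stats::dbinom(0:20, 20, p_eff)[abs(0:20 - expected) >=
                                                abs(observed - expected)])
  mc <- tail_probability(o = 9, d = 8, n1 = 3, n2 = 0, n_plans = 20,
                         n_reps = 2e5, seed = 11)
  expect_equal(mc, exact, tolerance = 0.01)
})

test_that("occurrence ratio measures fold-difference against consensus O", {
  r <- occurrence_ratio(o = 4.4, n1 = 8, n2 = 2, n_plans = dose_calc_plans)
  expect_equal(r, (64 / 6) / (0.0014 * 2358))
  expect_equal(round_half_away(r), 3)
  # score-1 consensus: 10.67 estimated vs 0.2358 implied
  expect_equal(occurrence_ratio(1, 8, 2, dose_calc_plans),
               (64 / 6) / (1e-4 * 2358))
  # consensus equal to the fitted continuous O gives ratio 1
  fit <- estimate_risk(dose_calc_counts(), n_plans = dose_calc_plans)
  expect_equal(occurrence_ratio(fit$o_continuous, 8, 2, dose_calc_plans), 1,
               tolerance = 1e-9)
  # invariant under proportional scaling of counts and plans
  expect_equal(occurrence_ratio(4.4, 80, 20, 23580),
               occurrence_ratio(4.4, 8, 2, 2358))
})

test_that("bootstrap intervals contain the point estimate and tighten with data", {
  small <- bootstrap_intervals(8, 2, 2358, n_boot = 1000, seed = 3)
  ints <- tidy(small)
  expect_true(all(ints$lower <= ints$estimate & ints$estimate <= ints$upper))
  expect_identical(glance(small)$n_boot, 1000)
  big <- bootstrap_intervals(800, 200, 235800, n_boot = 1000, seed = 3)
  w <- function(b, q) {
    r <- b$intervals[b$intervals$quantity == q, ]
    r$upper - r$lower
  }
  expect_lt(w(big, "ce"), w(small, "ce"))
  expect_false(big$indeterminate)
  # identical seed reproduces, breakdown replicates are counted
  again <- bootstrap_intervals(8, 2, 2358, n_boot = 1000, seed = 3)
  expect_identical(tidy(small), tidy(again))
  expect_gte(small$n_breakdown, 0)
  expect_error(bootstrap_intervals(2, 2, 100), "not estimable")
})

test_that("consensus validation issues verdicts per failure mode", {
  counts <- dose_calc_counts()
  fit <- estimate_risk(counts, n_plans = dose_calc_plans)
  consensus <- tibble::tibble(
    fm_id = c("FM36_dose_calc", "self"),
    o = c(4.4, fit$o_continuous), d = c(4.7, fit$d_continuous)
  )
  counts2 <- dplyr::bind_rows(counts,
                              tibble::tibble(fm_id = "self", n1 = 8L, n2 = 2L))
  rep <- validate_consensus(counts2, consensus, n_plans = dose_calc_plans,
                            n_reps = 2e4, n_boot = 500, seed = 5)
  expect_s3_class(rep, "validation_report")
  expect_equal(nrow(rep), 2)
  expect_equal(rep$verdict[rep$fm_id == "FM36_dose_calc"], "inconsistent")
  expect_equal(rep$verdict[rep$fm_id == "self"], "consistent")
  expect_true(all(rep$tail_prob >= 0 & rep$tail_prob <= 1))
  expect_true(all(rep$ce_lower <= 0.75 & 0.75 <= rep$ce_upper))
  g <- glance(rep)
  expect_equal(g$n_inconsistent, 1)
  # a broken-down FM gets an indeterminate verdict, not an error
  rep2 <- validate_consensus(tibble::tibble(fm_id = "x", n1 = 2L, n2 = 3L),
                             tibble::tibble(fm_id = "x", o = 4, d = 4),
                             n_plans = 100, n_reps = 1000, seed = 5)
  expect_equal(rep2$verdict, "indeterminate")
})
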
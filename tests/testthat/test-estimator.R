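test_that("check efficacy and total occurrences match the closed forms", {
  expect_equal(check_efficacy(8, 2), 0.75)
  expect_equal(check_efficacy(10, 5), 0.5)
  expect_equal(check_efficacy(7, 0), 1)  # nothing left for the second check

  occ <- total_occurrences(8, 2)
  expect_equal(occ$n0_continuous, 64 / 6)
  expect_equal(occ$n0, 11)
  expect_equal(occ$undetected_count, 4 / 6)  # about one escaped both checks
  expect_equal(total_occurrences(5, 0)$n0_continuous, 5)  # all caught first time

  expect_equal(occurrence_fraction(8, 2, dose_calc_plans), (64 / 6) / 2358)
  expect_equal(occurrence_fraction(5, 0, 5), 1)
  expect_error(check_efficacy(3.5, 1), "integer counts")
})

test_that("undetected probability decays with added check layers", {
  expect_equal(undetected_probability(0.75, 2), 0.0625)
  expect_equal(undetected_probability(0.84, 1), 0.16)
  expect_equal(undetected_probability(0.84, 3), 0.16^3)
  expect_equal(undetected_probability(1, 5), 0)
  up <- undetected_probability(0.6, 1:6)
  expect_true(all(diff(up) < 0))
  expect_error(undetected_probability(1.2, 2), "0, 1")
})

test_that("conservation and back-substitution hold over all count pairs", {
  grid <- expand.grid(n1 = 1:50, n2 = 0:49)
  grid <- grid[grid$n2 < grid$n1, ]
  ce <- check_efficacy(grid$n1, grid$n2)
  occ <- total_occurrences(grid$n1, grid$n2)
  # N0 = N1 + N2 + undetected, exactly
  expect_equal(occ$n0_continuous, grid$n1 + grid$n2 + occ$undetected_count,
               tolerance = 1e-9)
  # the defining two-check system: N1 = N0*CE, N2 = (N0 - N1)*CE
  expect_equal(occ$n0_continuous * ce, grid$n1, tolerance = 1e-9)
  expect_equal((occ$n0_continuous - grid$n1) * ce, grid$n2, tolerance = 1e-9)
  # monotonicity at fixed n1: more second-check catches means lower
  # efficacy and more inferred occurrences
  n2 <- 0:19
  expect_true(all(diff(total_occurrences(rep(20, 20), n2)$n0_continuous) > 0))
  expect_true(all(diff(check_efficacy(rep(20, 20), n2)) < 0))
})

test_that("the dose-calculation worked example estimates end to end", {
  est <- estimate_risk(dose_calc_counts(), n_plans = dose_calc_plans)
  expect_equal(est$status, "ok")
  expect_equal(est$ce, 0.75)
  expect_equal(est$n0, 11)
  expect_equal(round_half_away(est$undetected_count), 1)
  expect_equal(round(100 * est$occurrence_fraction, 1), 0.5)
  expect_equal(est$undetected_prob, 0.0625)
  expect_equal(round(est$o_continuous, 1), 5.8)
  expect_equal(est$o_score, 6)
  expect_equal(est$d_score, 6)
  expect_s3_class(est, "risk_estimates")
})

test_that("breakdown and insufficient-data counts are flagged, not dropped", {
  est <- estimate_risk(
    tibble::tibble(fm_id = c("a", "b", "c", "d"),
                   n1 = c(8L, 0L, 3L, 4L), n2 = c(2L, 1L, 3L, 6L)),
    n_plans = 100
  )
  expect_equal(nrow(est), 4)
  expect_equal(est$status,
               c("ok", "insufficient_data", "breakdown", "breakdown"))
  expect_true(all(is.na(est$ce[2:4])))
  expect_false(anyNA(est$ce[1]))
})

test_that("single-layer detectability reduces to the direct lookup", {
  est <- estimate_risk(dose_calc_counts(), n_plans = dose_calc_plans,
                       n_layers = 1)
  expect_equal(est$d_continuous, prob_to_score(1 - est$ce, det_table))
})

test_that("RPN multiplies scores and both conventions are reported", {
  expect_equal(rpn(10, 2, 10), 200)
  expect_equal(rpn(5, 6.2, 6), 186)
  expect_equal(rpn(1, 1, 1), 1)
  expect_error(rpn(11, 1, 1), "1, 10")
  est <- estimate_risk(dose_calc_counts(), n_plans = dose_calc_plans,
                       severity = 3)
  expect_equal(est$rpn, est$o_score * 3 * est$d_score)
  expect_equal(est$rpn_continuous, est$o_continuous * 3 * est$d_continuous)
})

test_that("half-away rounding matches the reporting convention", {
  expect_equal(round_half_away(c(10.67, 10.5, 0.4, -2.5)), c(11, 11, 0, -3))
})

test_that("tidy and glance summarise a risk_estimates table", {
  est <- estimate_risk(
    tibble::tibble(fm_id = c("a", "b"), n1 = c(8L, 2L), n2 = c(2L, 2L)),
    n_plans = 2358
  )
  expect_false(inherits(tidy(est), "risk_estimates"))
  g <- glance(est)
  expect_equal(g$n_fm, 2)
  expect_equal(g$n_ok, 1)
  expect_equal(g$n_breakdown, 1)
})
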
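# Parameter derivation arithmetic: probability conversions, cost inflation,
# discount derivation, moment matching, life-table lookup, validation.

test_that("period-to-month conversion reproduces the published derivations", {
  # 2-month CV mortality 10/440 -> monthly 0.0114
  expect_equal(round(monthly_prob_from_period(10, 440, 2), 4), 0.0114)
  # 27-month CV mortality 558/4187 -> monthly 0.0053
  expect_equal(round(monthly_prob_from_period(558, 4187, 27), 4), 0.0053)
  # 12-month hospitalization 392/1157 -> monthly 0.0339
  expect_equal(round(monthly_prob_from_period(392, 1157, 12), 4), 0.0339)
  expect_equal(monthly_prob_from_period(0, 440, 2), 0)
  # period of one month returns the raw proportion exactly
  expect_equal(monthly_prob_from_period(220, 440, 1), 0.5)
})

test_that("period-to-month conversion is the exact inverse of compounding", {
  cases <- expand.grid(events = c(1, 10, 150), at_risk = c(200, 1157),
                       period = c(1, 2, 12, 27))
  for (i in seq_len(nrow(cases))) {
    p <- monthly_prob_from_period(cases$events[i], cases$at_risk[i],
                                  cases$period[i])
    recovered <- 1 - (1 - p)^cases$period[i]
    expect_lt(abs(recovered - cases$events[i] / cases$at_risk[i]), 1e-14)
  }
})

test_that("conversion rejects degenerate inputs", {
  expect_error(monthly_prob_from_period(440, 440, 2), "smaller")
  expect_error(monthly_prob_from_period(10, 0, 2), "positive")
  expect_error(monthly_prob_from_period(-1, 440, 2), "non-negative")
  expect_error(monthly_prob_from_period(10, 440, 0), "period")
})

test_that("hazard-ratio adjustment scales the event count before conversion", {
  expect_equal(round(monthly_prob_with_hazard_ratio(392, 1157, 12, 0.79), 4),
               0.0256)
  expect_equal(monthly_prob_with_hazard_ratio(392, 1157, 12, 1),
               monthly_prob_from_period(392, 1157, 12))
  expect_equal(monthly_prob_with_hazard_ratio(392, 1157, 12, 0), 0)
  # monotone increasing in the hazard ratio
  hrs <- seq(0.1, 2.5, by = 0.2)
  ps <- vapply(hrs, function(h) {
    monthly_prob_with_hazard_ratio(100, 1000, 12, h)
  }, numeric(1))
  expect_true(all(diff(ps) > 0))
  expect_error(monthly_prob_with_hazard_ratio(392, 1157, 12, 3), "smaller")
  expect_error(monthly_prob_with_hazard_ratio(392, 1157, 12, -1),
               "non-negative")
})

test_that("cost inflation through the CPI chain converts to 2021 USD", {
  # one hospitalization: 12,351 CNY in 2014 prices -> 2361.5 USD in 2021
  expect_equal(round(inflate_and_convert_cost(12351, .cpi), 1), 2361.5)
  # identity chain
  expect_equal(inflate_and_convert_cost(42, cpi_chain(c(1, 1), 1)), 42)
  # single-step chain, hand arithmetic: 100 * 1.1 / 6.4515
  expect_equal(inflate_and_convert_cost(100, cpi_chain(1.1, 6.4515)),
               17.0503, tolerance = 1e-4)
})

test_that("cost inflation is multiplicative over sub-chains", {
  full <- .cpi$multipliers
  a <- cpi_chain(full[1:3], 1)
  b <- cpi_chain(full[4:7], .cpi$exchange_rate)
  chained <- inflate_and_convert_cost(inflate_and_convert_cost(500, a), b)
  expect_equal(chained, inflate_and_convert_cost(500, .cpi),
               tolerance = 1e-12)
})

test_that("discount rate is the geometric mean of the CPI chain minus one", {
  expect_equal(round(derive_discount_rate(.cpi), 2), 0.03)
  expect_equal(derive_discount_rate(cpi_chain(rep(1, 5), 1)), 0)
  expect_equal(derive_discount_rate(cpi_chain(c(1.05, 1.05), 1)), 0.05,
               tolerance = 1e-12)
})

test_that("beta moment matching recovers its target moments", {
  sym <- moment_match_beta(0.5, 0.1)
  expect_equal(sym$shape1, sym$shape2)
  for (case in list(c(0.0114, 0.0035), c(0.0172, 0.0044), c(0.0698, 0.0036),
                    c(0.1, 0.0128))) {
    spec <- moment_match_beta(case[1], case[2])
    m <- spec$shape1 / (spec$shape1 + spec$shape2)
    v <- spec$shape1 * spec$shape2 /
      ((spec$shape1 + spec$shape2)^2 * (spec$shape1 + spec$shape2 + 1))
    expect_equal(m, case[1], tolerance = 1e-3)
    expect_equal(sqrt(v), case[2], tolerance = 1e-3)
  }
  # independent quadrature oracle for the mean
  spec <- moment_match_beta(0.0114, 0.0035)
  m_int <- stats::integrate(function(x) {
    x * stats::dbeta(x, spec$shape1, spec$shape2)
  }, 0, 1, rel.tol = 1e-10)$value
  expect_equal(m_int, 0.0114, tolerance = 1e-6)
  expect_error(moment_match_beta(0.5, 0.6), "too large")
  expect_error(moment_match_beta(1.1, 0.1), "\\(0, 1\\)")
})

test_that("beta sampling reproduces the target mean within Monte Carlo error", {
  spec <- moment_match_beta(0.0172, 0.0044)
  set.seed(42)
  draws <- draw_distribution(spec, 1e6)
  se <- 0.0044 / sqrt(1e6)
  expect_lt(abs(mean(draws) - 0.0172), 3 * se)
})

test_that("gamma moment matching recovers its target moments", {
  spec <- moment_match_gamma(2361.5, 236)
  expect_equal(spec$shape * spec$scale, 2361.5, tolerance = 1e-12)
  expect_equal(sqrt(spec$shape) * spec$scale, 236, tolerance = 1e-12)
  # mean equal to sd gives the exponential special case
  expect_equal(moment_match_gamma(7, 7)$shape, 1)
  expect_error(moment_match_gamma(-1, 1), "positive")
  expect_error(moment_match_gamma(1, 0), "positive")
})

test_that("gamma sampling reproduces the target mean within Monte Carlo error", {
  spec <- moment_match_gamma(50.5, 18)
  set.seed(43)
  draws <- draw_distribution(spec, 1e6)
  expect_lt(abs(mean(draws) - 50.5), 3 * 18 / sqrt(1e6))
})

test_that("life-table lookup clamps to the open-ended last band", {
  expect_equal(noncv_mortality(62, .lt), 0.0004)
  expect_equal(noncv_mortality(65, .lt), 0.0007) # boundary enters next band
  expect_equal(noncv_mortality(85, .lt), 0.0054)
  expect_equal(noncv_mortality(120, .lt), 0.0054)
  expect_error(noncv_mortality(59, .lt), "below the first")
  expect_error(life_table(c(60, 65), c(0.002, 0.001)), "non-decreasing")
  expect_error(life_table(c(65, 60), c(0.001, 0.002)), "increasing")
})

test_that("parameter validation names the offending field", {
  expect_silent(validate_parameter_set(.params))
  bad <- .params; bad$u_sv_month <- 0.2
  expect_error(validate_parameter_set(bad), "u_sv_month")
  bad <- .params; bad$cost_hosp_event <- -5
  expect_error(validate_parameter_set(bad), "cost_hosp_event")
  bad <- .params; bad$p_cvd_early_ena <- 1.2
  expect_error(validate_parameter_set(bad), "p_cvd_early_ena")
  bad <- .params; bad$u_hosp_event <- 0.1
  expect_error(validate_parameter_set(bad), "u_hosp_event")
  bad <- .params; bad$p_cvd_early_sv <- 0.6; bad$p_hosp_early_sv <- 0.5
  expect_error(validate_parameter_set(bad), "competing")
  bad <- .params; bad$p_cvd_late_sv <- 0.9 # outside its range row
  expect_error(validate_parameter_set(bad), "competing|bracket")
  bad <- .params; bad$p_hosp_late_sv <- 0.03 # valid value, outside range
  expect_error(validate_parameter_set(bad), "bracket")
  expect_silent(validate_parameter_set(bad, check_ranges = FALSE))
})
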
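test_that("margin of error follows the binomial half-width formula", {
  expect_equal(margin_of_error(0.8, 1000), 0.0248, tolerance = 1e-3)
  expect_equal(margin_of_error(0, 500), 0)
  expect_equal(margin_of_error(1, 17), 0)
  expect_equal(margin_of_error(0.5, 100), 0.098, tolerance = 1e-3)
})

test_that("Wilson intervals behave at the boundaries and match the formula", {
  expect_equal(unname(power_ci(0, 25)[1]), 0)
  expect_equal(unname(power_ci(25, 25)[2]), 1)
  # direct textbook computation
  z <- qnorm(0.975); n <- 1000; p <- 800 / n
  lo <- (p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
  hi <- (p + z^2 / (2 * n) + z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
  expect_equal(unname(power_ci(800, 1000)), c(lo, hi), tolerance = 1e-6)
  expect_error(power_ci(1, 0), "undefined")
  expect_error(power_ci(5, 3))
})

test_that("degenerate and saturating Monte-Carlo runs behave as expected", {
  d <- short_term_design(2, 20, itn_reduction = 0.5)
  p1 <- estimate_power(d, n_sim = 1, seed = 4)
  expect_true(p1$power %in% c(0, 1))
  expect_gt(diff(unname(p1$ci)), 0.7)

  # effect so extreme the arms never overlap
  dsat <- short_term_design(8, 100, itn_reduction = 0.8, chamber_var = 0.01)
  ps <- estimate_power(dsat, n_sim = 40, seed = 4)
  expect_gte(ps$ci[["high"]], 0.99)
  expect_gt(ps$power, 0.9)

  # alpha = 1 rejects everything
  d0 <- short_term_design(2, 20)
  expect_equal(estimate_type1(d0, n_sim = 15, seed = 2, alpha = 1)$power, 1)
})

test_that("power estimates are reproducible and internally consistent", {
  d <- short_term_design(4, 30, itn_reduction = 0.6)
  a <- estimate_power(d, n_sim = 30, seed = 9)
  b <- estimate_power(d, n_sim = 30, seed = 9)
  expect_identical(a$pvalues, b$pvalues)
  expect_identical(a$power, b$power)
  expect_lte(a$n_significant, a$n_converged)
  expect_lte(a$n_converged, a$n_sim)
  expect_equal(a$power, a$n_significant / a$n_converged)
  expect_true(a$ci[["low"]] <= a$power && a$power <= a$ci[["high"]])
  expect_false(a$is_null_scenario)
  expect_output(print(a), "Monte-Carlo power")
})

test_that("type-I estimation insists on a null generating effect", {
  d <- short_term_design(2, 20, itn_reduction = 0.5)
  expect_error(estimate_type1(d, n_sim = 5), "zero generating effect")
  d0 <- short_term_design(2, 20)
  t1 <- estimate_type1(d0, n_sim = 20, seed = 3)
  expect_true(t1$is_null_scenario)
})

test_that("mismatched tested terms are config errors", {
  d <- short_term_design(2, 20, itn_reduction = 0.5)  # single arms
  expect_error(estimate_power(d, tested_term = "itn:ppf", n_sim = 2),
               "does not appear")
  expect_error(estimate_power(d, tested_term = "banana", n_sim = 2))
})

test_that("power rises with chambers, mosquitoes and effect size", {
  base <- list(n_ch = 4, lambda = 30, eff = 0.6)
  n_sim <- 150
  pw <- function(n_ch, lambda, eff, sc) {
    d <- short_term_design(n_ch, lambda, itn_reduction = eff)
    estimate_power(d, n_sim = n_sim, seed = 77, scenario = sc)$power
  }
  slack <- 0.08  # paired-seed Monte-Carlo slack
  expect_gte(pw(8, 30, 0.6, 1), pw(2, 30, 0.6, 1) - slack)
  expect_gte(pw(4, 80, 0.6, 2), pw(4, 10, 0.6, 2) - slack)
  expect_gte(pw(4, 30, 0.8, 3), pw(4, 30, 0.4, 3) - slack)
})

test_that("the null is approximately calibrated at eight chambers", {
  d0 <- short_term_design(8, 50)
  t1 <- estimate_type1(d0, n_sim = 250, seed = 5)
  # 99% binomial envelope around plausible mild inflation (<= 10%), never
  # below 1%
  expect_lte(t1$n_significant, qbinom(0.995, t1$n_converged, 0.10))
  expect_gte(t1$n_significant, qbinom(0.005, t1$n_converged, 0.01))
})

test_that("variance sensitivity sweeps scale the estimated variance", {
  base <- short_term_design(4, 30, arms = "combined", itn_reduction = 0.8,
                            ppf_reduction = 0.7, ixn_reduction = 0.8,
                            chamber_var = 0.1807)
  out <- variance_sensitivity(base, multipliers = c(0.5, 2),
                              n_ch_values = c(2, 4), n_sim = 25, seed = 6,
                              include_null = TRUE)
  expect_equal(nrow(out), 8)  # 2 multipliers x 2 chamber counts x {eff, null}
  expect_setequal(unique(out$var_multiplier), c(0.5, 2))
  expect_setequal(unique(out$chamber_var), 0.1807 * c(0.5, 2))
  expect_equal(sum(out$is_null_scenario), 4)
  expect_true(all(out$n_significant <= out$n_converged))

  off <- short_term_design(4, 30, chamber_var = 0.2)
  expect_error(variance_sensitivity(off), "0.1807")
})
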
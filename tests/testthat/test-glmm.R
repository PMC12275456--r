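test_that("Wald z-tests follow the normal tail", {
  expect_equal(wald_p(0, 2), 1)
  expect_equal(wald_p(1.959964 * 0.3, 0.3), 0.05, tolerance = 1e-6)
  expect_equal(wald_p(-3 * 1.7, 1.7), 2 * pnorm(-3), tolerance = 1e-12)
  expect_error(wald_p(1, 0), "positive")
  expect_error(wald_p(1, -2), "positive")
})

test_that("constant counts give the degenerate boundary fit", {
  dat <- data.frame(chamber = 1:6, itn = rep(0:1, each = 3), count = 7)
  fit <- fit_poisson_glmm(dat, terms = "itn")
  expect_true(fit$boundary)
  expect_identical(unname(fit$var_comp["chamber_var"]), 0)
  expect_equal(fit$coefficients$estimate[1], log(7), tolerance = 1e-6)
  expect_equal(fit$coefficients$estimate[2], 0, tolerance = 1e-6)
})

test_that("AGQ likelihood matches a dense-grid brute-force oracle", {
  # small instances: 4 chambers, one observation each
  for (seed in c(1, 2, 12)) {
    d <- short_term_design(2, 30, itn_reduction = 0.5, chamber_var = 0.25)
    dat <- simulate_short(d, seed = seed)
    fit <- fit_poisson_glmm(dat)
    X <- cbind(1, dat$itn)
    expect_false(fit$boundary)
    oracle <- grid_poisson_mle(dat$count, X, dat$chamber,
                               start = c(log(30), log(0.5), log(0.5)))
    expect_equal(fit$logLik, oracle$loglik, tolerance = 1e-4)
    expect_equal(fit$coefficients$estimate, unname(oracle$par[1:2]),
                 tolerance = 1e-3)
  }
})

test_that("a larger instance also matches the oracle log-likelihood", {
  d <- short_term_design(4, 50, itn_reduction = 0.6, chamber_var = 0.1807)
  dat <- simulate_short(d, seed = 21)
  fit <- fit_poisson_glmm(dat)
  expect_false(fit$boundary)
  ll <- grid_poisson_loglik(fit$coefficients$estimate,
                            sqrt(fit$var_comp[["chamber_var"]]),
                            dat$count, cbind(1, dat$itn), dat$chamber)
  # oracle evaluated at our MLE reproduces our maximised log-likelihood
  expect_equal(fit$logLik, ll, tolerance = 1e-6)
  # and our optimum cannot be beaten by the oracle's own search
  oracle <- grid_poisson_mle(dat$count, cbind(1, dat$itn), dat$chamber,
                             start = c(log(50), log(0.4), log(0.4)))
  expect_gte(fit$logLik, oracle$loglik - 1e-4)
})

test_that("estimates are stable when the quadrature is refined", {
  d <- short_term_design(4, 50, arms = "combined", itn_reduction = 0.8,
                         ppf_reduction = 0.7, ixn_reduction = 0.5)
  dat <- simulate_short(d, seed = 31)
  f15 <- fit_poisson_glmm(dat, nAGQ = 15)
  f30 <- fit_poisson_glmm(dat, nAGQ = 30)
  expect_equal(f15$coefficients$estimate, f30$coefficients$estimate,
               tolerance = 1e-4)
  expect_equal(f15$logLik, f30$logLik, tolerance = 1e-4)
})

test_that("the fit is invariant to row order", {
  d <- short_term_design(3, 40, arms = "combined", itn_reduction = 0.6,
                         ppf_reduction = 0.4, ixn_reduction = 0.5)
  dat <- simulate_short(d, seed = 13)
  f1 <- fit_poisson_glmm(dat)
  f2 <- fit_poisson_glmm(dat[sample.int(nrow(dat)), ])
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-8)
})

test_that("adding a true-zero term never lowers the maximised likelihood", {
  d <- short_term_design(4, 30, arms = "combined", itn_reduction = 0.5)
  dat <- simulate_short(d, seed = 17)
  ll_full <- fit_poisson_glmm(dat, terms = c("itn", "ppf", "itn:ppf"))$logLik
  ll_red <- fit_poisson_glmm(dat, terms = c("itn", "ppf"))$logLik
  expect_gte(ll_full + 1e-6, ll_red)
})

test_that("an all-zero arm yields a flagged fit, not an error", {
  dat <- data.frame(chamber = 1:8, itn = rep(0:1, each = 4),
                    count = c(12, 9, 15, 11, 0, 0, 0, 0))
  fit <- fit_poisson_glmm(dat)
  expect_true(fit$converged || fit$boundary)
  i <- match("itn", fit$coefficients$term)
  expect_gt(fit$coefficients$se[i], 10)  # separation: huge SE
  expect_gt(fit$coefficients$p[i], 0.9)
})

test_that("the ITN effect is recovered without bias across replicates", {
  d <- short_term_design(8, 50, itn_reduction = 0.8, chamber_var = 0.1807)
  est <- vapply(1:300, function(i) {
    fit <- fit_poisson_glmm(simulate_short(d, seed = 40000 + i))
    fit$coefficients$estimate[match("itn", fit$coefficients$term)]
  }, numeric(1))
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - log(0.2)), 3 * mc_se)
})

test_that("the AGQ fit agrees with an independent GLMM implementation", {
  skip_if_not_installed("lme4")
  d <- short_term_design(4, 50, arms = "combined", itn_reduction = 0.8,
                         ppf_reduction = 0.7, ixn_reduction = 0.5)
  for (seed in c(3, 14)) {
    dat <- simulate_short(d, seed = seed)
    fit <- fit_poisson_glmm(dat)
    ref <- suppressMessages(lme4::glmer(
      count ~ itn * ppf + (1 | chamber), data = dat, family = poisson,
      nAGQ = 15))
    cf <- summary(ref)$coefficients
    expect_equal(fit$coefficients$estimate, unname(cf[, 1]), tolerance = 1e-3)
    expect_equal(fit$coefficients$se, unname(cf[, 2]), tolerance = 5e-3)
  }
})

test_that("fits serialise to JSON audit records", {
  d <- short_term_design(2, 20, itn_reduction = 0.5)
  fit <- fit_poisson_glmm(simulate_short(d, seed = 2))
  js <- jsonlite::fromJSON(fit_to_json(fit))
  expect_equal(js$model, "poisson_agq")
  expect_equal(js$coefficients$estimate, fit$coefficients$estimate,
               tolerance = 1e-9)
  expect_type(js$converged, "logical")
  path <- withr::local_tempfile(fileext = ".json")
  fit_to_json(fit, path)
  expect_true(file.exists(path))
})
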
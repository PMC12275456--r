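# Independent oracles used by the fitter tests. These deliberately avoid the
# package's quadrature code path: the Poisson oracle integrates each
# chamber's likelihood over the random intercept on a dense fixed grid
# (trapezoid rule), the NB oracle integrates the crossed random-effect space
# by plain Monte Carlo.

# marginal log-likelihood of the Poisson random-intercept model by dense
# grid integration over c in [-8 sd, 8 sd]
grid_poisson_loglik <- function(beta, sigma, counts, X, chamber,
                                n_grid = 4001) {
  eta <- drop(X %*% beta)
  half <- max(8 * sigma, 2)
  cs <- seq(-half, half, length.out = n_grid)
  dc <- cs[2] - cs[1]
  total <- 0
  for (ch in unique(chamber)) {
    idx <- which(chamber == ch)
    # integrand on the grid, one column per grid point
    lg <- vapply(cs, function(c) {
      sum(stats::dpois(counts[idx], exp(eta[idx] + c), log = TRUE)) +
        stats::dnorm(c, 0, sigma, log = TRUE)
    }, numeric(1))
    m <- max(lg)
    total <- total + m + log(sum(exp(lg - m)) * dc)
  }
  total
}

# maximise the grid oracle over (beta, log sigma) with optim from the truth
# and a couple of jittered starts; independent of the AGQ code path
grid_poisson_mle <- function(counts, X, chamber, start) {
  obj <- function(par) {
    -grid_poisson_loglik(par[seq_len(ncol(X))], exp(par[ncol(X) + 1]),
                         counts, X, chamber, n_grid = 801)
  }
  best <- NULL
  for (st in list(start, start + 0.1, start - 0.1)) {
    o <- stats::optim(st, obj, method = "BFGS", control = list(maxit = 300))
    if (is.null(best) || o$value < best$value) best <- o
  }
  # polish the log-likelihood at the optimum on the dense grid
  list(par = best$par,
       loglik = grid_poisson_loglik(best$par[seq_len(ncol(X))],
                                    exp(best$par[ncol(X) + 1]),
                                    counts, X, chamber, n_grid = 4001))
}

# Monte-Carlo estimate (with standard error) of the marginal log-likelihood
# of the crossed NB model at fixed parameters, integrating over all random
# effects by simple prior sampling
mc_negbin_loglik <- function(beta, sd_t, sd_c, theta, counts, X, ti, ci,
                             n_mc = 2e5, seed = 1) {
  set.seed(seed)
  qt <- length(unique(ti)); qc <- length(unique(ci))
  eta0 <- drop(X %*% beta)
  lw <- vapply(seq_len(n_mc), function(s) {
    tau <- stats::rnorm(qt, 0, sd_t)
    cc <- stats::rnorm(qc, 0, sd_c)
    sum(stats::dnbinom(counts, mu = exp(eta0 + tau[ti] + cc[ci]),
                       size = theta, log = TRUE))
  }, numeric(1))
  m <- max(lw)
  w <- exp(lw - m)
  est <- m + log(mean(w))
  # delta-method SE of log mean weight
  se <- stats::sd(w) / (mean(w) * sqrt(n_mc))
  list(loglik = est, se = se)
}
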
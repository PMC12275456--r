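# Laplace-approximated marginal likelihood for the long-term model:
# y_{i,j} ~ NB(mu_{i,j}, theta), log mu = X beta + tau_i + c_j with crossed
# normal random intercepts. The joint mode over u = (tau, c) is found by a
# damped Newton iteration; the negative joint Hessian has the arrow-free
# 2x2 block structure [diag + W; W' + diag], dense-Cholesky-factorised
# directly (at most ~120 latent dimensions for daily sampling).

nb_laplace_engine <- function(y, X, ti, ci, qt, qc, incl_t, incl_c) {
  n <- length(y)
  if (anyDuplicated(cbind(ti, ci))) {
    stop("long-term count table must have one observation per chamber-time pair",
         call. = FALSE)
  }
  q <- incl_t * qt + incl_c * qc
  state <- new.env(parent = emptyenv())
  state$u <- numeric(q)

  function(beta, log_sd_t, log_sd_c, log_theta) {
    theta <- exp(log_theta)
    s2t <- exp(2 * log_sd_t); s2c <- exp(2 * log_sd_c)
    eta0 <- drop(X %*% beta)
    u <- state$u
    tau <- if (incl_t) u[seq_len(qt)] else numeric(qt)
    cc <- if (incl_c) u[incl_t * qt + seq_len(qc)] else numeric(qc)

    joint_ll <- function(tau, cc) {
      eta <- eta0 + tau[ti] + cc[ci]
      ll <- sum(stats::dnbinom(y, mu = exp(eta), size = theta, log = TRUE))
      if (incl_t) ll <- ll - 0.5 * sum(tau^2) / s2t - qt / 2 * log(2 * pi * s2t)
      if (incl_c) ll <- ll - 0.5 * sum(cc^2) / s2c - qc / 2 * log(2 * pi * s2c)
      ll
    }

    jl <- joint_ll(tau, cc)
    if (!is.finite(jl)) { tau <- numeric(qt); cc <- numeric(qc); jl <- joint_ll(tau, cc) }
    H <- NULL
    for (iter in seq_len(60)) {
      mu <- exp(eta0 + tau[ti] + cc[ci])
      g <- y - (y + theta) * mu / (mu + theta)
      w <- (y + theta) * theta * mu / (mu + theta)^2
      grad <- c(if (incl_t) drop(rowsum(g, ti, reorder = TRUE)) - tau / s2t,
                if (incl_c) drop(rowsum(g, ci, reorder = TRUE)) - cc / s2c)
      dt <- drop(rowsum(w, ti, reorder = TRUE)) + 1 / s2t
      dc <- drop(rowsum(w, ci, reorder = TRUE)) + 1 / s2c
      Wm <- matrix(0, qt, qc)
      Wm[cbind(ti, ci)] <- w
      H <- if (incl_t && incl_c) {
        rbind(cbind(diag(dt, qt), Wm), cbind(t(Wm), diag(dc, qc)))
      } else if (incl_t) diag(dt, qt) else diag(dc, qc)
      step <- tryCatch(drop(solve(H, grad)), error = function(e) NULL)
      if (is.null(step)) return(1e10)
      if (max(abs(step)) < 1e-9) break
      alpha <- 1
      repeat {
        tau2 <- tau; cc2 <- cc
        if (incl_t) tau2 <- tau + alpha * step[seq_len(qt)]
        if (incl_c) cc2 <- cc + alpha * step[incl_t * qt + seq_len(qc)]
        jl2 <- joint_ll(tau2, cc2)
        if (is.finite(jl2) && jl2 >= jl - 1e-12) { tau <- tau2; cc <- cc2; jl <- jl2; break }
        alpha <- alpha / 2
        if (alpha < 1e-6) break
      }
      if (alpha < 1e-6) break
    }
    state$u <- c(if (incl_t) tau, if (incl_c) cc)
    R <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(R)) return(1e10)
    ll <- jl + q / 2 * log(2 * pi) - sum(log(diag(R)))
    if (!is.finite(ll)) 1e10 else -ll
  }
}

fit_nb_once <- function(y, X, ti, ci, qt, qc, incl_t, incl_c, start,
                        max_restarts) {
  p <- ncol(X)
  engine <- nb_laplace_engine(y, X, ti, ci, qt, qc, incl_t, incl_c)
  idx_t <- if (incl_t) p + 1L else 0L
  idx_c <- if (incl_c) p + incl_t + 1L else 0L
  idx_th <- p + incl_t + incl_c + 1L
  nll <- function(par) {
    engine(par[seq_len(p)],
           if (incl_t) par[idx_t] else -Inf,
           if (incl_c) par[idx_c] else -Inf,
           par[idx_th])
  }
  nvar <- incl_t + incl_c
  lower <- c(rep(-Inf, p), rep(log(1e-4), nvar), log(1e-3))
  upper <- c(rep(Inf, p), rep(log(10), nvar), log(1e6))
  opt <- NULL; converged <- FALSE
  for (att in seq_len(max_restarts + 1)) {
    st <- if (att == 1) start else start + c(stats::rnorm(p, 0, 0.2),
                                             stats::runif(nvar + 1, -0.7, 0.7))
    o <- tryCatch(stats::nlminb(st, nll, lower = lower, upper = upper,
                                control = list(eval.max = 1000, iter.max = 500,
                                               rel.tol = 1e-9)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(opt) || o$objective < opt$objective)) opt <- o
    if (!is.null(o) && o$convergence == 0) { converged <- TRUE; break }
  }
  if (is.null(opt)) return(NULL)
  list(opt = opt, nll = nll, converged = converged,
       idx_t = idx_t, idx_c = idx_c, idx_th = idx_th, p = p)
}

#' Fit the long-term negative-binomial GLMM with crossed random intercepts
#'
#' Maximises the Laplace-approximated marginal likelihood of the model
#' \eqn{y_{i,j} \sim NB(\lambda_{i,j}, \theta)},
#' \eqn{\log \lambda_{i,j} = x_{i,j}'\beta + \tau_i + c_j}, with a random
#' intercept per sampling occasion (\eqn{\tau_i}, shared across chambers) and
#' per chamber (\eqn{c_j}), jointly over the fixed effects, both random-effect
#' standard deviations (log scale) and the dispersion \eqn{\theta}. All
#' lower-order fixed-effect terms of the generative equation are always
#' retained, even though their generating values are zero: with real data
#' their effects cannot be assumed away. When a random-effect standard
#' deviation collapses towards zero the profile with that component removed is
#' refitted and the better likelihood wins (boundary flag); a dispersion
#' estimate at the cap of 1e6 is flagged as the Poisson limit. Standard
#' errors come from the observed information of the approximate marginal
#' log-likelihood with the variance parameters held at their estimates, and
#' each coefficient gets a two-sided Wald z-test.
#'
#' @param data Count table with columns \code{chamber}, \code{itn},
#'   \code{ppf}, \code{time}, \code{count}, e.g. from [simulate_long()]; one
#'   observation per chamber-time pair.
#' @param terms Fixed-effect terms besides the intercept. Defaults to the
#'   generating model: \code{c("time", "itn", "time:itn")} or, with a PPFa
#'   arm, all main effects and interactions up to \code{time:itn:ppf}.
#' @param max_restarts Jittered optimiser restarts before declaring
#'   non-convergence.
#' @return An \code{"sfe_fit"} object; variance components are
#'   \code{time_var}, \code{chamber_var} and \code{theta}.
#' @examples
#' d <- long_term_design(3, 10, sampl_freq = "monthly", itn_reduction = 0.8)
#' fit_negbin_glmm(simulate_long(d, seed = 7))
#' @export
fit_negbin_glmm <- function(data, terms = NULL, max_restarts = 3) {
  stopifnot(all(c("chamber", "itn", "time", "count") %in% names(data)))
  if (is.null(terms)) {
    combined <- "ppf" %in% names(data) && any(data$ppf > 0)
    terms <- canonical_terms(long = TRUE, combined = combined)
  }
  X <- model_matrix_from_terms(data, terms)
  y <- as.numeric(data$count)
  times <- sort(unique(data$time))
  chambers <- sort(unique(data$chamber))
  ti <- match(data$time, times)
  ci <- match(data$chamber, chambers)
  qt <- length(times); qc <- length(chambers)
  p <- ncol(X)

  beta_start <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::poisson())$coefficients
  )
  beta_start[!is.finite(beta_start)] <- 0
  start_full <- c(beta_start, log(0.3), log(0.3), log(5))

  full <- fit_nb_once(y, X, ti, ci, qt, qc, TRUE, TRUE, start_full, max_restarts)
  if (is.null(full)) stop("optimiser failed on all restarts", call. = FALSE)
  best <- full; incl <- c(t = TRUE, c = TRUE)

  sd_t <- exp(full$opt$par[full$idx_t])
  sd_c <- exp(full$opt$par[full$idx_c])
  boundary <- FALSE
  # profile out near-zero components and keep the better likelihood
  try_reduced <- function(incl_t, incl_c) {
    st <- c(beta_start, rep(log(0.3), incl_t + incl_c), log(5))
    fit_nb_once(y, X, ti, ci, qt, qc, incl_t, incl_c, st, max_restarts)
  }
  if (sd_t < 1e-3 || sd_c < 1e-3) {
    cand <- list()
    if (sd_t < 1e-3) cand <- c(cand, list(list(f = try_reduced(FALSE, TRUE), i = c(FALSE, TRUE))))
    if (sd_c < 1e-3) cand <- c(cand, list(list(f = try_reduced(TRUE, FALSE), i = c(TRUE, FALSE))))
    if (sd_t < 1e-3 && sd_c < 1e-3) {
      cand <- c(cand, list(list(f = try_reduced(FALSE, FALSE), i = c(FALSE, FALSE))))
    }
    for (cd in cand) {
      if (!is.null(cd$f) && cd$f$opt$objective <= best$opt$objective + 1e-8) {
        best <- cd$f; incl <- c(t = cd$i[1], c = cd$i[2]); boundary <- TRUE
      }
    }
    if (!boundary && (sd_t < 1e-3 || sd_c < 1e-3)) boundary <- TRUE
  }

  opt <- best$opt
  est <- opt$par[seq_len(p)]
  theta_hat <- exp(opt$par[best$idx_th])
  vc <- c(time_var = if (incl["t"]) exp(2 * opt$par[best$idx_t]) else 0,
          chamber_var = if (incl["c"]) exp(2 * opt$par[best$idx_c]) else 0)
  if (boundary) {
    vc[vc < 1e-6] <- 0
  }
  poisson_limit <- theta_hat >= 1e6 * 0.99

  fixed_tail <- opt$par[-seq_len(p)]
  Hb <- num_hessian(function(b) best$nll(c(b, fixed_tail)), est)
  se <- tryCatch(sqrt(diag(solve(Hb))), error = function(e) rep(NA_real_, p))
  converged <- best$converged
  if (anyNA(se) || any(!is.finite(se))) {
    converged <- FALSE
    se[!is.finite(se) | is.na(se)] <- Inf
  }
  new_sfe_fit(coef_table(colnames(X), unname(est), se),
              var_comp = c(vc, theta = theta_hat),
              logLik = -opt$objective, converged = converged,
              boundary = boundary || poisson_limit,
              model = "negbin_laplace", n_obs = length(y),
              extra = list(poisson_limit = poisson_limit))
}
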
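#' @useDynLib sfepower, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Gauss-Hermite nodes/weights (weight function exp(-z^2)) by Golub-Welsch:
# eigen-decomposition of the symmetric Jacobi matrix of the Hermite
# three-term recurrence. n = 1 gives the Laplace approximation.
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

# central-difference Hessian of scalar function f at x
num_hessian <- function(f, x, h = 1e-4 * (1 + abs(x))) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    for (j in seq_len(i)) {
      ei <- ej <- numeric(p)
      ei[i] <- h[i]; ej[j] <- h[j]
      if (i == j) {
        H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
          (4 * h[i] * h[j])
      }
    }
  }
  H
}

canonical_terms <- function(long, combined) {
  if (!long) {
    if (combined) c("itn", "ppf", "itn:ppf") else "itn"
  } else {
    if (combined) c("time", "itn", "ppf", "itn:ppf",
                    "time:itn", "time:ppf", "time:itn:ppf")
    else c("time", "itn", "time:itn")
  }
}

model_matrix_from_terms <- function(data, terms) {
  cols <- lapply(terms, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    Reduce(`*`, lapply(parts, function(v) {
      if (!v %in% names(data)) stop(sprintf("term '%s' needs column '%s'", tm, v),
                                    call. = FALSE)
      as.numeric(data[[v]])
    }))
  })
  X <- cbind(1, do.call(cbind, cols))
  colnames(X) <- c("(Intercept)", terms)
  X
}

new_sfe_fit <- function(coef_df, var_comp, logLik, converged, boundary,
                        model, n_obs, extra = list()) {
  structure(
    c(list(coefficients = coef_df, var_comp = var_comp, logLik = logLik,
           converged = converged, boundary = boundary, model = model,
           n_obs = n_obs), extra),
    class = "sfe_fit"
  )
}

#' @export
print.sfe_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s)\n", x$model,
              if (x$converged) "converged" else "NOT converged"))
  cf <- x$coefficients
  cf$estimate <- round(cf$estimate, 4)
  cf$se <- round(cf$se, 4)
  cf$z <- round(cf$z, 3)
  cf$p <- signif(cf$p, 3)
  print(cf, row.names = FALSE)
  vc <- x$var_comp
  cat("variance components:",
      paste(sprintf("%s = %.4g", names(vc), vc), collapse = ", "), "\n")
  cat(sprintf("logLik = %.4f%s\n", x$logLik,
              if (x$boundary) "  [boundary: variance component at 0]" else ""))
  invisible(x)
}

#' @export
logLik.sfe_fit <- function(object, ...) object$logLik

#' @export
coef.sfe_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Two-sided Wald z-test p-value
#'
#' @param estimate Coefficient estimate.
#' @param se Its standard error (must be positive).
#' @return \code{2 * pnorm(-|estimate/se|)}.
#' @examples
#' wald_p(1.96, 1)  # ~0.05
#' @export
wald_p <- function(estimate, se) {
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop("'se' must be positive", call. = FALSE)
  }
  2 * stats::pnorm(-abs(estimate / se))
}

coef_table <- function(terms, est, se) {
  data.frame(term = terms, estimate = est, se = se,
             z = est / se, p = wald_p(est, se))
}

#' Fit the short-term Poisson GLMM with a chamber random intercept
#'
#' Maximises the marginal likelihood of the model
#' \eqn{y_j \sim Pois(e^{\eta_j + c_j})}, \eqn{c_j \sim N(0, \sigma_c^2)},
#' integrating the chamber intercept out by adaptive Gauss-Hermite quadrature
#' (the quadrature is re-centred and re-scaled at each chamber's conditional
#' mode). The chamber standard deviation is optimised on the log scale; when
#' the optimum collapses towards zero the \eqn{\sigma_c = 0} profile (an
#' ordinary Poisson GLM) is fitted as well and the better likelihood wins, so
#' boundary (singular) fits are reported as exactly \eqn{\hat\sigma_c^2 = 0}.
#' Fixed-effect standard errors are taken from the observed information of the
#' marginal log-likelihood at the optimum with the variance parameter held at
#' its estimate (the usual GLMM Wald convention), and each coefficient gets a
#' two-sided Wald z-test.
#'
#' @param data A count table with columns \code{chamber}, \code{itn}
#'   (optionally \code{ppf}) and \code{count}, e.g. from [simulate_short()].
#' @param terms Fixed-effect terms besides the intercept. Defaults to
#'   \code{"itn"} or, when a PPFa arm is present,
#'   \code{c("itn", "ppf", "itn:ppf")} -- the model the data were generated
#'   from.
#' @param nAGQ Number of quadrature nodes (default 15; 1 is the Laplace
#'   approximation).
#' @param max_restarts Jittered optimiser restarts before declaring
#'   non-convergence.
#' @return An object of class \code{"sfe_fit"}: coefficient table (estimate,
#'   SE, Wald z, p), variance components, maximised log-likelihood,
#'   convergence and boundary flags.
#' @examples
#' d <- short_term_design(4, 50, itn_reduction = 0.8)
#' fit_poisson_glmm(simulate_short(d, seed = 42))
#' @export
fit_poisson_glmm <- function(data, terms = NULL, nAGQ = 15, max_restarts = 3) {
  stopifnot(all(c("chamber", "itn", "count") %in% names(data)))
  if (is.null(terms)) {
    combined <- "ppf" %in% names(data) && any(data$ppf > 0)
    terms <- canonical_terms(long = FALSE, combined = combined)
  }
  X <- model_matrix_from_terms(data, terms)
  y <- as.numeric(data$count)
  group <- match(data$chamber, sort(unique(data$chamber))) - 1L
  ngroups <- length(unique(group))
  gh <- gauss_hermite(nAGQ)
  p <- ncol(X)

  nll <- function(par) {
    v <- agq_poisson_nll(par[seq_len(p)], par[p + 1], y, X, group, ngroups,
                         gh$nodes, gh$weights)
    if (!is.finite(v)) 1e10 else v
  }

  # sigma = 0 profile: an ordinary Poisson GLM
  glm_fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::poisson())
  )
  ll_glm <- -sum(glm_fit$deviance) / 2 +
    sum(stats::dpois(y, y, log = TRUE)) # saturated ll back in
  beta_glm <- glm_fit$coefficients

  start <- c(beta_glm, log(0.3))
  lower <- c(rep(-Inf, p), log(1e-4))
  upper <- c(rep(Inf, p), log(20))
  opt <- NULL
  converged <- FALSE
  for (att in seq_len(max_restarts + 1)) {
    st <- if (att == 1) start else start + c(stats::rnorm(p, 0, 0.2),
                                             stats::runif(1, -1, 1))
    o <- tryCatch(stats::nlminb(st, nll, lower = lower, upper = upper,
                                control = list(eval.max = 500, iter.max = 300)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(opt) || o$objective < opt$objective)) opt <- o
    if (!is.null(o) && o$convergence == 0) { converged <- TRUE; break }
  }
  if (is.null(opt)) stop("optimiser failed on all restarts", call. = FALSE)

  sigma_hat <- exp(opt$par[p + 1])
  ll_agq <- -opt$objective
  boundary <- FALSE
  if (sigma_hat < 1e-3 || ll_glm >= ll_agq - 1e-8) {
    # boundary fit wins (or is indistinguishable): report sigma^2 = 0 exactly
    est <- beta_glm
    XW <- X * glm_fit$weights  # canonical link: observed = expected information
    se <- sqrt(diag(solve(crossprod(X, XW))))
    fit <- new_sfe_fit(coef_table(colnames(X), unname(est), se),
                       var_comp = c(chamber_var = 0),
                       logLik = max(ll_glm, ll_agq), converged = TRUE,
                       boundary = TRUE, model = "poisson_agq",
                       n_obs = length(y), extra = list(nAGQ = nAGQ))
    return(fit)
  }

  est <- opt$par[seq_len(p)]
  Hb <- num_hessian(function(b) nll(c(b, opt$par[p + 1])), est)
  se <- tryCatch(sqrt(diag(solve(Hb))), error = function(e) rep(NA_real_, p))
  if (anyNA(se) || any(!is.finite(se))) converged <- FALSE
  if (!converged && anyNA(se)) se <- rep(Inf, p)
  new_sfe_fit(coef_table(colnames(X), unname(est), se),
              var_comp = c(chamber_var = sigma_hat^2),
              logLik = ll_agq, converged = converged, boundary = FALSE,
              model = "poisson_agq", n_obs = length(y),
              extra = list(nAGQ = nAGQ))
}

#' Serialise a fit to JSON
#'
#' Writes coefficients, standard errors, Wald tests, variance components,
#' log-likelihood and the convergence/boundary flags as a JSON audit record.
#'
#' @param fit An \code{sfe_fit}.
#' @param path Optional file path; when omitted the JSON string is returned.
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "sfe_fit"))
  obj <- list(model = fit$model, coefficients = fit$coefficients,
              var_comp = as.list(fit$var_comp), logLik = fit$logLik,
              converged = fit$converged, boundary = fit$boundary,
              n_obs = fit$n_obs)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
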
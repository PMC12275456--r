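term_for_design <- function(design) {
  if (inherits(design, "sfe_design_short")) {
    if (design$arms == "single") "itn" else "itn:ppf"
  } else {
    if (design$arms == "single") "time:itn" else "time:itn:ppf"
  }
}

generating_effect <- function(design, term) {
  b <- true_coefficients(design)
  key <- c("itn" = "beta_I", "ppf" = "beta_P", "itn:ppf" = "beta_IP",
           "time" = "beta_T", "time:itn" = "beta_TI", "time:ppf" = "beta_TP",
           "time:itn:ppf" = "beta_TIP")[term]
  if (is.na(key)) stop(sprintf("unknown tested term '%s'", term), call. = FALSE)
  unname(b[key])
}

#' Monte-Carlo margin of error of a power estimate
#'
#' Half-width of the normal-approximation 95\% interval for a proportion:
#' at true power 0.8 and 1000 simulations this is about 2.5 percentage
#' points, the precision the default replication buys.
#'
#' @param power Proportion in \code{[0, 1]}.
#' @param n_sim Number of simulated datasets.
#' @return \code{1.959964 * sqrt(power * (1 - power) / n_sim)}.
#' @examples
#' margin_of_error(0.8, 1000)  # ~0.025
#' @export
margin_of_error <- function(power, n_sim) {
  stopifnot(all(power >= 0), all(power <= 1), all(n_sim >= 1))
  stats::qnorm(0.975) * sqrt(power * (1 - power) / n_sim)
}

#' Wilson score 95\% confidence interval for a simulated proportion
#'
#' Used for the error bars on power and type-I estimates; unlike the Wald
#' interval it behaves sensibly when every (or no) simulation is significant.
#'
#' @param n_significant Number of significant datasets.
#' @param n_converged Number of converged fits (the denominator).
#' @return Numeric vector \code{c(low, high)}.
#' @export
power_ci <- function(n_significant, n_converged) {
  if (n_converged < 1) {
    stop("no converged fits: the power estimate is undefined", call. = FALSE)
  }
  stopifnot(n_significant >= 0, n_significant <= n_converged)
  z <- stats::qnorm(0.975)
  phat <- n_significant / n_converged
  denom <- 1 + z^2 / n_converged
  centre <- (phat + z^2 / (2 * n_converged)) / denom
  half <- z * sqrt(phat * (1 - phat) / n_converged +
                     z^2 / (4 * n_converged^2)) / denom
  c(low = max(0, centre - half), high = min(1, centre + half))
}

#' Estimate statistical power (or type-I error) of a design by simulation
#'
#' Simulates \code{n_sim} datasets from the design's generative model, refits
#' the matching GLMM to each, and reports the proportion of two-sided Wald
#' z-tests for the tested term with p below \code{alpha}. When the generating
#' effect of the tested term is zero this proportion estimates the type-I
#' error rate rather than power. Per-dataset RNG substreams are derived from
#' \code{(seed, scenario, replicate)}, so estimates are reproducible and
#' independent of execution order.
#'
#' @param design An \code{sfe_design}.
#' @param tested_term Coefficient tested; defaults to the highest-order
#'   intervention term of the design (\code{"itn"}, \code{"itn:ppf"},
#'   \code{"time:itn"} or \code{"time:itn:ppf"}).
#' @param n_sim Number of simulated datasets (1000 gives a margin of error of
#'   about ±2.5 percentage points at true power 80\%).
#' @param seed Master seed.
#' @param alpha Significance threshold (default 0.05).
#' @param nonconverged Either \code{"exclude"} (drop non-converged fits from
#'   the denominator; default) or \code{"nonsignificant"} (count them as
#'   failures to reject).
#' @param scenario Scenario index mixed into the RNG substreams; grid runs
#'   pass the cell index so cells can be reproduced in isolation.
#' @return An object of class \code{"sfe_power"}: power, Wilson 95\% CI,
#'   counts (\code{n_sim}, \code{n_converged}, \code{n_significant}),
#'   boundary-fit rate, the tested term and whether this is a null scenario.
#' @examples
#' d <- short_term_design(4, 20, itn_reduction = 0.8)
#' estimate_power(d, n_sim = 20, seed = 1)
#' @export
estimate_power <- function(design, tested_term = NULL, n_sim = 1000, seed = 1,
                           alpha = 0.05,
                           nonconverged = c("exclude", "nonsignificant"),
                           scenario = 1L) {
  stopifnot(inherits(design, "sfe_design"), n_sim >= 1)
  nonconverged <- match.arg(nonconverged)
  expected <- term_for_design(design)
  if (is.null(tested_term)) tested_term <- expected
  allowed <- if (inherits(design, "sfe_design_short")) {
    canonical_terms(FALSE, design$arms == "combined")
  } else {
    canonical_terms(TRUE, design$arms == "combined")
  }
  if (!tested_term %in% allowed) {
    stop(sprintf("tested term '%s' does not appear in the %s-arm model",
                 tested_term, design$arms), call. = FALSE)
  }
  short <- inherits(design, "sfe_design_short")
  pvals <- rep(NA_real_, n_sim)
  conv <- logical(n_sim)
  bnd <- logical(n_sim)
  for (r in seq_len(n_sim)) {
    sub <- substream_seed(seed, scenario, r)
    dat <- simulate_counts(design, sub)
    fit <- if (short) fit_poisson_glmm(dat) else fit_negbin_glmm(dat)
    conv[r] <- fit$converged
    bnd[r] <- fit$boundary
    i <- match(tested_term, fit$coefficients$term)
    if (!is.na(i)) pvals[r] <- fit$coefficients$p[i]
  }
  ok <- conv & !is.na(pvals)
  sig <- ok & pvals < alpha
  if (nonconverged == "exclude") {
    n_conv <- sum(ok)
    n_sig <- sum(sig)
    power <- if (n_conv > 0) n_sig / n_conv else NA_real_
  } else {
    n_conv <- n_sim
    n_sig <- sum(sig)
    power <- n_sig / n_sim
  }
  ci <- if (n_conv > 0) power_ci(n_sig, n_conv) else c(low = NA_real_, high = NA_real_)
  structure(
    list(design = design, tested_term = tested_term, n_sim = n_sim,
         n_converged = n_conv, n_significant = n_sig, power = power, ci = ci,
         alpha = alpha,
         is_null_scenario = generating_effect(design, tested_term) == 0,
         convergence_rate = mean(conv), boundary_rate = mean(bnd),
         sufficient = isTRUE(power >= 0.8), seed = seed, scenario = scenario,
         nonconverged_policy = nonconverged, pvalues = pvals),
    class = "sfe_power"
  )
}

#' Estimate the type-I error rate of a design
#'
#' Identical machinery to [estimate_power()], but requires the generating
#' effect of the tested term to be zero, so the proportion of rejections
#' estimates the false-positive rate (nominally \code{alpha}).
#'
#' @inheritParams estimate_power
#' @export
estimate_type1 <- function(design, tested_term = NULL, n_sim = 1000, seed = 1,
                           alpha = 0.05,
                           nonconverged = c("exclude", "nonsignificant"),
                           scenario = 1L) {
  if (is.null(tested_term)) tested_term <- term_for_design(design)
  if (generating_effect(design, tested_term) != 0) {
    stop("type-I estimation requires a zero generating effect for the tested term",
         call. = FALSE)
  }
  estimate_power(design, tested_term, n_sim, seed, alpha,
                 nonconverged = match.arg(nonconverged), scenario = scenario)
}

#' @export
print.sfe_power <- function(x, ...) {
  what <- if (x$is_null_scenario) "type-I error" else "power"
  cat(sprintf("Monte-Carlo %s for term '%s'\n", what, x$tested_term))
  cat(sprintf("  %s = %.1f%%  (95%% CI %.1f%% - %.1f%%)\n",
              what, 100 * x$power, 100 * x$ci["low"], 100 * x$ci["high"]))
  cat(sprintf("  %d / %d significant at alpha = %g; %d of %d fits converged (%.0f%% boundary)\n",
              x$n_significant, x$n_converged, x$alpha, x$n_converged, x$n_sim,
              100 * x$boundary_rate))
  if (!x$is_null_scenario) {
    cat(sprintf("  sufficient power (>= 80%%): %s\n",
                if (x$sufficient) "yes" else "no"))
  }
  invisible(x)
}

#' @export
as.data.frame.sfe_power <- function(x, ...) {
  d <- x$design
  data.frame(
    scenario = x$scenario, arms = d$arms,
    horizon = if (inherits(d, "sfe_design_long")) "long" else "short",
    n_ch_per_trt = d$n_ch_per_trt, lambda = d$lambda,
    itn_effect = d$effects$itn_reduction, ppf_effect = d$effects$ppf_reduction,
    ixn_effect = d$effects$ixn_reduction, chamber_var = d$chamber_var,
    sampl_points = if (inherits(d, "sfe_design_long")) length(d$sampling_times) else 1L,
    tested_term = x$tested_term, alpha = x$alpha, n_sim = x$n_sim,
    n_converged = x$n_converged, n_significant = x$n_significant,
    power = x$power, ci_low = unname(x$ci["low"]), ci_high = unname(x$ci["high"]),
    is_null_scenario = x$is_null_scenario,
    convergence_rate = x$convergence_rate, boundary_rate = x$boundary_rate,
    sufficient = x$sufficient
  )
}

#' Sensitivity of power to the inter-chamber variance
#'
#' Re-estimates power across chamber counts after scaling the inter-chamber
#' variance of a base design (estimated variance 0.1807) by the given
#' multipliers, optionally pairing each power estimate with the matching
#' zero-effect type-I estimate (the tested term's reduction set to 0, other
#' effects kept).
#'
#' @param base_design An \code{sfe_design} whose \code{chamber_var} is the
#'   estimated variance 0.1807.
#' @param multipliers Variance scale factors (default 0.5, 1, 2, 5).
#' @param n_ch_values Chamber counts per treatment to sweep (default 2, 4, 6, 8).
#' @param n_sim,seed,alpha As in [estimate_power()].
#' @param include_null Also estimate the paired zero-effect type-I error for
#'   every cell.
#' @return A data frame with one row per (multiplier, chamber count,
#'   null/effect) cell, carrying all [estimate_power()] fields plus
#'   \code{var_multiplier}.
#' @export
variance_sensitivity <- function(base_design, multipliers = c(0.5, 1, 2, 5),
                                 n_ch_values = c(2, 4, 6, 8), n_sim = 1000,
                                 seed = 1, alpha = 0.05, include_null = FALSE) {
  stopifnot(inherits(base_design, "sfe_design"))
  if (abs(base_design$chamber_var - 0.1807) > 1e-9) {
    stop("variance sensitivity sweeps start from the estimated variance 0.1807",
         call. = FALSE)
  }
  term <- term_for_design(base_design)
  cell <- 0L
  rows <- list()
  for (m in multipliers) {
    for (nch in n_ch_values) {
      cell <- cell + 1L
      d <- modify_design(base_design, n_ch_per_trt = nch,
                         chamber_var = base_design$chamber_var * m)
      pe <- estimate_power(d, term, n_sim, seed, alpha, scenario = cell)
      row <- as.data.frame(pe)
      row$var_multiplier <- m
      rows[[length(rows) + 1L]] <- row
      if (include_null) {
        d0 <- null_counterpart(d)
        pe0 <- estimate_power(d0, term, n_sim, seed, alpha,
                              scenario = cell + 10000L)
        row0 <- as.data.frame(pe0)
        row0$var_multiplier <- m
        rows[[length(rows) + 1L]] <- row0
      }
    }
  }
  do.call(rbind, rows)
}

# rebuild a design with some fields replaced
modify_design <- function(design, ...) {
  ch <- list(...)
  eff <- if ("effects" %in% names(ch)) ch$effects else design$effects
  g <- function(k, d) if (k %in% names(ch)) ch[[k]] else d
  if (inherits(design, "sfe_design_short")) {
    short_term_design(g("n_ch_per_trt", design$n_ch_per_trt),
                      g("lambda", design$lambda), effects = eff,
                      chamber_var = g("chamber_var", design$chamber_var),
                      arms = design$arms)
  } else {
    long_term_design(g("n_ch_per_trt", design$n_ch_per_trt),
                     g("lambda", design$lambda), effects = eff,
                     sampling_times = g("sampling_times", design$sampling_times),
                     chamber_var = g("chamber_var", design$chamber_var),
                     time_var = g("time_var", design$time_var),
                     theta = g("theta", design$theta), arms = design$arms)
  }
}

# same design with the tested (highest-order) effect switched off
null_counterpart <- function(design) {
  eff <- design$effects
  new_eff <- if (design$arms == "combined") {
    intervention_effects(eff$itn_reduction, eff$ppf_reduction, 0)
  } else {
    intervention_effects(0, 0, 0)
  }
  modify_design(design, effects = new_eff)
}
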
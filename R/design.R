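#' Sampling schedule for a long-term experiment
#'
#' A long-term semi-field experiment runs for 12 weeks (3 months). Time is
#' normalised to \code{(0, 1]} over that duration, so the named sampling
#' frequencies map to K equally spaced sampling points \code{k/K}: monthly
#' gives 3 points, fortnightly 6, weekly 12 and daily 90. The schedule excludes
#' a baseline observation at t = 0; the first sample is taken at the first
#' sampling point.
#'
#' @param frequency_label One of \code{"monthly"}, \code{"fortnightly"}
#'   (alias \code{"biweekly"}), \code{"weekly"}, \code{"daily"}.
#' @return A strictly increasing numeric vector of normalised sampling times
#'   ending at 1.
#' @examples
#' sampling_times_for("monthly")   # 1/3, 2/3, 1
#' length(sampling_times_for("daily"))
#' @export
sampling_times_for <- function(frequency_label) {
  k <- switch(tolower(gsub("[-_ ]", "", frequency_label)),
    monthly = 3L, fortnightly = 6L, biweekly = 6L,
    weekly = 12L, daily = 90L,
    stop(sprintf("unknown sampling frequency '%s'", frequency_label), call. = FALSE)
  )
  seq_len(k) / k
}

new_sfe_design <- function(type, n_ch_per_trt, lambda, effects, chamber_var,
                           arms, extra = list()) {
  stopifnot(length(n_ch_per_trt) == 1, n_ch_per_trt >= 1,
            n_ch_per_trt == as.integer(n_ch_per_trt))
  stopifnot(length(lambda) == 1, is.finite(lambda), lambda > 0)
  stopifnot(length(chamber_var) == 1, is.finite(chamber_var), chamber_var >= 0)
  arms <- match.arg(arms, c("single", "combined"))
  stopifnot(inherits(effects, "sfe_effects"))
  structure(
    c(list(
      n_ch_per_trt = as.integer(n_ch_per_trt),
      lambda = lambda,
      effects = effects,
      chamber_var = chamber_var,
      arms = arms
    ), extra),
    class = c(paste0("sfe_design_", type), "sfe_design")
  )
}

#' Specify a short-term semi-field experiment
#'
#' Short-term experiments last 24-48 h with a single recapture occasion.
#' Counts are modelled as Poisson with a log-normal chamber random intercept:
#' \eqn{y_j \sim Pois(\lambda_j)} with
#' \eqn{\log \lambda_j = \beta_0 + \beta_I ITN_j [+ \beta_P PPF_j +
#' \beta_{I,P} ITN_j PPF_j] + c_j}, \eqn{c_j \sim N(0, \sigma_c^2)}.
#'
#' @param n_ch_per_trt Chambers per treatment arm.
#' @param lambda Expected number of mosquitoes recaptured per control chamber
#'   (a proxy for how many must be released); \eqn{\beta_0 = \log \lambda}.
#' @param effects An [intervention_effects()] object, or individual reductions
#'   via \code{itn_reduction}, \code{ppf_reduction}, \code{ixn_reduction}.
#' @param chamber_var Inter-chamber variance \eqn{\sigma_c^2} on the log scale.
#'   The value 0.1807, estimated from published mesocosm data, is the default.
#' @param arms \code{"single"} (control + ITN) or \code{"combined"} (full
#'   factorial: control, ITN, PPFa, ITN+PPFa).
#' @param itn_reduction,ppf_reduction,ixn_reduction Shorthand used when
#'   \code{effects} is not supplied.
#' @return An object of class \code{c("sfe_design_short", "sfe_design")}.
#' @examples
#' d <- short_term_design(4, lambda = 50, itn_reduction = 0.6)
#' d
#' @export
short_term_design <- function(n_ch_per_trt, lambda, effects = NULL,
                              chamber_var = 0.1807,
                              arms = c("single", "combined"),
                              itn_reduction = 0, ppf_reduction = 0,
                              ixn_reduction = 0) {
  arms <- match.arg(arms)
  if (is.null(effects)) {
    effects <- intervention_effects(itn_reduction, ppf_reduction, ixn_reduction)
  }
  new_sfe_design("short", n_ch_per_trt, lambda, effects, chamber_var, arms)
}

#' Specify a long-term semi-field experiment
#'
#' Long-term experiments run for 12 weeks (3 months) with repeated sampling.
#' Counts are negative-binomial with crossed normal random intercepts for
#' chamber and sampling occasion:
#' \eqn{y_{i,j} \sim NB(\lambda_{i,j}, \theta)} with
#' \eqn{\log \lambda_{i,j} = \beta_0 + \beta_T t + \beta_I ITN +
#' \beta_{T,I} t\,ITN + \ldots + \tau_i + c_j}. Intervention effects are
#' dynamic: they enter as time slopes, so the target reduction is reached at
#' the end of the experiment (normalised time t = 1). The static effects
#' (\eqn{\beta_T, \beta_I, \beta_P, \beta_{I,P}}) are zero in the generative
#' model but are always retained in the fitted model.
#'
#' @inheritParams short_term_design
#' @param lambda Expected mosquitoes sampled per control chamber per sampling
#'   occasion.
#' @param sampl_freq Sampling frequency label passed to [sampling_times_for()],
#'   or \code{NULL} if \code{sampling_times} is given directly.
#' @param sampling_times Optional explicit vector of strictly increasing
#'   normalised times in \code{(0, 1]} ending at 1.
#' @param time_var Between-occasion variance \eqn{\sigma_\tau^2} of the random
#'   time effect shared by all chambers (default 0.2266, estimated from
#'   published mesocosm data).
#' @param theta Negative-binomial dispersion; variance is
#'   \eqn{\lambda + \lambda^2/\theta}, so large \code{theta} recovers the
#'   Poisson.
#' @return An object of class \code{c("sfe_design_long", "sfe_design")}.
#' @examples
#' long_term_design(4, lambda = 10, sampl_freq = "weekly", itn_reduction = 0.6)
#' @export
long_term_design <- function(n_ch_per_trt, lambda, effects = NULL,
                             sampl_freq = "weekly", sampling_times = NULL,
                             chamber_var = 0.1807, time_var = 0.2266,
                             theta = 10, arms = c("single", "combined"),
                             itn_reduction = 0, ppf_reduction = 0,
                             ixn_reduction = 0) {
  arms <- match.arg(arms)
  if (is.null(effects)) {
    effects <- intervention_effects(itn_reduction, ppf_reduction, ixn_reduction)
  }
  if (is.null(sampling_times)) {
    sampling_times <- sampling_times_for(sampl_freq)
  } else {
    sampl_freq <- NA_character_
  }
  stopifnot(all(diff(sampling_times) > 0), all(sampling_times > 0),
            abs(sampling_times[length(sampling_times)] - 1) < 1e-12)
  stopifnot(length(time_var) == 1, is.finite(time_var), time_var >= 0)
  if (!is.finite(theta) || theta <= 0) {
    stop("'theta' must be a positive dispersion parameter", call. = FALSE)
  }
  new_sfe_design("long", n_ch_per_trt, lambda, effects, chamber_var, arms,
                 extra = list(sampling_times = sampling_times,
                              sampl_freq = sampl_freq,
                              time_var = time_var, theta = theta,
                              duration_label = "12 weeks"))
}

#' @export
print.sfe_design <- function(x, ...) {
  long <- inherits(x, "sfe_design_long")
  cat(sprintf("%s-term semi-field design (%s interventions)\n",
              if (long) "Long" else "Short", x$arms))
  n_arms <- if (x$arms == "single") 2L else 4L
  cat(sprintf("  chambers: %d per treatment x %d arms = %d total\n",
              x$n_ch_per_trt, n_arms, x$n_ch_per_trt * n_arms))
  cat(sprintf("  expected control count (lambda): %g per chamber%s\n",
              x$lambda, if (long) " per sampling occasion" else ""))
  cat(sprintf("  inter-chamber variance: %g\n", x$chamber_var))
  if (long) {
    cat(sprintf("  sampling: %d occasions over %s (sigma_tau^2 = %g, theta = %g)\n",
                length(x$sampling_times), x$duration_label, x$time_var, x$theta))
  }
  cat(sprintf("  effects: ITN %.0f%%, PPFa %.0f%%, interaction %.0f%%\n",
              100 * x$effects$itn_reduction, 100 * x$effects$ppf_reduction,
              100 * x$effects$ixn_reduction))
  invisible(x)
}

n_arms <- function(design) if (design$arms == "single") 2L else 4L

#' Generative fixed-effect coefficients of a design
#'
#' Translates the design's target effect sizes into the coefficients of its
#' generative model. For short-term designs the static intervention terms
#' carry the effects and all time terms are zero; for long-term designs the
#' effects are time slopes (reaching the target remainder at normalised time
#' t = 1) and the static intervention terms and the time main effect are zero.
#'
#' @param design An [short_term_design()] or [long_term_design()] object.
#' @return Named numeric vector with elements \code{beta0}, \code{beta_I},
#'   \code{beta_P}, \code{beta_IP}, \code{beta_T}, \code{beta_TI},
#'   \code{beta_TP}, \code{beta_TIP}.
#' @export
true_coefficients <- function(design) {
  stopifnot(inherits(design, "sfe_design"))
  eff <- design$effects
  b <- c(beta0 = log(design$lambda),
         beta_I = 0, beta_P = 0, beta_IP = 0,
         beta_T = 0, beta_TI = 0, beta_TP = 0, beta_TIP = 0)
  if (inherits(design, "sfe_design_short")) {
    b["beta_I"] <- eff$beta_itn
    if (design$arms == "combined") {
      b["beta_P"] <- eff$beta_ppf
      b["beta_IP"] <- eff$beta_ixn
    }
  } else {
    b["beta_TI"] <- eff$beta_itn
    if (design$arms == "combined") {
      b["beta_TP"] <- eff$beta_ppf
      b["beta_TIP"] <- eff$beta_ixn
    }
  }
  b
}

#' Build a grid of designs from candidate values per variable
#'
#' Expands candidate values for each design variable into the Cartesian
#' product of scenarios, one design per combination. Variables are crossed in
#' lexicographic order of their declaration: the first variable varies
#' slowest. Variable names follow the conventional R object names of the
#' framework: \code{n.ch.per.trt}, \code{lambda}, \code{itn.effect},
#' \code{ppf.effect}, \code{ixn.effect}, \code{chamber.var},
#' \code{sampl.freq}, \code{time.var}, \code{theta}.
#'
#' @param type One of \code{"short_single"}, \code{"short_combined"},
#'   \code{"long_single"}, \code{"long_combined"}.
#' @param vars Named list of candidate value vectors. Effects are proportions
#'   in \code{[0, 1)}. Unlisted variables take the design constructors'
#'   defaults.
#' @return A list of \code{sfe_design} objects; each carries the generating
#'   combination in attribute \code{"cell"}.
#' @examples
#' g <- build_design_grid("short_single",
#'                        list(`n.ch.per.trt` = c(2, 4), lambda = c(10, 50),
#'                             itn.effect = 0.6))
#' length(g)  # 4
#' @export
build_design_grid <- function(type, vars) {
  type <- match.arg(type, c("short_single", "short_combined",
                            "long_single", "long_combined"))
  stopifnot(is.list(vars), length(vars) > 0, !is.null(names(vars)))
  known <- c("n.ch.per.trt", "lambda", "itn.effect", "ppf.effect",
             "ixn.effect", "chamber.var", "sampl.freq", "time.var", "theta")
  bad <- setdiff(names(vars), known)
  if (length(bad)) {
    stop("unknown design variable(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(lengths(vars) == 0)) {
    stop("every design variable needs at least one candidate value", call. = FALSE)
  }
  # first declared variable varies slowest => reverse for expand.grid
  cells <- expand.grid(rev(vars), KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)[, names(vars), drop = FALSE]
  long <- grepl("^long", type)
  arms <- if (grepl("combined$", type)) "combined" else "single"
  lapply(seq_len(nrow(cells)), function(r) {
    cell <- as.list(cells[r, , drop = FALSE])
    g <- function(key, default) if (key %in% names(cell)) cell[[key]] else default
    eff <- intervention_effects(
      itn_reduction = g("itn.effect", 0),
      ppf_reduction = g("ppf.effect", 0),
      ixn_reduction = g("ixn.effect", 0)
    )
    d <- if (long) {
      long_term_design(g("n.ch.per.trt", 4), g("lambda", 10), effects = eff,
                       sampl_freq = g("sampl.freq", "weekly"),
                       chamber_var = g("chamber.var", 0.1807),
                       time_var = g("time.var", 0.2266),
                       theta = g("theta", 10), arms = arms)
    } else {
      short_term_design(g("n.ch.per.trt", 4), g("lambda", 50), effects = eff,
                        chamber_var = g("chamber.var", 0.1807), arms = arms)
    }
    attr(d, "cell") <- cell
    d
  })
}
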
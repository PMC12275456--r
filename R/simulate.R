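arm_table <- function(design) {
  arms <- if (design$arms == "single") {
    data.frame(itn = c(0L, 1L), ppf = c(0L, 0L))
  } else {
    data.frame(itn = c(0L, 1L, 0L, 1L), ppf = c(0L, 0L, 1L, 1L))
  }
  n_ch <- design$n_ch_per_trt
  data.frame(
    chamber = seq_len(nrow(arms) * n_ch),
    itn = rep(arms$itn, each = n_ch),
    ppf = rep(arms$ppf, each = n_ch)
  )
}

new_counts <- function(df, latent_chamber, latent_time = NULL) {
  attr(df, "latent_chamber") <- latent_chamber
  attr(df, "latent_time") <- latent_time
  class(df) <- c("sfe_counts", "data.frame")
  df
}

#' Simulate one short-term mosquito-count dataset
#'
#' Draws one dataset from the short-term generative model: a chamber random
#' intercept \eqn{c_j \sim N(0, \sigma_c^2)}, a log-linear fixed-effect
#' predictor for the intervention indicators, and a Poisson count per chamber.
#' Each chamber is observed once (a single recapture occasion).
#'
#' @param design A [short_term_design()].
#' @param seed Integer seed; the result is reproducible given
#'   \code{(design, seed)}.
#' @return A data frame of class \code{"sfe_counts"} with columns
#'   \code{chamber}, \code{itn}, \code{ppf}, \code{count}. The latent chamber
#'   effects are kept in attribute \code{"latent_chamber"} for diagnostics;
#'   they are never used by the fitting functions.
#' @examples
#' simulate_short(short_term_design(4, 50, itn_reduction = 0.6), seed = 1)
#' @export
simulate_short <- function(design, seed = NULL) {
  stopifnot(inherits(design, "sfe_design_short"))
  if (!is.null(seed)) set.seed(seed)
  tab <- arm_table(design)
  b <- true_coefficients(design)
  c_j <- stats::rnorm(nrow(tab), 0, sqrt(design$chamber_var))
  eta <- b["beta0"] + b["beta_I"] * tab$itn + b["beta_P"] * tab$ppf +
    b["beta_IP"] * tab$itn * tab$ppf + c_j
  tab$count <- stats::rpois(nrow(tab), exp(eta))
  new_counts(tab, latent_chamber = stats::setNames(c_j, tab$chamber))
}

#' Simulate one long-term mosquito-count dataset
#'
#' Draws one dataset from the long-term generative model: crossed random
#' intercepts \eqn{c_j \sim N(0, \sigma_c^2)} per chamber and
#' \eqn{\tau_i \sim N(0, \sigma_\tau^2)} per sampling occasion (shared across
#' all chambers at that occasion), dynamic intervention effects entering as
#' time slopes, and negative-binomial counts with dispersion \eqn{\theta}
#' (variance \eqn{\lambda + \lambda^2/\theta}). Following the generative
#' assumptions, the time main effect and all static intervention effects are
#' zero, so control chambers have a flat expected trajectory.
#'
#' @param design A [long_term_design()].
#' @inheritParams simulate_short
#' @return A data frame of class \code{"sfe_counts"} with columns
#'   \code{chamber}, \code{itn}, \code{ppf}, \code{time}, \code{count}, one
#'   row per chamber and sampling occasion. Latent draws are kept in
#'   attributes \code{"latent_chamber"} and \code{"latent_time"}.
#' @export
simulate_long <- function(design, seed = NULL) {
  stopifnot(inherits(design, "sfe_design_long"))
  if (!is.null(seed)) set.seed(seed)
  tab <- arm_table(design)
  times <- design$sampling_times
  b <- true_coefficients(design)
  c_j <- stats::rnorm(nrow(tab), 0, sqrt(design$chamber_var))
  tau_i <- stats::rnorm(length(times), 0, sqrt(design$time_var))
  df <- data.frame(
    chamber = rep(tab$chamber, each = length(times)),
    itn = rep(tab$itn, each = length(times)),
    ppf = rep(tab$ppf, each = length(times)),
    time = rep(times, times = nrow(tab))
  )
  eta <- b["beta0"] +
    b["beta_TI"] * df$time * df$itn +
    b["beta_TP"] * df$time * df$ppf +
    b["beta_TIP"] * df$time * df$itn * df$ppf +
    tau_i[match(df$time, times)] + c_j[df$chamber]
  df$count <- stats::rnbinom(nrow(df), mu = exp(eta), size = design$theta)
  new_counts(df, latent_chamber = stats::setNames(c_j, tab$chamber),
             latent_time = stats::setNames(tau_i, times))
}

#' Simulate a dataset from any semi-field design
#'
#' Generic front door dispatching to [simulate_short()] or [simulate_long()].
#'
#' @inheritParams simulate_short
#' @param design An \code{sfe_design} object.
#' @export
simulate_counts <- function(design, seed = NULL) {
  if (inherits(design, "sfe_design_short")) simulate_short(design, seed)
  else if (inherits(design, "sfe_design_long")) simulate_long(design, seed)
  else stop("'design' must be an sfe_design object", call. = FALSE)
}

#' Noise-free expected count trajectory of a long-term design
#'
#' Evaluates the exponentiated fixed-effect predictor of the long-term model
#' at each sampling time for one arm: a flat line at \code{lambda} for the
#' control arm (all static effects and the time main effect are zero) and
#' exponential decay towards \code{lambda} times the target remaining
#' proportion at the end of the experiment for treated arms.
#'
#' @param design A [long_term_design()].
#' @param arm One of \code{"control"}, \code{"itn"}, \code{"ppf"},
#'   \code{"itn_ppf"}.
#' @return Data frame with columns \code{time} and \code{mean}.
#' @examples
#' d <- long_term_design(4, 10, arms = "combined", itn_reduction = 0.8,
#'                       ppf_reduction = 0.7, ixn_reduction = 0.5)
#' expected_trajectory(d, "itn_ppf")  # decays to 10 * 0.03 at t = 1
#' @export
expected_trajectory <- function(design, arm = c("control", "itn", "ppf", "itn_ppf")) {
  stopifnot(inherits(design, "sfe_design_long"))
  arm <- match.arg(arm)
  ind <- switch(arm,
    control = c(0, 0), itn = c(1, 0), ppf = c(0, 1), itn_ppf = c(1, 1))
  if (design$arms == "single" && any(ind == c(0, 1))) {
    if (arm %in% c("ppf", "itn_ppf")) {
      stop("single-intervention designs have no PPFa arm", call. = FALSE)
    }
  }
  b <- true_coefficients(design)
  t <- design$sampling_times
  eta <- b["beta0"] + b["beta_TI"] * t * ind[1] + b["beta_TP"] * t * ind[2] +
    b["beta_TIP"] * t * ind[1] * ind[2]
  data.frame(time = t, mean = unname(exp(eta)))
}

#' Derive a reproducible per-dataset seed from a master seed
#'
#' Grid runs and power estimates derive one RNG substream per simulated
#' dataset from \code{(master seed, scenario index, replicate index)}, so that
#' any cell of a grid can be re-simulated in isolation and results are
#' invariant to execution order and parallel scheduling.
#'
#' @param master Master integer seed.
#' @param scenario Scenario (grid cell) index, from 1.
#' @param replicate Replicate index, from 1.
#' @return An integer seed in \code{[1, 2^31 - 1]}.
#' @export
substream_seed <- function(master, scenario = 1L, replicate = 1L) {
  m <- 2147483629 # largest prime below 2^31
  s <- (abs(as.numeric(master)) %% m) * 1048573 +
    as.numeric(scenario) * 7919 + as.numeric(replicate)
  as.integer(s %% m) + 1L
}

#' Write / read a count table as CSV
#'
#' The on-disk form has columns \code{chamber}, \code{itn}, \code{ppf},
#' \code{time} (long-term only) and \code{count}. Latent diagnostic
#' attributes are not serialised.
#'
#' @param x An \code{sfe_counts} data frame.
#' @param path File path.
#' @export
write_counts <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- utils::read.csv(path)
  need <- c("chamber", "itn", "ppf", "count")
  if (!all(need %in% names(df))) {
    stop("count CSV must have columns chamber, itn, ppf[, time], count", call. = FALSE)
  }
  new_counts(df, latent_chamber = NULL)
}
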
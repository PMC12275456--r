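#' Convert a percentage-reduction effect size to a log-scale model coefficient
#'
#' Intervention effect sizes are specified as the proportion of the mosquito
#' population removed by the end of the experiment. The complement, the
#' proportion remaining, is the multiplicative effect of the intervention on
#' expected abundance, so the corresponding coefficient of the log-linear model
#' is its natural logarithm: an 80\% reduction leaves 20\% of mosquitoes and
#' maps to a coefficient of \code{log(0.2)}.
#'
#' @param reduction Proportion(s) in \code{[0, 1)}: the fraction of the
#'   population removed. A reduction of 1 (total elimination) has no finite
#'   log-scale image and is rejected.
#' @return The coefficient \code{log(1 - reduction)}, vectorised over
#'   \code{reduction}.
#' @examples
#' reduction_to_log_effect(0.8)  # log(0.2) = -1.609
#' reduction_to_log_effect(0)    # no effect
#' @export
reduction_to_log_effect <- function(reduction) {
  stopifnot(is.numeric(reduction))
  if (any(!is.finite(reduction)) || any(reduction < 0) || any(reduction >= 1)) {
    stop("'reduction' must lie in [0, 1): total elimination has no finite log effect",
         call. = FALSE)
  }
  log1p(-reduction)
}

#' Proportion of mosquitoes remaining under two combined interventions
#'
#' When two interventions act without interacting, the proportion of the
#' population remaining is the product of the proportions each would leave on
#' its own: ITN removing 80\% and PPFa removing 70\% jointly leave
#' 20\% x 30\% = 6\%.
#'
#' @param itn_reduction,ppf_reduction Proportions in \code{[0, 1)} removed by
#'   each intervention alone.
#' @return The remaining proportion \code{(1 - itn_reduction) * (1 - ppf_reduction)}.
#' @seealso [apply_interaction()] for adding a synergistic interaction.
#' @export
combined_remaining <- function(itn_reduction, ppf_reduction) {
  check_proportion(itn_reduction, "itn_reduction")
  check_proportion(ppf_reduction, "ppf_reduction")
  (1 - itn_reduction) * (1 - ppf_reduction)
}

#' Apply an interaction effect to a no-interaction remainder
#'
#' A synergistic interaction removes an additional fraction of the mosquitoes
#' that would remain if the combined interventions acted independently: a 50\%
#' interaction halves the 6\% no-interaction remainder to 3\%. The log of
#' \code{1 - ixn_reduction} is the interaction coefficient of the model.
#'
#' @param remaining Proportion in \code{(0, 1]} left by the combined
#'   interventions without interaction.
#' @param ixn_reduction Additional reduction in \code{[0, 1)} applied to that
#'   remainder.
#' @return \code{remaining * (1 - ixn_reduction)}.
#' @export
apply_interaction <- function(remaining, ixn_reduction) {
  stopifnot(is.numeric(remaining))
  if (any(!is.finite(remaining)) || any(remaining <= 0) || any(remaining > 1)) {
    stop("'remaining' must lie in (0, 1]", call. = FALSE)
  }
  check_proportion(ixn_reduction, "ixn_reduction")
  remaining * (1 - ixn_reduction)
}

# shared domain check for reduction-type proportions
check_proportion <- function(x, name) {
  stopifnot(is.numeric(x))
  if (any(!is.finite(x)) || any(x < 0) || any(x >= 1)) {
    stop(sprintf("'%s' must lie in [0, 1)", name), call. = FALSE)
  }
  invisible(x)
}

#' Bundle the target effect sizes of an experimental scenario
#'
#' @param itn_reduction Proportion of mosquitoes removed by the ITN.
#' @param ppf_reduction Proportion removed by PPFa (combined designs only).
#' @param ixn_reduction Additional interaction reduction applied to the
#'   no-interaction remainder of the combined arm.
#' @return An object of class \code{"sfe_effects"}: a list with the three
#'   reductions and their log-scale coefficient images.
#' @export
intervention_effects <- function(itn_reduction = 0, ppf_reduction = 0,
                                 ixn_reduction = 0) {
  check_proportion(itn_reduction, "itn_reduction")
  check_proportion(ppf_reduction, "ppf_reduction")
  check_proportion(ixn_reduction, "ixn_reduction")
  structure(
    list(
      itn_reduction = itn_reduction,
      ppf_reduction = ppf_reduction,
      ixn_reduction = ixn_reduction,
      beta_itn = reduction_to_log_effect(itn_reduction),
      beta_ppf = reduction_to_log_effect(ppf_reduction),
      beta_ixn = reduction_to_log_effect(ixn_reduction)
    ),
    class = "sfe_effects"
  )
}

#' @export
print.sfe_effects <- function(x, ...) {
  cat("Intervention effect sizes (% reduction -> log coefficient)\n")
  cat(sprintf("  ITN:         %4.0f%%  -> %8.4f\n", 100 * x$itn_reduction, x$beta_itn))
  cat(sprintf("  PPFa:        %4.0f%%  -> %8.4f\n", 100 * x$ppf_reduction, x$beta_ppf))
  cat(sprintf("  interaction: %4.0f%%  -> %8.4f\n", 100 * x$ixn_reduction, x$beta_ixn))
  invisible(x)
}
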
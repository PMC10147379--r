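# Analytic power for binary-outcome two-sample MR.

#' Power of a binary-outcome MR analysis
#'
#' Analytic normal-approximation power for a two-sided Wald test of the IVW
#' estimate against the null, in the style of published MR power
#' calculators. The non-centrality parameter is
#' `NCP = n K (1 - K) R^2 (log OR)^2`, with `n` the total outcome sample
#' size, `K` the case fraction and `R^2` the variance of the exposure
#' explained by the instrument; power is
#' `pnorm(sqrt(NCP) - z) + pnorm(-sqrt(NCP) - z)` with
#' `z = qnorm(1 - alpha / 2)`.
#'
#' @param n_total total outcome sample size (cases + controls).
#' @param case_fraction case proportion K in (0, 1).
#' @param r2_instrument instrument R^2 in (0, 1).
#' @param or_alt odds ratio under the alternative (> 0), per exposure unit.
#' @param alpha two-sided significance level (default 0.05).
#' @return power in `[0, 1]`.
#' @export
mr_power_binary <- function(n_total, case_fraction, r2_instrument, or_alt,
                            alpha = 0.05) {
  if (!is_scalar_number(n_total) || n_total <= 0) abort("`n_total` must be > 0")
  if (!is_scalar_number(case_fraction) || case_fraction <= 0 || case_fraction >= 1) {
    abort("`case_fraction` must lie in (0, 1)")
  }
  if (!is_scalar_number(r2_instrument) || r2_instrument <= 0 || r2_instrument >= 1) {
    abort("`r2_instrument` must lie in (0, 1)")
  }
  if (!is_scalar_number(or_alt) || or_alt <= 0) abort("`or_alt` must be > 0")
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie in (0, 1)")
  }
  ncp <- n_total * r2_instrument * case_fraction * (1 - case_fraction) *
    log(or_alt)^2
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(sqrt(ncp) - z) + stats::pnorm(-sqrt(ncp) - z)
}

#' Smallest detectable odds ratio
#'
#' The smallest odds ratio at least 1 whose power under
#' [mr_power_binary()] reaches `target_power`, found by bisection to a
#' tolerance of 1e-6 on the OR scale.
#'
#' @inheritParams mr_power_binary
#' @param target_power desired power, in `(alpha, 1)`.
#' @return odds ratio >= 1.
#' @export
detectable_or <- function(n_total, case_fraction, r2_instrument,
                          target_power = 0.8, alpha = 0.05) {
  if (!is_scalar_number(target_power) || target_power <= alpha ||
      target_power >= 1) {
    abort("`target_power` must lie in (alpha, 1)")
  }
  pw <- function(or) mr_power_binary(n_total, case_fraction, r2_instrument,
                                     or, alpha)
  lo <- 1
  hi <- 1000
  if (pw(hi) < target_power) abort("no OR below 1000 reaches the target power")
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (pw(mid) >= target_power) hi <- mid else lo <- mid
  }
  hi
}

#' Power grid over a range of odds ratios
#'
#' @inheritParams mr_power_binary
#' @param or_grid odds ratios to evaluate (default `seq(1, 2, by = 0.05)`).
#' @return data.frame with columns `or` and `power`.
#' @export
power_grid <- function(n_total, case_fraction, r2_instrument,
                       or_grid = seq(1, 2, by = 0.05), alpha = 0.05) {
  data.frame(or = or_grid,
             power = vapply(or_grid, function(o) {
               mr_power_binary(n_total, case_fraction, r2_instrument, o, alpha)
             }, numeric(1L)))
}
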
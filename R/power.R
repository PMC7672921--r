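#' Effect size / power target
#'
#' Bundles the standardized effect size `delta` (on the `sigma = 1` scale,
#' i.e. delta/sigma), the two-sided significance level and the target power.
#'
#' @param delta standardized effect size, `> 0` for target-precision
#'   conversion.
#' @param alpha two-sided significance level, in `(0, 1)`. Default 0.05.
#' @param power target power, in `(0, 1)`. Default 0.9.
#' @return An object of class `sw_power_spec`.
#' @export
power_spec <- function(delta, alpha = 0.05, power = 0.9) {
  sw_check(length(delta) == 1 && is.finite(delta) && delta >= 0,
           "delta must be a non-negative number")
  sw_check(length(alpha) == 1 && alpha > 0 && alpha < 1,
           "alpha must lie in (0, 1)")
  sw_check(length(power) == 1 && power > 0 && power < 1,
           "power must lie in (0, 1)")
  structure(list(delta = as.numeric(delta), alpha = as.numeric(alpha),
                 power = as.numeric(power)),
            class = "sw_power_spec")
}

#' Precision needed to detect an effect with given power
#'
#' Under the normal approximation, detecting a standardized effect `delta`
#' with the stated power at a two-sided significance level `alpha` requires
#' treatment-effect precision (at `sigma2 = 1`)
#' `((z_{1-alpha/2} + z_{power}) / delta)^2`. Monotone decreasing in
#' `delta`, increasing in `power`.
#'
#' @param spec an [power_spec()] (or a bare `delta`, combined with `alpha`
#'   and `power` arguments).
#' @param alpha,power used only when `spec` is a bare numeric effect size.
#' @return Required precision (a single number).
#' @examples
#' required_precision(power_spec(0.3))  # about 116.75
#' @export
required_precision <- function(spec, alpha = 0.05, power = 0.9) {
  if (!inherits(spec, "sw_power_spec")) spec <- power_spec(spec, alpha, power)
  sw_check(spec$delta > 0, "delta must be positive to convert to precision")
  ((qnorm(1 - spec$alpha / 2) + qnorm(spec$power)) / spec$delta)^2
}

#' Power of a fixed design, optionally under a different analysis polynomial
#'
#' Computes `Phi(|delta| * sqrt(precision) - z_{1-alpha/2})`, the standard
#' normal-approximation power with the minor tail ignored (`delta = 0`
#' returns `alpha / 2`). `analysis_degree` re-evaluates the design's
#' precision with a different polynomial degree for the secular trend than
#' the scenario's, which is how sensitivity of a chosen design to the
#' assumed form of the time effect is assessed: precision can only decrease
#' as nuisance degrees are added.
#'
#' @param scenario an [sw_scenario()].
#' @param design an [sw_design()].
#' @param delta standardized effect size delta/sigma.
#' @param alpha two-sided significance level.
#' @param analysis_degree optional polynomial degree overriding
#'   `scenario$degree` for the analysis model.
#' @return Power (a single number in `(0, 1)`).
#' @export
design_power <- function(scenario, design, delta, alpha = 0.05,
                         analysis_degree = NULL) {
  sw_check(inherits(scenario, "sw_scenario"), "scenario must be an sw_scenario")
  sw_check(length(delta) == 1 && is.finite(delta) && delta >= 0,
           "delta must be a non-negative number")
  if (!is.null(analysis_degree)) {
    scenario <- sw_scenario(scenario$K, scenario$M, scenario$rho,
                            scenario$tau, scenario$sigma2, analysis_degree)
  }
  prec <- treatment_precision(scenario, design)
  pnorm(abs(delta) * sqrt(prec) - qnorm(1 - alpha / 2))
}
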
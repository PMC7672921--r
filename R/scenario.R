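#' Define a stepped wedge trial scenario
#'
#' A scenario fixes the constants of the design problem. One eligible
#' participant presents at each of `K` clusters at each of the regularly
#' spaced times `1/M, 2/M, ..., 1` (the trial duration is scaled to one time
#' unit, so `M` is both the arrival rate and the number of recruitment slots
#' per cluster). Each recruited participant contributes one continuous
#' outcome, modelled as a degree-`degree` polynomial secular trend plus an
#' immediate treatment effect and a residual with variance `sigma2`.
#'
#' Residuals of two participants from the same cluster recruited at times
#' `t1` and `t2` have correlation `rho * tau^abs(t1 - t2)`; residuals from
#' different clusters are independent. `tau = 1` gives the classic
#' exchangeable (Hussey-Hughes-type) structure; `tau < 1` lets the
#' intracluster correlation decay over the trial, so that two participants
#' sampled at opposite ends of the trial have correlation `rho * tau`.
#'
#' `K` must be even: the search machinery works in the space of designs that
#' are invariant under reversing time and swapping the control and
#' intervention conditions, which pairs each cluster with a mirror partner.
#'
#' @param K number of clusters; a positive even integer.
#' @param M recruitment slots per cluster; a positive integer.
#' @param rho intracluster correlation at zero time separation; in `[0, 1)`.
#' @param tau correlation decay over the whole (unit) trial duration; in
#'   `(0, 1]`.
#' @param sigma2 residual outcome variance; positive. Default 1. Precision is
#'   always reported on the `sigma2 = 1` scale.
#' @param degree polynomial degree of the secular time trend; a non-negative
#'   integer. Default 6.
#'
#' @return An object of class `sw_scenario`: a list with the validated
#'   fields above.
#' @examples
#' sw_scenario(K = 4, M = 6, rho = 0.05, tau = 0.2, degree = 1)
#' @export
sw_scenario <- function(K, M, rho, tau, sigma2 = 1, degree = 6L) {
  sw_check(is_count(K, 2L), "K must be an integer >= 2")
  sw_check(K %% 2 == 0, "K must be even (reversal-symmetric design space)")
  sw_check(is_count(M, 1L), "M must be a positive integer")
  sw_check(length(rho) == 1 && is.finite(rho) && rho >= 0 && rho < 1,
           "rho must satisfy 0 <= rho < 1")
  sw_check(length(tau) == 1 && is.finite(tau) && tau > 0 && tau <= 1,
           "tau must satisfy 0 < tau <= 1")
  sw_check(length(sigma2) == 1 && is.finite(sigma2) && sigma2 > 0,
           "sigma2 must be positive")
  sw_check(is_count(degree, 0L), "degree must be a non-negative integer")
  structure(
    list(K = as.integer(K), M = as.integer(M), rho = as.numeric(rho),
         tau = as.numeric(tau), sigma2 = as.numeric(sigma2),
         degree = as.integer(degree)),
    class = "sw_scenario"
  )
}

#' @export
print.sw_scenario <- function(x, ...) {
  cat(sprintf(
    "Stepped wedge scenario: K = %d clusters, M = %d slots/cluster\n",
    x$K, x$M))
  cat(sprintf("  correlation rho = %g decaying by tau = %g over the trial\n",
              x$rho, x$tau))
  cat(sprintf("  sigma2 = %g, polynomial time trend of degree %d\n",
              x$sigma2, x$degree))
  invisible(x)
}

# number of fixed-effect columns: 1 + t + ... + t^degree + treatment
n_params <- function(scenario) scenario$degree + 2L
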
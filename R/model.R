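#' Within-cluster correlation matrix at given recruitment times
#'
#' Entry `(i, j)` is `rho * tau^abs(t_i - t_j)` for `i != j` and 1 on the
#' diagonal. For `rho < 1` and `tau > 0` the matrix is positive definite:
#' it is the sum of a scaled Ornstein-Uhlenbeck kernel and an independent
#' residual component.
#'
#' @param scenario an [sw_scenario()].
#' @param times strictly increasing recruitment times in `(0, 1]` (one
#'   arrival per slot, so ties are forbidden).
#' @return Symmetric positive definite correlation matrix.
#' @export
correlation_block <- function(scenario, times) {
  sw_check(inherits(scenario, "sw_scenario"), "scenario must be an sw_scenario")
  sw_check(is.numeric(times) && length(times) >= 1 && all(is.finite(times)),
           "times must be a non-empty finite numeric vector")
  sw_check(all(diff(times) > 0) || length(times) == 1,
           "times must be strictly increasing (one arrival per slot)")
  sw_check(scenario$rho < 1, "rho must be < 1")
  R <- scenario$rho * scenario$tau^abs(outer(times, times, "-"))
  diag(R) <- 1
  R
}

# Fixed-effect basis over [0,1]: either the documented raw powers
# [1, t, ..., t^d] or shifted Legendre polynomials of the same degrees (an
# invertible reparameterization used internally for conditioning; the
# treatment variance is identical under either basis).
sw_basis <- function(times, degree, basis = c("raw", "orthogonal")) {
  basis <- match.arg(basis)
  m <- length(times)
  B <- matrix(0, m, degree + 1L)
  if (basis == "raw") {
    for (d in 0:degree) B[, d + 1L] <- times^d
  } else {
    x <- 2 * times - 1
    B[, 1L] <- 1
    if (degree >= 1) B[, 2L] <- x
    if (degree >= 2) {
      for (nn in 1:(degree - 1L)) {
        B[, nn + 2L] <- ((2 * nn + 1) * x * B[, nn + 1L] - nn * B[, nn]) /
          (nn + 1)
      }
    }
  }
  B
}

# recruited slots of cluster k
cluster_slots <- function(design, k) which(design$recruit[k, ] == 1L)

#' Per-cluster fixed-effect design matrices
#'
#' For each cluster, one row per recruited slot `s` (in slot order):
#' `[1, t, t^2, ..., t^degree, 1(s >= crossover[k])]` with `t = s / M`.
#' The last column is the treatment indicator; a participant recruited
#' exactly at the cross-over slot is under the intervention.
#'
#' @param scenario an [sw_scenario()].
#' @param design an [sw_design()] matching the scenario dimensions.
#' @param basis `"raw"` (the documented power basis, default) or
#'   `"orthogonal"` (shifted Legendre time columns).
#' @return List of `m_k x (degree + 2)` matrices, one per cluster (0-row
#'   matrices for clusters recruiting nobody).
#' @export
design_matrix <- function(scenario, design, basis = c("raw", "orthogonal")) {
  basis <- match.arg(basis)
  sw_check(inherits(scenario, "sw_scenario"), "scenario must be an sw_scenario")
  assert_design(design, scenario)
  p <- n_params(scenario)
  lapply(seq_len(scenario$K), function(k) {
    slots <- cluster_slots(design, k)
    if (!length(slots)) return(matrix(0, 0, p))
    t <- slots / scenario$M
    cbind(sw_basis(t, scenario$degree, basis),
          as.numeric(slots >= design$crossover[k]))
  })
}

# per-cluster information contributions Z_k' R_k^-1 Z_k (correlation scale,
# i.e. sigma2 = 1); total information in the model's units is the sum / sigma2
cluster_infos <- function(scenario, design, basis = "orthogonal") {
  Zs <- design_matrix(scenario, design, basis)
  lapply(seq_len(scenario$K), function(k) {
    Z <- Zs[[k]]
    if (nrow(Z) == 0) return(matrix(0, ncol(Z), ncol(Z)))
    slots <- cluster_slots(design, k)
    R <- correlation_block(scenario, slots / scenario$M)
    crossprod(Z, solve(R, Z))
  })
}

#' GLS information matrix of a design
#'
#' Returns `Z' V^-1 Z`, accumulated cluster by cluster (the covariance of
#' outcomes is block-diagonal across clusters, so its inverse is too). The
#' rows of `Z` are as in [design_matrix()].
#'
#' @inheritParams design_matrix
#' @return Symmetric positive semi-definite `(degree + 2) x (degree + 2)`
#'   matrix.
#' @export
information_matrix <- function(scenario, design,
                               basis = c("raw", "orthogonal")) {
  basis <- match.arg(basis)
  sw_check(design_n(design) >= 1, "empty design: nobody is recruited")
  Reduce(`+`, cluster_infos(scenario, design, basis)) / scenario$sigma2
}

# shared GLS core: unit-sigma2 information (orthogonal basis) and the
# treatment-effect variance on the sigma2 = 1 scale; classed errors on
# non-identifiable designs
sw_gls <- function(scenario, design) {
  p <- n_params(scenario)
  n <- design_n(design)
  if (n < p)
    sw_stop(sprintf(
      "non-identifiable design: n = %d recruited but %d fixed-effect parameters",
      n, p), "swhunt_identifiability")
  treat <- unlist(lapply(seq_len(scenario$K), function(k) {
    slots <- cluster_slots(design, k)
    slots >= design$crossover[k]
  }))
  if (all(treat) || !any(treat))
    sw_stop(paste0(
      "non-identifiable design: every recruited participant is under the ",
      if (all(treat)) "intervention" else "control",
      " condition, so the treatment effect is confounded"),
      "swhunt_identifiability")
  W <- Reduce(`+`, cluster_infos(scenario, design, "orthogonal"))
  ch <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(ch))
    sw_stop(paste0(
      "non-identifiable design: singular information matrix (treatment ",
      "indicator confounded with the polynomial time trend, e.g. too few ",
      "distinct recruitment times)"), "swhunt_identifiability")
  v <- chol2inv(ch)[p, p]
  if (!is.finite(v) || v <= 0)
    sw_stop("non-identifiable design: singular information matrix",
            "swhunt_identifiability")
  list(var_unit = v, W_unit = W)
}

#' Variance and precision of the treatment effect estimator
#'
#' `treatment_variance()` returns the `(treatment, treatment)` entry of
#' `(Z' V^-1 Z)^-1`, the exact GLS variance of the estimated treatment
#' effect (proportional to `sigma2`). `treatment_precision()` returns its
#' inverse computed with `sigma2 = 1` — the scale on which precision is
#' always reported and compared.
#'
#' Internally the polynomial time columns are reparameterized to a shifted
#' Legendre basis for numerical conditioning; the treatment coefficient, and
#' hence its variance, is invariant to that choice.
#'
#' @inheritParams design_matrix
#' @return A single number.
#' @examples
#' sc <- sw_scenario(2, 1, rho = 0, tau = 1, degree = 0)
#' d <- sw_design(c(1, 2), matrix(1, 2, 1))
#' treatment_variance(sc, d)  # 2 * sigma2
#' @export
treatment_variance <- function(scenario, design) {
  sw_check(inherits(scenario, "sw_scenario"), "scenario must be an sw_scenario")
  assert_design(design, scenario)
  scenario$sigma2 * sw_gls(scenario, design)$var_unit
}

#' @rdname treatment_variance
#' @export
treatment_precision <- function(scenario, design) {
  sw_check(inherits(scenario, "sw_scenario"), "scenario must be an sw_scenario")
  assert_design(design, scenario)
  1 / sw_gls(scenario, design)$var_unit
}
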
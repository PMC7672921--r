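# Independent oracles used across the suite.

# dense single-matrix GLS: build the full n x n covariance, the raw-basis
# design matrix, and invert once; returns precision at sigma2 = 1
dense_precision <- function(scenario, design) {
  Zs <- design_matrix(scenario, design, basis = "raw")
  Z <- do.call(rbind, Zs)
  n <- nrow(Z)
  V <- matrix(0, n, n)
  off <- 0
  for (k in seq_len(scenario$K)) {
    s <- which(design$recruit[k, ] == 1)
    if (length(s)) {
      V[off + seq_along(s), off + seq_along(s)] <-
        scenario$sigma2 * correlation_block(scenario, s / scenario$M)
      off <- off + length(s)
    }
  }
  W <- crossprod(Z, solve(V, Z))
  p <- ncol(Z)
  scenario$sigma2 / solve(W)[p, p]
}

# closed-form inverse of the exchangeable correlation (1-rho) I + rho J
exchangeable_inverse <- function(m, rho) {
  (diag(m) - rho * matrix(1, m, m) / (1 - rho + m * rho)) / (1 - rho)
}

# draw random symmetric designs until one is identifiable for the scenario
random_identifiable_design <- function(scenario, max_tries = 200) {
  for (i in seq_len(max_tries)) {
    d <- random_symmetric_design(scenario$K, scenario$M)
    ok <- tryCatch({
      treatment_precision(scenario, d)
      TRUE
    }, swhunt_error = function(e) FALSE)
    if (ok) return(d)
  }
  stop("could not draw an identifiable design")
}

cluster_times_of <- function(design, k, M) {
  which(design$recruit[k, ] == 1) / M
}

# all reversal-symmetric designs for K = 2 (half = one cluster)
enumerate_symmetric_K2 <- function(M) {
  out <- vector("list", (M + 1) * 2^M)
  i <- 0
  for (cc in seq_len(M + 1)) {
    for (b in 0:(2^M - 1)) {
      rec <- matrix(as.integer(intToBits(b)[seq_len(M)]), 1, M)
      i <- i + 1
      out[[i]] <- symmetrize(list(crossover = cc, recruit = rec))
    }
  }
  out
}

# precision of many designs at once (engine batch path); NA when
# non-identifiable
batch_precision <- function(scenario, designs) {
  ev <- swhunt:::cpp_eval_many(
    list(K = scenario$K, M = scenario$M, rho = scenario$rho,
         tau = scenario$tau, degree = scenario$degree),
    lapply(designs, function(d) list(d$crossover, d$recruit)))
  data.frame(n = ev$n, precision = ev$precision, ok = ev$ok)
}
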
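test_that("correlation_block implements rho * tau^|dt| with unit diagonal", {
  sc <- sw_scenario(2, 10, rho = 0.05, tau = 0.2)
  R <- correlation_block(sc, c(0.001, 1))
  expect_equal(diag(R), c(1, 1))
  # nearly co-located pair approaches rho; ends of the trial give rho * tau
  expect_equal(R[1, 2], 0.05 * 0.2^0.999)
  expect_lt(R[1, 2] - 0.05 * 0.2, 1e-3)
  Rnear <- correlation_block(sc, c(0.5, 0.5 + 1e-9))
  expect_equal(Rnear[1, 2], 0.05, tolerance = 1e-6)

  # tau = 1: exchangeable, all off-diagonals rho
  sc1 <- sw_scenario(2, 10, rho = 0.3, tau = 1)
  R1 <- correlation_block(sc1, c(0.1, 0.4, 1))
  expect_equal(R1[upper.tri(R1)], rep(0.3, 3))

  expect_error(correlation_block(sc, c(0.5, 0.5)), class = "swhunt_error")
  expect_error(correlation_block(sc, c(0.7, 0.2)), class = "swhunt_error")
  expect_error(sw_scenario(2, 10, rho = 1, tau = 1), class = "swhunt_error")
  # positive definiteness across the correlation grid
  for (rho in c(0, 0.25, 0.9)) for (tau in c(0.04, 0.2, 1)) {
    sck <- sw_scenario(2, 20, rho, tau)
    ev <- eigen(correlation_block(sck, (1:20) / 20), only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("design_matrix builds [1, t, ..., t^d, treatment] rows per cluster", {
  sc <- sw_scenario(2, 2, rho = 0.05, tau = 0.5, degree = 0)
  d <- sw_design(c(2, 1), matrix(1L, 2, 2))
  Z <- design_matrix(sc, d)
  # cluster 1 crosses at slot 2: rows [1,0], [1,1]
  expect_equal(Z[[1]], cbind(c(1, 1), c(0, 1)))

  # never-crossing cluster has an all-zero treatment column
  sc2 <- sw_scenario(2, 3, 0.05, 0.5, degree = 1)
  d2 <- sw_design(c(1, 4), matrix(1L, 2, 3))
  Z2 <- design_matrix(sc2, d2)
  expect_equal(Z2[[2]][, 3], c(0, 0, 0))
  # participant recruited exactly at cross-over is under the intervention
  expect_equal(Z2[[1]][, 3], c(1, 1, 1))
  d3 <- sw_design(c(2, 3), matrix(1L, 2, 3))
  expect_equal(design_matrix(sc2, d3)[[1]][, 3], c(0, 1, 1))
  # time columns are s/M powers
  expect_equal(Z2[[1]][, 2], c(1, 2, 3) / 3)
})

test_that("information matrix matches independence and exchangeable closed forms", {
  set.seed(42)
  # rho = 0: information is Z'Z / sigma2
  sc <- sw_scenario(4, 6, rho = 0, tau = 0.5, sigma2 = 2, degree = 2)
  d <- random_identifiable_design(sc)
  Z <- do.call(rbind, design_matrix(sc, d))
  expect_equal(information_matrix(sc, d), crossprod(Z) / 2, tolerance = 1e-12)

  # tau = 1: per-cluster information from the closed-form inverse of
  # (1 - rho) I + rho J
  sc1 <- sw_scenario(4, 8, rho = 0.25, tau = 1, degree = 1)
  d1 <- random_identifiable_design(sc1)
  W_closed <- 0
  Zs <- design_matrix(sc1, d1)
  for (k in 1:4) {
    m <- nrow(Zs[[k]])
    if (m == 0) next
    W_closed <- W_closed + crossprod(Zs[[k]],
                                     exchangeable_inverse(m, 0.25) %*% Zs[[k]])
  }
  expect_equal(information_matrix(sc1, d1), W_closed, tolerance = 1e-12)

  expect_error(information_matrix(sc, sw_design(c(2, 2, 2, 2),
                                                matrix(0L, 4, 6))),
               class = "swhunt_error")
})

test_that("treatment variance matches hand GLS and the dense oracle", {
  # two clusters, one slot, intercept-only trend: Var = 2 sigma2
  for (s2 in c(1, 3)) {
    sc <- sw_scenario(2, 1, rho = 0.1, tau = 1, sigma2 = s2, degree = 0)
    d <- sw_design(c(1, 2), matrix(1L, 2, 1))
    expect_equal(treatment_variance(sc, d), 2 * s2, tolerance = 1e-12)
    expect_equal(treatment_precision(sc, d), 0.5, tolerance = 1e-12)
  }
  set.seed(7)
  for (i in 1:10) {
    sc <- sw_scenario(sample(c(2, 4), 1), sample(3:8, 1),
                      runif(1, 0, 0.3), runif(1, 0.1, 1),
                      sigma2 = runif(1, 0.5, 2), degree = sample(0:2, 1))
    d <- random_identifiable_design(sc)
    expect_equal(treatment_precision(sc, d), dense_precision(sc, d),
                 tolerance = 1e-9)
  }
})

test_that("non-identifiable designs raise classed identifiability errors", {
  sc <- sw_scenario(2, 4, 0.05, 0.5, degree = 0)
  # all clusters under control throughout
  expect_error(treatment_variance(sc, sw_design(c(5, 5), matrix(1L, 2, 4))),
               class = "swhunt_identifiability")
  # all under intervention
  expect_error(treatment_variance(sc, sw_design(c(1, 1), matrix(1L, 2, 4))),
               class = "swhunt_identifiability")
  # K = 2, M = 1, linear trend: time confounded with intercept
  sc2 <- sw_scenario(2, 1, 0.05, 0.5, degree = 1)
  expect_error(treatment_variance(sc2, sw_design(c(1, 2), matrix(1L, 2, 1))),
               class = "swhunt_identifiability")
  # fewer recruits than parameters
  sc3 <- sw_scenario(2, 4, 0.05, 0.5, degree = 6)
  d3 <- sw_design(c(3, 3), rbind(c(1L, 0L, 0L, 0L), c(0L, 0L, 0L, 1L)))
  expect_error(treatment_variance(sc3, d3), class = "swhunt_identifiability")
})

test_that("treatment variance is invariant to the polynomial basis", {
  set.seed(11)
  for (i in 1:5) {
    sc <- sw_scenario(4, 10, 0.1, 0.3, degree = 4)
    d <- random_identifiable_design(sc)
    W_raw <- information_matrix(sc, d, basis = "raw")
    p <- nrow(W_raw)
    v_raw <- sc$sigma2 * solve(W_raw)[p, p]
    expect_equal(treatment_variance(sc, d), v_raw, tolerance = 1e-9)
    # and under an arbitrary invertible reparameterization of the trend
    # columns (treatment column kept): recompute the GLS variance with
    # Z %*% A instead of Z
    A <- diag(p)
    repeat {
      A[1:(p - 1), 1:(p - 1)] <- matrix(rnorm((p - 1)^2), p - 1)
      if (abs(det(A)) > 1e-2) break
    }
    Zs <- design_matrix(sc, d, basis = "raw")
    W_re <- 0
    for (k in seq_len(sc$K)) {
      if (nrow(Zs[[k]]) == 0) next
      ZA <- Zs[[k]] %*% A
      R <- correlation_block(sc, cluster_times_of(d, k, sc$M))
      W_re <- W_re + crossprod(ZA, solve(R, ZA))
    }
    v_re <- sc$sigma2 * solve(W_re)[p, p]
    expect_equal(v_re, v_raw, tolerance = 1e-9)
  }
})

test_that("rank-one downdates equal from-scratch recomputation", {
  set.seed(21)
  sc <- sw_scenario(4, 8, 0.1, 0.3, degree = 1)
  d <- random_symmetric_design(4, 8, p = 0.9)
  st <- cluster_state(sc, d, 1)
  slot <- st$slots[2]
  W_down <- adjust_information(st, slot, "remove")
  d_edit <- d
  d_edit$recruit[1, slot] <- 0L
  expect_equal(unclass(W_down), cluster_state(sc, d_edit, 1)$W,
               tolerance = 1e-12, ignore_attr = TRUE)
  # remove then re-add restores the original contribution
  W_back <- adjust_information(attr(W_down, "state"), slot, "add")
  expect_equal(unclass(W_back), st$W, tolerance = 1e-10, ignore_attr = TRUE)
  # and the full restored state matches a rebuild
  st_back <- attr(W_back, "state")
  expect_equal(st_back$Rinv, st$Rinv, tolerance = 1e-10)
  expect_equal(st_back$G, st$G, tolerance = 1e-10)

  # removing an observation never increases any information eigenvalue
  for (i in 1:10) {
    dk <- random_symmetric_design(4, 8, p = runif(1, 0.5, 1))
    stk <- cluster_state(sc, dk, sample(1:4, 1))
    if (!length(stk$slots)) next
    s <- sample(stk$slots, 1)
    Wd <- adjust_information(stk, s, "remove")
    ev <- eigen(stk$W - Wd, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
  }
})

test_that("precision_after_changes equals full recomputation without mutating", {
  set.seed(31)
  sc <- sw_scenario(4, 6, 0.05, 0.2, degree = 1)
  d <- random_identifiable_design(sc)
  snapshot <- d
  expect_equal(precision_after_changes(sc, d, data.frame(
    cluster = integer(0), slot = integer(0), action = character(0))),
    treatment_precision(sc, d), tolerance = 1e-12)

  rec_slot <- which(d$recruit[1, ] == 1)[1]
  skip_if(is.na(rec_slot))
  ch <- data.frame(cluster = 1L, slot = rec_slot, action = "remove")
  d_edit <- d
  d_edit$recruit[1, rec_slot] <- 0L
  expect_equal(precision_after_changes(sc, d, ch),
               treatment_precision(sc, d_edit), tolerance = 1e-10)
  expect_identical(d, snapshot)

  # mirror-pair removal keeps the edited design reversal-symmetric
  ch2 <- data.frame(cluster = c(1L, 4L), slot = c(rec_slot, 7L - rec_slot),
                    action = "remove")
  d_edit2 <- d
  d_edit2$recruit[1, rec_slot] <- 0L
  d_edit2$recruit[4, 7 - rec_slot] <- 0L
  expect_equal(precision_after_changes(sc, d, ch2),
               treatment_precision(sc, d_edit2), tolerance = 1e-10)
  expect_length(validate_design(d_edit2, sc, check_symmetry = TRUE), 0)

  expect_error(precision_after_changes(sc, d, data.frame(
    cluster = c(1L, 1L), slot = c(rec_slot, rec_slot),
    action = c("remove", "add"))), class = "swhunt_error")
})
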
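test_that("improvement sweeps never lose precision and preserve n and symmetry", {
  set.seed(41)
  sc <- sw_scenario(4, 6, 0.05, 0.2, degree = 1)
  for (i in 1:8) {
    d <- random_identifiable_design(sc)
    p0 <- treatment_precision(sc, d)
    out <- improvement_sweep(d, sc)
    expect_gte(attr(out, "precision"), p0 - 1e-12)
    expect_equal(design_n(out), design_n(d))
    expect_length(validate_design(out, sc, check_symmetry = TRUE), 0)
    # reported precision is exact
    expect_equal(attr(out, "precision"), treatment_precision(sc, out),
                 tolerance = 1e-10)
  }
})

test_that("a per-n enumerated optimum is a fixed point of the sweep", {
  sc <- sw_scenario(2, 3, 0.05, 0.2, degree = 0)
  designs <- enumerate_symmetric_K2(3)
  ev <- batch_precision(sc, designs)
  for (nn in c(4, 6)) {
    idx <- which(ev$ok & ev$n == nn)
    best <- designs[[idx[which.max(ev$precision[idx])]]]
    out <- improvement_sweep(best, sc)
    expect_identical(out$crossover, best$crossover)
    expect_identical(out$recruit, best$recruit)
  }
})

test_that("a complete design only admits cross-over shifts", {
  sc <- sw_scenario(4, 5, 0.1, 0.5, degree = 1)
  d <- complete_diagonal_design(4, 5)
  out <- improvement_sweep(d, sc)
  expect_equal(design_n(out), 20)
  expect_identical(out$recruit, d$recruit)
})

test_that("greedy pair removal matches exhaustive evaluation", {
  sc <- sw_scenario(2, 2, 0.05, 0.2, degree = 0)
  d <- complete_diagonal_design(2, 2)
  # two mirror pairs: removing (1, s) together with (2, 3 - s)
  cand_prec <- vapply(1:2, function(s) {
    dd <- d
    dd$recruit[1, s] <- 0L
    dd$recruit[2, 3 - s] <- 0L
    treatment_precision(sc, dd)
  }, numeric(1))
  res <- greedy_remove_pair(d, sc)
  expect_equal(design_n(res$design), 2)
  expect_equal(res$precision, max(cand_prec), tolerance = 1e-12)
  expect_equal(res$pair$slot[1], which.max(cand_prec))
  expect_lte(res$precision, treatment_precision(sc, d))
})

test_that("greedy pair addition matches exhaustive evaluation", {
  sc <- sw_scenario(4, 6, 0.05, 0.2, degree = 1)
  d <- staircase_design(4, 6, 1)
  free <- which(d$recruit[1:2, , drop = FALSE] == 0L, arr.ind = TRUE)
  cand_prec <- apply(free, 1, function(rs) {
    dd <- d
    dd$recruit[rs[1], rs[2]] <- 1L
    dd$recruit[5 - rs[1], 7 - rs[2]] <- 1L
    treatment_precision(sc, dd)
  })
  res <- greedy_add_pair(d, sc)
  expect_equal(design_n(res$design), design_n(d) + 2)
  expect_equal(res$precision, max(cand_prec), tolerance = 1e-10)
  expect_gte(res$precision, treatment_precision(sc, d) - 1e-12)

  # adding then greedily removing cannot end below the starting precision
  back <- greedy_remove_pair(res$design, sc)
  expect_gte(back$precision, treatment_precision(sc, d) - 1e-10)

  # exhausted cases raise classed errors
  full <- complete_diagonal_design(4, 6)
  expect_error(greedy_add_pair(full, sc), class = "swhunt_exhausted")
  tiny <- sw_scenario(2, 2, 0.05, 0.2, degree = 0)
  d2 <- symmetrize(list(crossover = 2L, recruit = matrix(c(1L, 0L), 1, 2)))
  expect_error(greedy_remove_pair(d2, tiny), class = "swhunt_exhausted")
})

test_that("forward search records a deterministic, symmetric trajectory", {
  sc <- sw_scenario(4, 4, 0.05, 0.2, degree = 0)
  tr <- forward_search(sc, min_n = 2)
  r <- tr$records
  # n decreases by exactly 2 per removal, from MK down
  rem <- r[r$step_type == "remove", ]
  expect_equal(r$n[1], 16)
  expect_equal(diff(c(16, rem$n)), rep(-2, nrow(rem)))
  # sweeps never decrease precision at fixed n; removals never increase it
  for (i in 2:nrow(r)) {
    if (r$step_type[i] == "sweep") {
      expect_gte(r$precision[i], r$precision[i - 1] - 1e-12)
    } else {
      expect_lte(r$precision[i], r$precision[i - 1] + 1e-12)
    }
  }
  # every iterate is reversal-symmetric and exactly re-evaluates
  for (j in seq_along(tr$designs)) {
    expect_length(validate_design(tr$designs[[j]], sc, check_symmetry = TRUE),
                  0)
  }
  spot <- seq(1, nrow(r), by = 4)
  expect_equal(r$precision[spot],
               vapply(tr$designs[spot],
                      function(d) treatment_precision(sc, d), numeric(1)),
               tolerance = 1e-10)
  # determinism
  tr2 <- forward_search(sc, min_n = 2)
  expect_identical(tr$records, tr2$records)
  expect_identical(tr$designs, tr2$designs)
})

test_that("the two-direction search dominates a large random-design envelope", {
  # the algorithm's per-n solutions are the better of the forward and
  # backward iterates (both directions are always run; strict hill
  # climbing in a single direction can sit a fraction of a percent below
  # the global optimum of a tiny design space)
  sc <- sw_scenario(4, 4, 0.05, 0.2, degree = 0)
  fwd <- forward_search(sc, min_n = 2)
  bwd <- backward_search(sc, attr(best_complete(sc), "precision"))
  r <- rbind(fwd$records, bwd$records)
  r <- r[r$step_type == "sweep", ]
  base <- random_baseline(sc, 10000, seed = 99)
  for (nn in unique(r$n)) {
    rivals <- base$precision[base$n == nn]
    if (!length(rivals)) next
    expect_gte(max(r$precision[r$n == nn]) * (1 + 1e-8), max(rivals))
  }
})

test_that("backward search grows the staircase start to the target", {
  sc <- sw_scenario(6, 10, 0.05, 0.2, degree = 1)
  # starting width: nearest integer to M / (K - 1), i.e. j = 2; four
  # interior clusters recruit 4 slots each, the two boundary clusters 2
  expect_equal(design_n(staircase_design(6, 10, 2)), 20)
  target <- 0.8 * attr(best_complete(sc), "precision")
  tr <- backward_search(sc, target)
  expect_equal(tr$status, "achieved")
  r <- tr$records
  expect_equal(r$n[1], 20)  # j = round(10/5) = 2 staircase
  add <- r[r$step_type == "add", ]
  if (nrow(add)) expect_true(all(diff(c(r$n[1], add$n)) == 2))
  expect_gte(tr$candidate$precision, target)
  expect_length(validate_design(tr$candidate$design, sc,
                                check_symmetry = TRUE), 0)
})

test_that("hunt returns the smaller-n achieving design or flags unachievable", {
  sc <- sw_scenario(2, 3, 0.05, 0.2, degree = 0)
  designs <- enumerate_symmetric_K2(3)
  ev <- batch_precision(sc, designs)
  bc_prec <- attr(best_complete(sc), "precision")
  target <- 0.6 * bc_prec
  delta <- (qnorm(0.975) + qnorm(0.9)) / sqrt(target)
  h <- hunt(sc, power_spec(delta))
  expect_true(attr(h, "achieved"))
  expect_gte(attr(h, "precision"), target)
  # no symmetric design with smaller n achieves the target
  achievers <- ev$n[ev$ok & ev$precision >= target]
  expect_equal(attr(h, "n"), min(achievers))
  # and hunt's design is within 1% of the enumerated optimum at its n
  opt <- max(ev$precision[ev$ok & ev$n == attr(h, "n")])
  expect_gte(attr(h, "precision"), 0.99 * opt)

  h2 <- hunt(sc, power_spec(delta / 10))
  expect_false(attr(h2, "achieved"))
  expect_equal(attr(h2, "source"), "best_complete")
  expect_equal(design_n(h2), 6)
})

test_that("best_complete matches the exhaustive symmetric cross-over grid", {
  sc <- sw_scenario(2, 4, 0.1, 0.5, degree = 0)
  # K = 2: the half cluster's cross-over determines the whole design
  grid_prec <- vapply(1:5, function(cc) {
    d <- symmetrize(list(crossover = cc, recruit = matrix(1L, 1, 4)))
    tryCatch(treatment_precision(sc, d),
             swhunt_error = function(e) NA_real_)
  }, numeric(1))
  bc <- best_complete(sc)
  expect_equal(attr(bc, "precision"), max(grid_prec, na.rm = TRUE),
               tolerance = 1e-10)
  expect_gte(attr(bc, "precision"),
             treatment_precision(sc, complete_diagonal_design(2, 4)))
})
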
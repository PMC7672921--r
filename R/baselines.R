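#' Evaluate randomly generated symmetric designs
#'
#' Draws `n_designs` reversal-symmetric designs (see
#' [random_symmetric_design()]), evaluates the treatment-effect precision
#' of each, and returns a baseline table. Non-identifiable draws (too few
#' recruits, or a schedule confounding treatment with time) are skipped and
#' counted in attribute `n_skipped`. Reproducible from `seed`.
#'
#' @param scenario an [sw_scenario()].
#' @param n_designs number of random designs (`>= 1`).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param chunk_size internal batch size for evaluation.
#' @param verbose log progress every chunk (to `message()`, never into the
#'   returned table).
#' @return Data frame with columns `design_id`, `generator`, `n`,
#'   `variance`, `precision` (precision is `1/variance` at `sigma2 = 1`).
#' @export
random_baseline <- function(scenario, n_designs, seed = NULL,
                            chunk_size = 1000L, verbose = FALSE) {
  sw_check(inherits(scenario, "sw_scenario"), "scenario must be an sw_scenario")
  sw_check(is_count(n_designs, 1L), "n_designs must be >= 1")
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  sl <- scen_list(scenario)
  out <- vector("list", ceiling(n_designs / chunk_size))
  skipped <- 0L
  done <- 0L
  ci <- 0L
  while (done < n_designs) {
    nb <- min(chunk_size, n_designs - done)
    designs <- lapply(seq_len(nb), function(i) {
      d <- random_symmetric_design(scenario$K, scenario$M)
      list(d$crossover, d$recruit)
    })
    ev <- cpp_eval_many(sl, designs)
    keep <- which(ev$ok)
    skipped <- skipped + (nb - length(keep))
    ci <- ci + 1L
    out[[ci]] <- data.frame(
      design_id = done + keep,
      generator = "random",
      n = ev$n[keep],
      variance = scenario$sigma2 * ev$variance[keep],
      precision = ev$precision[keep],
      stringsAsFactors = FALSE)
    done <- done + nb
    if (verbose)
      message(sprintf("random_baseline: %d/%d designs evaluated (%d skipped)",
                      done, n_designs, skipped))
  }
  res <- do.call(rbind, out[seq_len(ci)])
  rownames(res) <- NULL
  attr(res, "n_skipped") <- skipped
  res
}

#' Evaluate staircase designs over a range of window widths
#'
#' One record per `j` in `j_values`, tagged `staircase-<j>`. Precision is
#' non-decreasing in `j` (wider windows recruit supersets of participants),
#' and `j >= M` reproduces the complete design.
#'
#' @param scenario an [sw_scenario()].
#' @param j_values vector of window widths (`>= 1`).
#' @return Data frame with columns `design_id`, `generator`, `n`,
#'   `variance`, `precision`.
#' @export
staircase_sweep <- function(scenario, j_values) {
  sw_check(inherits(scenario, "sw_scenario"), "scenario must be an sw_scenario")
  sw_check(length(j_values) >= 1 && all(vapply(j_values, is_count, logical(1))),
           "j_values must be a non-empty vector of integers >= 1")
  rows <- lapply(seq_along(j_values), function(i) {
    j <- j_values[i]
    d <- staircase_design(scenario$K, scenario$M, j)
    v <- treatment_variance(scenario, d)
    data.frame(design_id = i, generator = paste0("staircase-", j),
               n = design_n(d), variance = v,
               precision = scenario$sigma2 / v, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Built-in scenarios
#'
#' The five full-scale scenarios studied with this machinery (`K = 30`,
#' `M = 100`, degree-6 trend, `(rho, tau)` in `(0.01, 1)`, `(0.05, 0.2)`,
#' `(0.05, 1)`, `(0.25, 0.2)`, `(0.25, 1)`), one further full-scale
#' correlation structure (`rho = 0.25`, `tau = 0.04`, tagged
#' `results-only mention`), and a set of small test scenarios used for
#' fast property checks. Each element carries a `tag` attribute
#' (`"full-scale"`, `"results-only mention"` or `"test"`).
#'
#' @return Named list of [sw_scenario()] objects.
#' @export
fixture_scenarios <- function() {
  full <- list(
    c(0.01, 1.0), c(0.05, 0.2), c(0.05, 1.0), c(0.25, 0.2), c(0.25, 1.0))
  out <- list()
  for (ct in full) {
    s <- sw_scenario(30, 100, ct[1], ct[2], degree = 6)
    attr(s, "tag") <- "full-scale"
    out[[sprintf("full_rho%g_tau%g", ct[1], ct[2])]] <- s
  }
  extra <- sw_scenario(30, 100, 0.25, 0.04, degree = 6)
  attr(extra, "tag") <- "results-only mention"
  out[["full_rho0.25_tau0.04"]] <- extra
  test_grid <- list(c(2, 3), c(2, 6), c(4, 4), c(4, 8), c(8, 12))
  for (km in test_grid) {
    s <- sw_scenario(km[1], km[2], 0.05, 0.2, degree = 1)
    attr(s, "tag") <- "test"
    out[[sprintf("test_K%d_M%d", km[1], km[2])]] <- s
  }
  out
}
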
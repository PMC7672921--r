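#' Configure the improvement moves of the design search
#'
#' The sample-size-preserving improvement step considers, in deterministic
#' order, (A) shifting one half-cluster's cross-over by one slot, (B)
#' relocating one recruited slot to an unrecruited slot of the same cluster,
#' and optionally (C) relocating a recruited slot to an unrecruited slot of
#' a different cluster. Every move is applied simultaneously to a
#' half-cluster and its mirror image, so the design stays
#' reversal-symmetric and the sample size unchanged. Moves are accepted
#' best-first while the relative precision gain exceeds `tol`.
#'
#' Family C is off by default: cross-cluster transfer of recruitment effort
#' is already achieved across iterations by the greedy remove/add steps,
#' and enabling it makes sweeps quadratically more expensive.
#'
#' @param crossover enable cross-over shift moves (family A).
#' @param relocate enable within-cluster relocation moves (family B).
#' @param cross_cluster enable cross-cluster relocation moves (family C).
#' @param tol relative precision gain below which a move does not count as
#'   an improvement (guards hill climbing against float noise).
#' @param sweep_limit maximum number of committed moves per sweep;
#'   `NULL` means `10 * K * M`, a termination safeguard never reached in
#'   practice.
#' @return An object of class `sw_move_config`.
#' @export
move_config <- function(crossover = TRUE, relocate = TRUE,
                        cross_cluster = FALSE, tol = 1e-10,
                        sweep_limit = NULL) {
  sw_check(length(tol) == 1 && is.finite(tol) && tol > 0, "tol must be > 0")
  sw_check(is.null(sweep_limit) || is_count(sweep_limit, 1L),
           "sweep_limit must be NULL or a positive integer")
  structure(list(crossover = isTRUE(crossover), relocate = isTRUE(relocate),
                 cross_cluster = isTRUE(cross_cluster), tol = tol,
                 sweep_limit = sweep_limit),
            class = "sw_move_config")
}

scen_list <- function(scenario) {
  list(K = scenario$K, M = scenario$M, rho = scenario$rho,
       tau = scenario$tau, degree = scenario$degree)
}

sweep_limit_of <- function(moves, scenario) {
  if (is.null(moves$sweep_limit)) 10L * scenario$K * scenario$M
  else as.integer(moves$sweep_limit)
}

# shared pre-flight for search operations: symmetric + identifiable
assert_search_input <- function(design, scenario) {
  assert_design(design, scenario, check_symmetry = TRUE)
  invisible(sw_gls(scenario, design))   # classed identifiability errors
}

#' Improve a design at fixed sample size
#'
#' Repeatedly applies the single best improving move (see [move_config()])
#' until a full pass finds none whose relative precision gain exceeds the
#' tolerance. The output has the same sample size, remains
#' reversal-symmetric, and its precision is never below the input's.
#'
#' @param design a reversal-symmetric, identifiable [sw_design()].
#' @param scenario an [sw_scenario()].
#' @param moves an [move_config()].
#' @return The improved [sw_design()], with attributes `precision` and
#'   `moves` (number of committed moves).
#' @export
improvement_sweep <- function(design, scenario, moves = move_config()) {
  assert_search_input(design, scenario)
  res <- cpp_sweep(scen_list(scenario), design$crossover, design$recruit,
                   moves$crossover, moves$relocate, moves$cross_cluster,
                   moves$tol, sweep_limit_of(moves, scenario))
  out <- sw_design(res$crossover, res$recruit)
  attr(out, "precision") <- res$precision
  attr(out, "moves") <- res$moves
  out
}

#' Greedy removal / addition of the least / most informative mirror pair
#'
#' `greedy_remove_pair()` exhaustively evaluates removing each recruited
#' slot of clusters `1..K/2` together with its mirror image, and returns
#' the design whose post-removal precision is largest (ties broken by
#' lowest cluster, then slot). `greedy_add_pair()` is the reverse:
#' mirror-symmetric addition maximizing precision. Sample size changes by
#' exactly 2.
#'
#' @inheritParams improvement_sweep
#' @return A list with `design` (the modified [sw_design()]), `pair` (a
#'   two-row data frame with the cluster/slot of both affected
#'   participants) and `precision`.
#' @export
greedy_remove_pair <- function(design, scenario) {
  assert_search_input(design, scenario)
  p <- n_params(scenario)
  if (design_n(design) - 2L < p)
    sw_stop("cannot remove a pair: sample size would fall below the number of model parameters",
            "swhunt_exhausted")
  res <- cpp_remove_pair(scen_list(scenario), design$crossover,
                         design$recruit)
  if (!res$ok)
    sw_stop("every mirror-pair removal destroys identifiability",
            "swhunt_exhausted")
  pair_result(res, scenario)
}

#' @rdname greedy_remove_pair
#' @export
greedy_add_pair <- function(design, scenario) {
  assert_search_input(design, scenario)
  h <- scenario$K %/% 2L
  if (all(design$recruit[seq_len(h), ] == 1L))
    sw_stop("design is already complete: no slot left to add",
            "swhunt_exhausted")
  res <- cpp_add_pair(scen_list(scenario), design$crossover, design$recruit)
  if (!res$ok)
    sw_stop("no addable mirror pair found", "swhunt_exhausted")
  pair_result(res, scenario)
}

pair_result <- function(res, scenario) {
  d <- sw_design(res$crossover, res$recruit)
  list(design = d,
       pair = data.frame(
         cluster = c(res$cluster, scenario$K + 1L - res$cluster),
         slot = c(res$slot, scenario$M + 1L - res$slot)),
       precision = res$precision)
}

build_trajectory <- function(res, scenario, direction, target) {
  nrec <- length(res$n)
  records <- data.frame(
    iteration = seq_len(nrec),
    step_type = res$step_type,
    n = res$n,
    variance = scenario$sigma2 * res$variance,
    precision = res$precision,
    stringsAsFactors = FALSE
  )
  designs <- NULL
  if (!is.null(res$designs)) {
    designs <- lapply(res$designs, function(d) sw_design(d[[1]], d[[2]]))
  }
  candidate <- NULL
  if (isTRUE(res$cand_ok)) {
    cd <- sw_design(res$cand_crossover, res$cand_recruit)
    candidate <- list(design = cd, n = design_n(cd),
                      precision = res$cand_precision)
  }
  structure(list(records = records, designs = designs, candidate = candidate,
                 final = sw_design(res$final_crossover, res$final_recruit),
                 status = res$status, direction = direction,
                 target = target, scenario = scenario),
            class = "sw_trajectory")
}

#' @export
print.sw_trajectory <- function(x, ...) {
  r <- x$records
  cat(sprintf("%s search trajectory (%d records, status: %s)\n",
              x$direction, nrow(r), x$status))
  cat(sprintf("  n from %d to %d, precision from %.4g to %.4g\n",
              r$n[1], r$n[nrow(r)], r$precision[1], r$precision[nrow(r)]))
  if (!is.null(x$candidate))
    cat(sprintf("  candidate achieving target: n = %d, precision = %.4g\n",
                x$candidate$n, x$candidate$precision))
  invisible(x)
}

#' @export
as.data.frame.sw_trajectory <- function(x, ...) x$records

#' Forward search: prune a complete design down
#'
#' Starts from the complete diagonal design, improves it at fixed sample
#' size, then alternates greedy mirror-pair removal with improvement sweeps,
#' recording every iterate. Stops when the precision first falls below
#' `target_precision` (that iterate is recorded too, and the previous
#' iterate is kept as the achieving `candidate`), or when the sample size
#' reaches `min_n`. Deterministic given the scenario and move
#' configuration.
#'
#' @param scenario an [sw_scenario()].
#' @param target_precision target precision at `sigma2 = 1`, or `NULL` to
#'   run down to `min_n` unconditionally.
#' @param min_n sample-size floor; defaults to the number of fixed-effect
#'   parameters.
#' @param moves an [move_config()].
#' @param record_designs store the design of every iterate (`NULL` = only
#'   when `K * M <= 2000`).
#' @return An `sw_trajectory`: a list with `records` (data frame with
#'   `iteration`, `step_type`, `n`, `variance`, `precision`), `designs`
#'   (when recorded), `candidate` (last iterate meeting the target),
#'   `final`, and `status` (`"achieved"`, `"floor_reached"`,
#'   `"target_crossed"`, `"unachievable"` or `"exhausted"`).
#' @export
forward_search <- function(scenario, target_precision = NULL, min_n = NULL,
                           moves = move_config(), record_designs = NULL) {
  sw_check(inherits(scenario, "sw_scenario"), "scenario must be an sw_scenario")
  p <- n_params(scenario)
  floor_n <- max(p, if (is.null(min_n)) p else as.integer(min_n))
  target <- if (is.null(target_precision)) 0 else as.numeric(target_precision)
  start <- complete_diagonal_design(scenario$K, scenario$M)
  assert_search_input(start, scenario)
  if (is.null(record_designs))
    record_designs <- scenario$K * scenario$M <= 2000
  res <- cpp_search(scen_list(scenario), start$crossover, start$recruit,
                    TRUE, target, floor_n,
                    moves$crossover, moves$relocate, moves$cross_cluster,
                    moves$tol, sweep_limit_of(moves, scenario),
                    isTRUE(record_designs))
  build_trajectory(res, scenario, "forward", target)
}

#' Backward search: grow a staircase design up
#'
#' Starts from the staircase design with window width
#' `j = max(1, round(M / (K - 1)))` (widened if that staircase is not
#' identifiable), improves it at fixed sample size, then alternates greedy
#' mirror-pair addition with improvement sweeps until the target precision
#' is reached or the design is complete.
#'
#' @inheritParams forward_search
#' @param target_precision target precision at `sigma2 = 1` (required).
#' @return An `sw_trajectory` (see [forward_search()]).
#' @export
backward_search <- function(scenario, target_precision,
                            moves = move_config(), record_designs = NULL) {
  sw_check(inherits(scenario, "sw_scenario"), "scenario must be an sw_scenario")
  sw_check(length(target_precision) == 1 && is.finite(target_precision) &&
             target_precision > 0, "target_precision must be positive")
  j <- max(1L, as.integer(round_half_up(scenario$M / (scenario$K - 1))))
  start <- NULL
  while (j <= scenario$M + 1L) {
    cand <- staircase_design(scenario$K, scenario$M, j)
    ok <- tryCatch({sw_gls(scenario, cand); TRUE},
                   swhunt_identifiability = function(e) FALSE)
    if (ok) { start <- cand; break }
    j <- j + 1L
  }
  if (is.null(start))
    sw_stop("no identifiable staircase starting design exists for this scenario",
            "swhunt_identifiability")
  if (is.null(record_designs))
    record_designs <- scenario$K * scenario$M <= 2000
  res <- cpp_search(scen_list(scenario), start$crossover, start$recruit,
                    FALSE, as.numeric(target_precision), n_params(scenario),
                    moves$crossover, moves$relocate, moves$cross_cluster,
                    moves$tol, sweep_limit_of(moves, scenario),
                    isTRUE(record_designs))
  build_trajectory(res, scenario, "backward", as.numeric(target_precision))
}

#' Hunt for an efficient design at a target power
#'
#' Converts the power target to a required precision, runs the forward
#' search (complete design pruned down) and the backward search (staircase
#' design grown up), and returns whichever candidate achieves the target
#' with the smaller sample size (ties broken by higher precision). When
#' even the best complete design cannot reach the target, that design is
#' returned flagged as unachievable.
#'
#' @param scenario an [sw_scenario()].
#' @param spec an [power_spec()] (or a bare effect size delta/sigma).
#' @param moves an [move_config()].
#' @return An [sw_design()] with attributes `n`, `precision`, `power`,
#'   `achieved` (logical), `target_precision`, `source` (`"forward"`,
#'   `"backward"` or `"best_complete"`).
#' @export
hunt <- function(scenario, spec, moves = move_config()) {
  sw_check(inherits(scenario, "sw_scenario"), "scenario must be an sw_scenario")
  if (!inherits(spec, "sw_power_spec")) spec <- power_spec(spec)
  target <- required_precision(spec)
  bc <- best_complete(scenario, moves)
  bc_prec <- attr(bc, "precision")
  if (bc_prec < target) {
    return(hunt_result(bc, bc_prec, spec, target, achieved = FALSE,
                       source = "best_complete"))
  }
  fwd <- forward_search(scenario, target_precision = target, moves = moves,
                        record_designs = FALSE)
  bwd <- backward_search(scenario, target_precision = target, moves = moves,
                         record_designs = FALSE)
  cands <- list()
  if (!is.null(fwd$candidate)) cands$forward <- fwd$candidate
  if (!is.null(bwd$candidate)) cands$backward <- bwd$candidate
  if (!length(cands)) {
    # target below any reachable iterate should not happen once the
    # complete design qualifies; fall back defensively
    return(hunt_result(bc, bc_prec, spec, target, achieved = TRUE,
                       source = "best_complete"))
  }
  ns <- vapply(cands, function(cc) cc$n, numeric(1))
  ps <- vapply(cands, function(cc) cc$precision, numeric(1))
  best <- order(ns, -ps)[1]
  hunt_result(cands[[best]]$design, cands[[best]]$precision, spec, target,
              achieved = TRUE, source = names(cands)[best])
}

hunt_result <- function(design, precision, spec, target, achieved, source) {
  attr(design, "n") <- design_n(design)
  attr(design, "precision") <- precision
  attr(design, "power") <- pnorm(spec$delta * sqrt(precision) -
                                   qnorm(1 - spec$alpha / 2))
  attr(design, "achieved") <- achieved
  attr(design, "target_precision") <- target
  attr(design, "source") <- source
  design
}

#' Most precise complete design reachable by cross-over shifts
#'
#' Keeps full recruitment everywhere and hill-climbs the cross-over slots
#' only (mirror-symmetric shifts) from the diagonal start until no
#' improvement remains.
#'
#' @inheritParams forward_search
#' @return An [sw_design()] with attribute `precision`.
#' @export
best_complete <- function(scenario, moves = move_config()) {
  sw_check(inherits(scenario, "sw_scenario"), "scenario must be an sw_scenario")
  start <- complete_diagonal_design(scenario$K, scenario$M)
  improvement_sweep(start, scenario,
                    move_config(crossover = TRUE, relocate = FALSE,
                                cross_cluster = FALSE, tol = moves$tol,
                                sweep_limit = moves$sweep_limit))
}
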
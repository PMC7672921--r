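#' Construct a design (recruitment and cross-over schedule)
#'
#' A design is the free object of the search: for each cluster `k`, the slot
#' `crossover[k]` at which the cluster first recruits under the intervention
#' (`M + 1` means the cluster never crosses over; `1` means it is under the
#' intervention throughout), and a 0/1 matrix saying which of the `M`
#' arrival slots are recruited. A recruited slot `s` in cluster `k` is under
#' the intervention exactly when `s >= crossover[k]`: the intervention takes
#' effect immediately at cross-over, so a participant presenting exactly at
#' the cross-over time is treated.
#'
#' @param crossover integer vector of length `K`, values in `1..M+1`.
#' @param recruit `K x M` matrix of 0/1 recruitment indicators.
#' @return An object of class `sw_design`.
#' @examples
#' sw_design(crossover = c(1, 3), recruit = matrix(1, 2, 2))
#' @export
sw_design <- function(crossover, recruit) {
  sw_check(is.numeric(crossover) && length(crossover) >= 1,
           "crossover must be a numeric vector")
  recruit <- as.matrix(recruit)
  K <- length(crossover)
  M <- ncol(recruit)
  sw_check(nrow(recruit) == K,
           "recruit must have one row per cluster")
  sw_check(all(is.finite(crossover)) && all(crossover == as.integer(crossover)),
           "crossover slots must be integers")
  sw_check(all(crossover >= 1 & crossover <= M + 1),
           "crossover slots must lie in 1..M+1")
  sw_check(all(recruit %in% c(0, 1)), "recruit entries must be 0 or 1")
  storage.mode(recruit) <- "integer"
  dimnames(recruit) <- NULL
  structure(list(crossover = as.integer(crossover), recruit = recruit),
            class = "sw_design")
}

#' Total sample size of a design
#'
#' @param design an [sw_design()].
#' @return The number of recruited participants, `sum(design$recruit)`.
#' @export
design_n <- function(design) sum(design$recruit)

#' @export
print.sw_design <- function(x, ...) {
  K <- length(x$crossover); M <- ncol(x$recruit)
  cat(sprintf("Stepped wedge design: K = %d, M = %d, n = %d recruited\n",
              K, M, design_n(x)))
  if (K <= 40 && M <= 120) {
    for (k in seq_len(K)) {
      row <- ifelse(x$recruit[k, ] == 1L,
                    ifelse(seq_len(M) >= x$crossover[k], "I", "c"), ".")
      cat(sprintf("%3d |%s|\n", k, paste(row, collapse = "")))
    }
    cat("  (c = recruited control, I = recruited intervention, . = skipped)\n")
  }
  invisible(x)
}

#' Check a design for structural violations
#'
#' Reports rather than raises: returns a character vector of violation
#' messages, empty when the design is valid.
#'
#' @param design an [sw_design()] (or a bare list with `crossover` and
#'   `recruit` fields).
#' @param scenario optional [sw_scenario()]; if given, dimensions must match.
#' @param check_symmetry if `TRUE`, additionally require invariance under
#'   [reverse_design()].
#' @return Character vector of violations (`character(0)` if valid).
#' @export
validate_design <- function(design, scenario = NULL, check_symmetry = FALSE) {
  v <- character()
  if (!is.list(design) || is.null(design$crossover) || is.null(design$recruit))
    return("design must have crossover and recruit fields")
  cr <- design$crossover
  rec <- design$recruit
  if (!is.matrix(rec)) return("recruit must be a matrix")
  K <- length(cr); M <- ncol(rec)
  if (nrow(rec) != K) v <- c(v, "recruit must have one row per cluster")
  if (!all(cr == as.integer(cr))) v <- c(v, "crossover slots must be integers")
  bad <- which(cr < 1 | cr > M + 1)
  if (length(bad))
    v <- c(v, sprintf("crossover out of range (1..M+1) in cluster %s",
                      paste(bad, collapse = ", ")))
  if (!all(rec %in% c(0L, 1L))) v <- c(v, "recruit entries must be 0 or 1")
  if (!is.null(scenario)) {
    if (K != scenario$K) v <- c(v, "cluster count does not match scenario K")
    if (M != scenario$M) v <- c(v, "slot count does not match scenario M")
  }
  if (check_symmetry && !length(v)) {
    if (K %% 2 != 0) {
      v <- c(v, "symmetry requires an even number of clusters")
    } else {
      rd <- reverse_design(design)
      if (!identical(rd$crossover, as.integer(cr)) ||
          !identical(rd$recruit, rec))
        v <- c(v, "not reversal-invariant")
    }
  }
  v
}

# raise (classed) if invalid
assert_design <- function(design, scenario = NULL, check_symmetry = FALSE) {
  v <- validate_design(design, scenario, check_symmetry)
  if (length(v))
    sw_stop(paste0("invalid design: ", paste(v, collapse = "; ")),
            "swhunt_invalid_input")
  invisible(design)
}

#' Reverse time and swap conditions
#'
#' The correlation model is unchanged by running time backwards, so a design
#' with the time-scale reversed *and* the control/intervention labels
#' swapped is again a valid design with exactly the same treatment-effect
#' precision. On the slot grid, reversal maps slot `s` to `M + 1 - s`,
#' cluster `k` to `K + 1 - k`, and the crossover slot `c` to `M + 2 - c`.
#'
#' @param design an [sw_design()].
#' @return The reversed [sw_design()]. Applying `reverse_design()` twice
#'   returns the original design.
#' @export
reverse_design <- function(design) {
  assert_design(design)
  K <- length(design$crossover)
  M <- ncol(design$recruit)
  sw_design(rev(M + 2L - design$crossover),
            design$recruit[K:1, M:1, drop = FALSE])
}

#' Expand a half-schedule into a reversal-symmetric design
#'
#' Schedules are chosen freely for clusters `1..K/2`; clusters
#' `K, K-1, ..., K/2+1` are then set to the time-and-condition reversal of
#' clusters `1, 2, ..., K/2`, so the result is always invariant under
#' [reverse_design()].
#'
#' @param half list with `crossover` (length `K/2`) and `recruit`
#'   (`K/2 x M` 0/1 matrix) for the first half of the clusters.
#' @param K total number of clusters; defaults to twice the half size, and
#'   must equal it (and be even).
#' @return A full, reversal-symmetric [sw_design()].
#' @export
symmetrize <- function(half, K = NULL) {
  sw_check(is.list(half) && !is.null(half$crossover) && !is.null(half$recruit),
           "half must have crossover and recruit fields")
  hK <- length(half$crossover)
  rec <- as.matrix(half$recruit)
  storage.mode(rec) <- "integer"
  sw_check(nrow(rec) == hK, "half recruit must have one row per half-cluster")
  if (is.null(K)) K <- 2L * hK
  sw_check(K %% 2 == 0, "K must be even")
  sw_check(K == 2L * hK, "K must be twice the number of half-schedule clusters")
  M <- ncol(rec)
  sw_design(c(half$crossover, rev(M + 2L - half$crossover)),
            rbind(rec, rec[hK:1, M:1, drop = FALSE]))
}

#' Extract the free half of a symmetric design
#'
#' @param design an [sw_design()] with an even number of clusters.
#' @return list with `crossover` and `recruit` for clusters `1..K/2`.
#' @export
design_half <- function(design) {
  assert_design(design)
  K <- length(design$crossover)
  sw_check(K %% 2 == 0, "K must be even")
  h <- K %/% 2L
  list(crossover = design$crossover[seq_len(h)],
       recruit = design$recruit[seq_len(h), , drop = FALSE])
}

#' Complete design with a straight diagonal cross-over boundary
#'
#' Every slot is recruited (`n = M * K`). The last control slot in cluster
#' `k` is the nearest integer to `M * (k - 1) / (K - 1)` (half-integers
#' round up; for even `K` no half-integer ever arises), so cluster 1 is
#' under the intervention throughout and cluster `K` under control
#' throughout. This is the classic continuous-time stepped wedge and the
#' starting point of the forward search.
#'
#' @param K number of clusters (`>= 2`).
#' @param M slots per cluster.
#' @return An [sw_design()].
#' @export
complete_diagonal_design <- function(K, M) {
  sw_check(is_count(K, 2L), "K must be an integer >= 2")
  sw_check(is_count(M, 1L), "M must be a positive integer")
  i_last_control <- round_half_up(M * (seq_len(K) - 1) / (K - 1))
  sw_design(as.integer(i_last_control) + 1L, matrix(1L, K, M))
}

#' Staircase design: recruitment windows hugging the cross-over boundary
#'
#' Uses the same cross-over slots as [complete_diagonal_design()], but each
#' cluster recruits only at the `j` slots immediately before its cross-over
#' and the `j` slots from the cross-over onwards; windows are truncated at
#' the trial boundaries (slots `1` and `M`), so `n <= 2 * j * K`.
#'
#' @param K number of clusters (`>= 2`).
#' @param M slots per cluster.
#' @param j recruitment window width on each side of cross-over (`>= 1`).
#' @return An [sw_design()].
#' @examples
#' design_n(staircase_design(30, 100, 3))  # 174
#' @export
staircase_design <- function(K, M, j) {
  sw_check(is_count(j, 1L), "j must be an integer >= 1")
  base <- complete_diagonal_design(K, M)
  rec <- matrix(0L, K, M)
  for (k in seq_len(K)) {
    ck <- base$crossover[k]
    before <- if (ck > 1L) seq.int(max(1L, ck - j), ck - 1L) else integer(0)
    after <- if (ck <= M) seq.int(ck, min(M, ck + j - 1L)) else integer(0)
    rec[k, c(before, after)] <- 1L
  }
  sw_design(base$crossover, rec)
}

#' Draw a random reversal-symmetric design
#'
#' For each of the first `K/2` clusters the cross-over slot is drawn
#' uniformly from `1..M+1` (so some clusters may stay in one condition
#' throughout); a recruitment probability `p` is drawn once per design
#' uniformly on `[0, 1]` and each of the `K/2 * M` free slots is recruited
#' independently with probability `p`. The other half of the design is the
#' mirror image ([symmetrize()]). Uses the R random number generator, so
#' results are reproducible under `set.seed()`.
#'
#' @param K number of clusters (even).
#' @param M slots per cluster.
#' @param p optional fixed recruitment probability (drawn uniformly when
#'   `NULL`).
#' @return A reversal-symmetric [sw_design()].
#' @export
random_symmetric_design <- function(K, M, p = NULL) {
  sw_check(is_count(K, 2L) && K %% 2 == 0, "K must be a positive even integer")
  sw_check(is_count(M, 1L), "M must be a positive integer")
  h <- K %/% 2L
  cr <- sample.int(M + 1L, h, replace = TRUE)
  if (is.null(p)) p <- runif(1)
  sw_check(length(p) == 1 && p >= 0 && p <= 1, "p must lie in [0, 1]")
  rec <- matrix(rbinom(h * M, 1L, p), h, M)
  symmetrize(list(crossover = cr, recruit = rec))
}
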
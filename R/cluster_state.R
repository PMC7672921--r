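#' Cached per-cluster quantities for fast observation add/remove
#'
#' For one cluster the state caches the inverse within-cluster correlation
#' matrix `Rinv`, `G = Rinv %*% Z`, and the information contribution
#' `W = Z' Rinv Z` (all on the `sigma2 = 1` scale). These make the effect
#' of recruiting or un-recruiting a single participant a rank-one update,
#' which is what lets the search evaluate every candidate change cheaply.
#'
#' @param scenario an [sw_scenario()].
#' @param design an [sw_design()].
#' @param cluster cluster index in `1..K`.
#' @param basis time-column basis, `"raw"` or `"orthogonal"`; either gives
#'   the same precision.
#' @return An object of class `sw_cluster_state`.
#' @export
cluster_state <- function(scenario, design, cluster,
                          basis = c("raw", "orthogonal")) {
  basis <- match.arg(basis)
  sw_check(inherits(scenario, "sw_scenario"), "scenario must be an sw_scenario")
  assert_design(design, scenario)
  sw_check(is_count(cluster, 1L) && cluster <= scenario$K,
           "cluster must index a cluster of the scenario")
  slots <- cluster_slots(design, cluster)
  p <- n_params(scenario)
  ck <- design$crossover[cluster]
  if (!length(slots)) {
    st <- list(scenario = scenario, cluster = as.integer(cluster),
               crossover = ck, basis = basis, slots = integer(0),
               times = numeric(0), Z = matrix(0, 0, p),
               Rinv = matrix(0, 0, 0), G = matrix(0, 0, p),
               W = matrix(0, p, p))
    return(structure(st, class = "sw_cluster_state"))
  }
  times <- slots / scenario$M
  Z <- cbind(sw_basis(times, scenario$degree, basis),
             as.numeric(slots >= ck))
  R <- correlation_block(scenario, times)
  Rinv <- chol2inv(chol(R))
  G <- Rinv %*% Z
  structure(list(scenario = scenario, cluster = as.integer(cluster),
                 crossover = ck, basis = basis, slots = slots, times = times,
                 Z = Z, Rinv = Rinv, G = G, W = crossprod(Z, G)),
            class = "sw_cluster_state")
}

# z-row for a (possibly unrecruited) slot of the state's cluster
state_zrow <- function(state, slot) {
  t <- slot / state$scenario$M
  c(drop(sw_basis(t, state$scenario$degree, state$basis)),
    as.numeric(slot >= state$crossover))
}

# apply one add/remove to a cluster state, returning the updated state;
# standard observation deletion/augmentation identities on Rinv, G, W
sw_state_apply <- function(state, slot, mode) {
  sw_check(is_count(slot, 1L) && slot <= state$scenario$M,
           "slot must lie in 1..M")
  if (mode == "remove") {
    i <- match(slot, state$slots)
    sw_check(!is.na(i), "remove: slot is not currently recruited")
    u <- state$Rinv[i, i]
    if (!is.finite(u) || u <= 0)
      sw_stop("broken cluster state cache: non-positive Rinv diagonal",
              "swhunt_numeric")
    g <- state$G[i, ]
    m <- length(state$slots)
    v <- state$Rinv[-i, i, drop = FALSE]            # (m-1) x 1
    state$W <- state$W - tcrossprod(g) / u
    state$Rinv <- state$Rinv[-i, -i, drop = FALSE] - tcrossprod(v) / u
    state$G <- state$G[-i, , drop = FALSE] - v %*% rbind(g) / u
    state$Z <- state$Z[-i, , drop = FALSE]
    state$slots <- state$slots[-i]
    state$times <- state$times[-i]
  } else if (mode == "add") {
    sw_check(!(slot %in% state$slots), "add: slot is already recruited")
    sc <- state$scenario
    t <- slot / sc$M
    z <- state_zrow(state, slot)
    m <- length(state$slots)
    if (m == 0) {
      s <- 1
      a <- z
      state$Rinv <- matrix(1, 1, 1)
      state$G <- rbind(z)
      state$W <- state$W + tcrossprod(a)
      state$Z <- rbind(z)
      state$slots <- slot
      state$times <- t
    } else {
      cv <- sc$rho * sc$tau^abs(t - state$times)    # correlations to current
      w <- drop(state$Rinv %*% cv)
      s <- 1 / (1 - sum(cv * w))
      if (!is.finite(s) || s <= 0)
        sw_stop("broken cluster state cache: augmented correlation not PD",
                "swhunt_numeric")
      a <- z - drop(crossprod(state$G, cv))
      ord <- order(c(state$slots, slot))
      Rnew <- rbind(cbind(state$Rinv + s * tcrossprod(w), -s * w),
                    c(-s * w, s))[ord, ord, drop = FALSE]
      Gnew <- rbind(state$G - s * w %*% rbind(a), s * a)[ord, , drop = FALSE]
      state$W <- state$W + s * tcrossprod(a)
      state$Rinv <- Rnew
      state$G <- Gnew
      state$Z <- rbind(state$Z, z)[ord, , drop = FALSE]
      state$slots <- c(state$slots, slot)[ord]
      state$times <- c(state$times, t)[ord]
    }
  } else {
    sw_stop("mode must be 'add' or 'remove'", "swhunt_invalid_input")
  }
  state
}

#' Update a cluster's information contribution after one add/remove
#'
#' Removing a recruited participant downdates the cluster information by
#' `g g' / u`, where `g` is the participant's row of `Rinv %*% Z` and `u`
#' the matching diagonal entry of `Rinv`; adding reverses the update. The
#' result equals rebuilding the cluster information from scratch.
#'
#' @param state an [cluster_state()] object.
#' @param slot arrival slot (`1..M`) to recruit or un-recruit.
#' @param mode `"remove"` (slot must be recruited) or `"add"` (slot must be
#'   unrecruited).
#' @return The updated `p x p` information contribution of the cluster, with
#'   the updated state attached as attribute `"state"`.
#' @export
adjust_information <- function(state, slot, mode = c("remove", "add")) {
  mode <- match.arg(mode)
  sw_check(inherits(state, "sw_cluster_state"),
           "state must come from cluster_state()")
  new_state <- sw_state_apply(state, slot, mode)
  structure(new_state$W, state = new_state)
}

#' Precision of a design after a set of add/remove changes
#'
#' Evaluates the treatment-effect precision of the design obtained by
#' applying `changes` without mutating the input design, reusing cached
#' cluster states and rank-one updates for the affected clusters. Equals a
#' full recomputation on the edited design.
#'
#' @param scenario an [sw_scenario()].
#' @param design an [sw_design()].
#' @param changes data frame with columns `cluster`, `slot`, `action`
#'   (`"add"` or `"remove"`); a slot may not be both added and removed.
#' @return The precision (inverse treatment variance at `sigma2 = 1`) of
#'   the modified design.
#' @export
precision_after_changes <- function(scenario, design, changes) {
  sw_check(inherits(scenario, "sw_scenario"), "scenario must be an sw_scenario")
  assert_design(design, scenario)
  sw_check(is.data.frame(changes) &&
             all(c("cluster", "slot", "action") %in% names(changes)),
           "changes must be a data frame with cluster, slot, action")
  if (nrow(changes)) {
    key <- paste(changes$cluster, changes$slot)
    sw_check(!anyDuplicated(key),
             "changes must be mutually consistent (each cluster/slot once)")
    sw_check(all(changes$action %in% c("add", "remove")),
             "action must be 'add' or 'remove'")
  }
  p <- n_params(scenario)
  Ws <- cluster_infos(scenario, design, "orthogonal")
  for (k in unique(changes$cluster)) {
    st <- cluster_state(scenario, design, k, basis = "orthogonal")
    rows <- which(changes$cluster == k)
    for (r in rows) st <- sw_state_apply(st, changes$slot[r], changes$action[r])
    Ws[[k]] <- st$W
  }
  W <- Reduce(`+`, Ws)
  ch <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(ch))
    sw_stop("changes make the design non-identifiable",
            "swhunt_identifiability")
  v <- chol2inv(ch)[p, p]
  if (!is.finite(v) || v <= 0)
    sw_stop("changes make the design non-identifiable",
            "swhunt_identifiability")
  1 / v
}
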
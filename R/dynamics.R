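#' One decision-making iteration
#'
#' Advances every individual's vaccination decision by one round. Under the
#' synchronous scheme each node's perceived risk, cost-minimized choice,
#' influence strengths, social opinion and final decision are computed from
#' the incoming state, then all decisions are replaced at once. Under the
#' asynchronous scheme nodes update one at a time in a freshly drawn random
#' order, each seeing the current (partially updated) state.
#'
#' Isolated nodes perceive zero risk and skip the social conversion (their
#' cost-minimized choice stands). When `p = 0` the step is fully
#' deterministic and consumes no random numbers. When `p > 0`, the
#' synchronous step consumes, in this order: one uniform per node for the
#' social-opinion draw, then one uniform per node for the conformity draw
#' (the asynchronous step additionally draws the update order first).
#'
#' @param decisions integer vector in `{+1, -1}`, one per node.
#' @param net a [contact_network()].
#' @param params a [decision_params()].
#' @param cache internal adjacency cache from `network_adjacency(net)`;
#'   recomputed when `NULL`.
#' @return The successor decision vector.
#' @export
decision_step <- function(decisions, net, params, cache = NULL) {
  stopifnot(inherits(net, "contact_network"),
            inherits(params, "decision_params"),
            length(decisions) == net$n_nodes)
  if (params$update_scheme == "asynchronous")
    return(.step_async(decisions, net, params,
                       if (is.null(cache)) network_neighbors(net) else cache))
  if (is.null(cache)) cache <- network_adjacency(net)
  .step_sync(decisions, params, cache)
}

.step_sync <- function(d, params, cache) {
  n <- length(d)
  plus <- as.numeric(d == 1L)
  n_plus <- as.vector(cache$B %*% plus)
  n_minus <- as.vector(cache$B %*% (1 - plus))
  deg <- n_plus + n_minus
  pos <- deg > 0

  if (params$weighted_risk) {
    w_minus <- as.vector(cache$A %*% (1 - plus))
    w_all <- as.vector(cache$A %*% rep(1, n))
    lambda <- ifelse(pos, params$beta_perc * w_minus / pmax(w_all, .Machine$double.xmin), 0)
  } else {
    lambda <- ifelse(pos, params$beta_perc * n_minus / pmax(deg, 1), 0)
  }
  cost <- ifelse(lambda > params$r, 1L,
                 ifelse(lambda < params$r, -1L, d))

  if (params$p == 0)
    return(as.integer(cost))

  W_plus <- as.vector(cache$A %*% plus)
  W_minus <- as.vector(cache$A %*% (1 - plus))
  ex <- params$sit_exponent - 1
  I_plus <- ifelse(n_plus > 0, W_plus * n_plus^ex, 0)
  I_minus <- ifelse(n_minus > 0, W_minus * n_minus^ex, 0)
  delta <- normalized_discrepancy(I_plus, I_minus)
  q <- opinion_probability(delta, params$kappa)
  social <- ifelse(stats::runif(n) < q, 1L, -1L)
  conform <- stats::runif(n) < params$p
  as.integer(ifelse(conform & pos, social, cost))
}

.step_async <- function(d, net, params, nblist) {
  order <- if (params$p == 0) seq_len(net$n_nodes) else sample.int(net$n_nodes)
  for (v in order) {
    nbr <- nblist$nbr[[v]]
    if (length(nbr) == 0L) next_d <- d[v] else {
      nd <- d[nbr + 1L]
      plus <- nd == 1L
      lambda <- if (params$weighted_risk) {
        wt <- nblist$wt[[v]]
        params$beta_perc * sum(wt[!plus]) / sum(wt)
      } else params$beta_perc * mean(!plus)
      cost <- if (lambda > params$r) 1L else if (lambda < params$r) -1L else d[v]
      if (params$p == 0) next_d <- cost else {
        wt <- nblist$wt[[v]]
        ex <- params$sit_exponent - 1
        I_p <- if (any(plus)) sum(wt[plus]) * sum(plus)^ex else 0
        I_m <- if (any(!plus)) sum(wt[!plus]) * sum(!plus)^ex else 0
        delta <- normalized_discrepancy(I_p, I_m)
        social <- if (stats::runif(1) < opinion_probability(delta, params$kappa)) 1L else -1L
        next_d <- if (stats::runif(1) < params$p) social else cost
      }
    }
    d[v] <- next_d
  }
  d
}

#' Iterate decision making to a steady state
#'
#' Runs the hybrid decision dynamics from a fresh Bernoulli(`w0`)
#' initialization. For `p = 0` the dynamics are deterministic, so iteration
#' stops as soon as a fixed point or a 2-cycle is detected (steady-state
#' coverage over a 2-cycle is the average of the two states); otherwise the
#' run spans `max_iters` iterations and reports the mean coverage over the
#' final `window` iterations.
#'
#' All randomness (initialization, social-opinion draws, conformity draws)
#' derives from `seed` through a single stream, consumed in a fixed
#' documented order, so runs are replayable.
#'
#' @param net a [contact_network()].
#' @param params a [decision_params()].
#' @param seed integer seed for the run.
#' @param init optional explicit initial decision vector (overrides `w0`
#'   initialization; the seed then governs only the in-run draws).
#' @return A list of class `steady_state` with `coverage`, `trajectory`
#'   (coverage after each iteration, including iteration 0), `converged`,
#'   `termination_reason` (`"fixed_point"`, `"two_cycle"` or `"max_iters"`),
#'   `iterations`, and `final_decisions`.
#' @export
#' @examples
#' net <- generate_network(n_nodes = 50, mean_degree = 6, mean_weight = 10,
#'                         seed = 1)
#' run_decision_dynamics(net, decision_params(r = 0.2, p = 0), seed = 1)$coverage
run_decision_dynamics <- function(net, params, seed = 1L, init = NULL) {
  stopifnot(inherits(net, "contact_network"),
            inherits(params, "decision_params"))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  cache <- if (params$update_scheme == "asynchronous")
    network_neighbors(net) else network_adjacency(net)
  d <- if (is.null(init)) initialize_decisions(net, params$w0) else {
    stopifnot(length(init) == net$n_nodes, all(init %in% c(-1L, 1L)))
    as.integer(init)
  }
  traj <- numeric(params$max_iters + 1L)
  traj[1L] <- coverage(d)
  prev1 <- d
  prev2 <- NULL
  reason <- "max_iters"
  iters <- params$max_iters
  deterministic <- params$p == 0
  for (t in seq_len(params$max_iters)) {
    d <- decision_step(d, net, params, cache = cache)
    traj[t + 1L] <- coverage(d)
    if (deterministic) {
      if (identical(d, prev1)) {
        reason <- "fixed_point"; iters <- t; break
      }
      if (!is.null(prev2) && identical(d, prev2)) {
        reason <- "two_cycle"; iters <- t; break
      }
    }
    prev2 <- prev1
    prev1 <- d
  }
  traj <- traj[seq_len(iters + 1L)]
  cov <- if (deterministic) {
    switch(reason,
           fixed_point = traj[length(traj)],
           two_cycle = mean(traj[length(traj) - 0:1]),
           mean(traj[length(traj) - seq_len(min(params$window, iters)) + 1L]))
  } else {
    mean(traj[length(traj) - seq_len(min(params$window, iters)) + 1L])
  }
  structure(list(coverage = cov, trajectory = traj,
                 converged = reason != "max_iters",
                 termination_reason = reason, iterations = iters,
                 final_decisions = d),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("steady state after %d iteration(s) [%s]: coverage %.4f\n",
              x$iterations, x$termination_reason, x$coverage))
  invisible(x)
}
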
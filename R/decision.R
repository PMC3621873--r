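#' Decision-model parameters
#'
#' Bundles and validates the parameters of the hybrid vaccination decision
#' model.
#'
#' @param r cost ratio `c_vac / c_inf` (>= 0): the relative cost of taking
#'   the vaccine versus being infected. An individual's cost-minimized choice
#'   compares the perceived infection risk against `r`.
#' @param p conformity rate in `[0, 1]`: the probability an individual
#'   abandons the cost-minimized choice and adopts the socially formed
#'   opinion of the neighbourhood. `p = 0` is a pure cost-based decider;
#'   `p = 1` an absolute social follower.
#' @param beta_perc perceived disease transmission rate in `[0, 1]`. The
#'   default treats perception as accurate and equals the transmission rate
#'   of an epidemic with reproduction number 1.4 and recovery rate 0.312.
#' @param kappa Fermi responsiveness (> 0): smaller values make the opinion
#'   with the larger social influence dominate even when the normalized
#'   discrepancy is small.
#' @param w0 initial vaccination willingness in `[0, 1]`: each individual
#'   starts willing to vaccinate independently with this probability.
#' @param max_iters maximum number of decision iterations.
#' @param window number of final iterations averaged to report steady-state
#'   coverage when `p > 0` (must not exceed `max_iters`).
#' @param update_scheme `"synchronous"` (all individuals update from the
#'   previous state) or `"asynchronous"` (individuals update one at a time in
#'   a random order within each sweep).
#' @param sit_exponent exponent on the source count in the social-impact
#'   strength (default `0.5`, the diminishing-returns form; `1` gives plain
#'   weighted sums).
#' @param weighted_risk if `TRUE`, the perceived risk uses closeness-weighted
#'   neighbour fractions instead of plain counts (default `FALSE`).
#' @return A list of class `decision_params`.
#' @export
decision_params <- function(r = 0.5, p = 0, beta_perc = 1.4 * 0.312,
                            kappa = 0.1, w0 = 0.5, max_iters = 200L,
                            window = 50L,
                            update_scheme = c("synchronous", "asynchronous"),
                            sit_exponent = 0.5, weighted_risk = FALSE) {
  update_scheme <- match.arg(update_scheme)
  stopifnot(is.numeric(r), length(r) == 1L, r >= 0,
            is.numeric(p), length(p) == 1L, p >= 0, p <= 1,
            is.numeric(beta_perc), beta_perc >= 0, beta_perc <= 1,
            is.numeric(w0), w0 >= 0, w0 <= 1,
            max_iters >= 1L, window >= 1L, window <= max_iters,
            sit_exponent >= 0)
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0)
    stop("'kappa' must be a positive number")
  structure(list(r = r, p = p, beta_perc = beta_perc, kappa = kappa, w0 = w0,
                 max_iters = as.integer(max_iters),
                 window = as.integer(window),
                 update_scheme = update_scheme,
                 sit_exponent = sit_exponent,
                 weighted_risk = weighted_risk),
            class = "decision_params")
}

#' Initialize vaccination decisions
#'
#' Draws each individual's initial decision independently: `+1` (accept
#' vaccination) with probability `w0`, else `-1` (reject).
#'
#' @param net a [contact_network()].
#' @param w0 initial vaccination willingness in `[0, 1]`.
#' @return Integer vector of decisions in `{+1, -1}`, one per node.
#' @export
initialize_decisions <- function(net, w0) {
  stopifnot(inherits(net, "contact_network"), w0 >= 0, w0 <= 1)
  ifelse(stats::runif(net$n_nodes) < w0, 1L, -1L)
}

#' Vaccination coverage of a decision state
#'
#' @param decisions integer vector with values in `{+1, -1}`.
#' @return Fraction of individuals whose decision is `+1`.
#' @export
coverage <- function(decisions) {
  if (!all(decisions %in% c(-1L, 1L)))
    stop("decisions must take values +1 or -1")
  mean(decisions == 1L)
}

#' Perceived infection risk of one individual
#'
#' The risk an unvaccinated individual perceives is the perceived
#' transmission rate scaled by the proportion of the individual's neighbours
#' that are unvaccinated. By default neighbours are counted without weights;
#' with `weighted = TRUE` the proportion is closeness-weighted. An isolated
#' individual perceives zero risk.
#'
#' @param node 0-based node id.
#' @param decisions decision vector in `{+1, -1}`.
#' @param net a [contact_network()].
#' @param beta_perc perceived transmission rate in `[0, 1]`.
#' @param weighted use closeness-weighted neighbour fractions.
#' @return Perceived risk in `[0, beta_perc]`.
#' @export
#' @examples
#' net <- contact_network(rep(0, 4), 1:4, rep(1, 4))
#' d <- c(-1L, 1L, 1L, 1L, -1L)           # one of the hub's 4 neighbours unvaccinated
#' perceived_risk(0, d, net, beta_perc = 0.4368)  # 0.1092
perceived_risk <- function(node, decisions, net, beta_perc,
                           weighted = FALSE) {
  stopifnot(inherits(net, "contact_network"))
  e <- net$edges
  sel <- e$from == node | e$to == node
  if (!any(sel)) return(0)
  nbr <- ifelse(e$from[sel] == node, e$to[sel], e$from[sel])
  wt <- if (weighted) e$weight[sel] else rep(1, length(nbr))
  unvac <- decisions[nbr + 1L] == -1L
  beta_perc * sum(wt[unvac]) / sum(wt)
}

#' Cost-minimized vaccination choice
#'
#' Minimizing the two-sided cost (vaccination cost versus risk-weighted
#' infection cost) reduces to a threshold rule on the cost ratio: accept
#' vaccination (`+1`) when the perceived risk exceeds `r`, reject (`-1`)
#' when it is below, and keep the previous decision on an exact tie. The tie
#' rule means an unvaccinated individual whose neighbours are all vaccinated
#' stays unvaccinated even at zero vaccination cost.
#'
#' @param lambda perceived infection risk(s) in `[0, 1]`.
#' @param r cost ratio (>= 0).
#' @param previous previous decision(s) in `{+1, -1}`, used on ties.
#' @return Decision(s) in `{+1, -1}`; vectorized over `lambda`/`previous`.
#' @export
cost_minimized_choice <- function(lambda, r, previous) {
  stopifnot(all(lambda >= 0), all(lambda <= 1), r >= 0)
  out <- ifelse(lambda > r, 1L, ifelse(lambda < r, -1L, as.integer(previous)))
  out
}

#' Social-impact influence strengths of the two opinions
#'
#' For each opinion (accept `+1` / reject `-1`), the strength of its social
#' influence on an individual grows with the closeness of the neighbours
#' holding it and with their number at a diminishing rate:
#' `I_o = n_o^exponent * (W_o / n_o) = W_o * n_o^(exponent - 1)`, where
#' `W_o` is the summed edge weight to neighbours with opinion `o` and `n_o`
#' their count (`I_o = 0` when there are none). The default exponent `0.5`
#' gives the classic multi-source diminishing-returns form `W_o / sqrt(n_o)`;
#' `exponent = 1` gives the plain weighted sum and `0` the mean closeness.
#'
#' @param node 0-based node id.
#' @param decisions decision vector in `{+1, -1}`.
#' @param net a [contact_network()].
#' @param exponent source-count exponent (default 0.5).
#' @return Named numeric vector `c(I_plus = ..., I_minus = ...)`.
#' @export
#' @examples
#' net <- contact_network(c(0, 0), c(1, 2), c(2, 8))
#' influence_strengths(0, c(-1L, 1L, 1L), net)  # I_plus = 10/sqrt(2)
influence_strengths <- function(node, decisions, net, exponent = 0.5) {
  stopifnot(inherits(net, "contact_network"))
  e <- net$edges
  sel <- e$from == node | e$to == node
  if (!any(sel)) return(c(I_plus = 0, I_minus = 0))
  nbr <- ifelse(e$from[sel] == node, e$to[sel], e$from[sel])
  wt <- e$weight[sel]
  plus <- decisions[nbr + 1L] == 1L
  strength <- function(w, n) if (n > 0L) sum(w) * n^(exponent - 1) else 0
  c(I_plus = strength(wt[plus], sum(plus)),
    I_minus = strength(wt[!plus], sum(!plus)))
}

#' Normalized influence discrepancy
#'
#' The discrepancy between the influence strengths of acceptance and
#' rejection, normalized to `[-1, 1]`:
#' `(I_plus - I_minus) / (I_plus + I_minus)`, and `0` when both strengths
#' vanish. The relative form is scale-free in the edge weights, so the Fermi
#' responsiveness is comparable across networks with different closeness
#' magnitudes.
#'
#' @param I_plus,I_minus non-negative influence strengths.
#' @return Discrepancy in `[-1, 1]`; vectorized.
#' @export
normalized_discrepancy <- function(I_plus, I_minus) {
  stopifnot(all(I_plus >= 0), all(I_minus >= 0))
  tot <- I_plus + I_minus
  ifelse(tot > 0, (I_plus - I_minus) / tot, 0)
}

#' Fermi probability of a pro-vaccination social opinion
#'
#' Maps the normalized influence discrepancy to the probability that the
#' social opinion formed in an individual's neighbourhood is acceptance of
#' vaccination, through the Fermi (logistic) function
#' `q = 1 / (1 + exp(-delta / kappa))`. At `delta = 0` the two opinions are
#' equally likely; as `kappa` shrinks, the dominant opinion wins with
#' probability approaching 1.
#'
#' @param delta normalized discrepancy in `[-1, 1]`.
#' @param kappa responsiveness (> 0).
#' @return Probability in `(0, 1)`; vectorized over `delta`.
#' @export
#' @examples
#' opinion_probability(0, 0.1)        # 0.5
#' opinion_probability(0.5, 0.5)      # 1 / (1 + exp(-1))
opinion_probability <- function(delta, kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0)
    stop("'kappa' must be a positive number")
  stats::plogis(delta / kappa)
}

#' Final decision under conformity
#'
#' With probability `p` (the conformity rate) the individual adopts the
#' socially formed opinion; otherwise the cost-minimized choice stands.
#'
#' @param cost_choice cost-minimized decision(s) in `{+1, -1}`.
#' @param social_opinion social opinion(s) in `{+1, -1}`.
#' @param p conformity rate in `[0, 1]`.
#' @return Decision(s) in `{+1, -1}`; vectorized; consumes one uniform draw
#'   per element.
#' @export
final_decision <- function(cost_choice, social_opinion, p) {
  stopifnot(p >= 0, p <= 1)
  n <- max(length(cost_choice), length(social_opinion))
  conform <- stats::runif(n) < p
  ifelse(conform, as.integer(social_opinion), as.integer(cost_choice))
}
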
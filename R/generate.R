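#' Generator presets
#'
#' Named parameter bundles for [generate_network()]. The `"highschool"`
#' preset emulates a dense, clustered close-proximity contact network of the
#' kind recorded among students over a school day: 800 nodes, mean degree 35
#' and mean edge weight 115 interaction units, on a small-world topology.
#' Only the two published means are matched; degree and weight dispersions
#' are the generator's own.
#'
#' @param name preset name; currently `"highschool"`.
#' @return A named list of generator parameters accepted by
#'   [generate_network()].
#' @export
#' @examples
#' network_preset("highschool")$mean_degree  # 35
network_preset <- function(name = "highschool") {
  presets <- list(
    highschool = list(n_nodes = 800L, mean_degree = 35, mean_weight = 115,
                      topology = "smallworld", rewire_prob = 0.1,
                      weight_sdlog = 1)
  )
  if (!name %in% names(presets))
    stop("unknown preset: ", name)
  presets[[name]]
}

#' Generate a synthetic weighted contact network
#'
#' Builds a connected undirected network with a prescribed mean degree and
#' i.i.d. positive heavy-tailed edge weights, emulating a school-type
#' close-proximity contact network. Three topologies are available:
#'
#' * `"smallworld"` (default): a ring lattice with `floor(mean_degree/2)`
#'   neighbours per side, topped up with random extra edges so the edge count
#'   hits `round(n_nodes * mean_degree / 2)` exactly, then rewired
#'   edge-by-edge with probability `rewire_prob` (Watts-Strogatz style;
#'   rewirings that would create a loop or duplicate keep the original edge,
#'   so the edge count — and hence the mean degree — is preserved exactly).
#'   School proximity networks are dense and clustered, which this family
#'   captures.
#' * `"random"`: Erdos-Renyi G(n, m) with the same edge count.
#' * `"preferential"`: Barabasi-Albert preferential attachment.
#'
#' Weights are log-normal with `sdlog = weight_sdlog` and `meanlog` solved so
#' the distribution mean equals `mean_weight` (contact-frequency counts are
#' positive and right-skewed). Generation is retried (deterministically, by
#' advancing the stream) until the network is connected, so there are never
#' isolated nodes. The same `seed` and parameters always give the identical
#' network.
#'
#' @param n_nodes number of individuals (>= 2).
#' @param mean_degree target mean degree, in `(0, n_nodes - 1]`.
#' @param mean_weight target mean edge weight (> 0).
#' @param topology one of `"smallworld"`, `"random"`, `"preferential"`.
#' @param rewire_prob per-edge rewiring probability for the small-world
#'   topology.
#' @param weight_sdlog log-scale standard deviation of the weight
#'   distribution.
#' @param seed integer seed; all randomness derives from it.
#' @param preset optional preset name (see [network_preset()]); explicit
#'   arguments override preset entries.
#' @return A [contact_network()].
#' @export
#' @examples
#' net <- generate_network(n_nodes = 100, mean_degree = 10, mean_weight = 50,
#'                         seed = 1)
#' summarize_network(net)
generate_network <- function(n_nodes = NULL, mean_degree = NULL,
                             mean_weight = NULL,
                             topology = c("smallworld", "random", "preferential"),
                             rewire_prob = 0.1, weight_sdlog = 1,
                             seed = 1L, preset = NULL) {
  if (!is.null(preset)) {
    p <- network_preset(preset)
    if (is.null(n_nodes)) n_nodes <- p$n_nodes
    if (is.null(mean_degree)) mean_degree <- p$mean_degree
    if (is.null(mean_weight)) mean_weight <- p$mean_weight
    if (missing(topology)) topology <- p$topology
    if (missing(rewire_prob)) rewire_prob <- p$rewire_prob
    if (missing(weight_sdlog)) weight_sdlog <- p$weight_sdlog
  }
  topology <- match.arg(topology)
  n <- as.integer(n_nodes)
  if (is.na(n) || n < 2L)
    stop("'n_nodes' must be an integer >= 2")
  if (!is.numeric(mean_degree) || mean_degree <= 0 || mean_degree > n - 1L)
    stop("'mean_degree' must lie in (0, n_nodes - 1]")
  if (!is.numeric(mean_weight) || mean_weight <= 0)
    stop("'mean_weight' must be positive")
  m_target <- max(1L, round(n * mean_degree / 2))

  set.seed(as.integer(seed) %% .Machine$integer.max)
  for (attempt in 1:50) {
    ep <- switch(topology,
      smallworld = .gen_smallworld(n, m_target, rewire_prob),
      random = .gen_random(n, m_target),
      preferential = .gen_preferential(n, mean_degree))
    g <- igraph::graph_from_edgelist(cbind(ep$i + 1L, ep$j + 1L),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    if (igraph::is_connected(g)) break
    if (attempt == 50L)
      stop("failed to generate a connected network in 50 attempts; ",
           "increase 'mean_degree'")
  }
  m <- length(ep$i)
  meanlog <- log(mean_weight) - weight_sdlog^2 / 2
  w <- stats::rlnorm(m, meanlog = meanlog, sdlog = weight_sdlog)
  contact_network(ep$i, ep$j, w, n_nodes = n)
}

# ring lattice + random fill-in edges + degree-preserving rewiring
.gen_smallworld <- function(n, m_target, rewire_prob) {
  nei <- max(1L, floor(2 * m_target / n / 2))  # neighbours per side
  v <- 0:(n - 1L)
  i <- rep(v, nei)
  j <- (i + rep(seq_len(nei), each = n)) %% n
  sw <- i > j
  tmp <- i[sw]; i[sw] <- j[sw]; j[sw] <- tmp
  dup <- duplicated(paste(i, j))  # ring wrap-around duplicates when 2*nei >= n
  i <- i[!dup]; j <- j[!dup]
  keyset <- new.env(hash = TRUE, parent = emptyenv())
  for (k in seq_along(i)) assign(paste(i[k], j[k]), TRUE, envir = keyset)
  extra <- m_target - length(i)
  while (extra > 0L) {
    a <- sample.int(n, 1L) - 1L
    b <- sample.int(n, 1L) - 1L
    if (a == b) next
    lo <- min(a, b); hi <- max(a, b)
    key <- paste(lo, hi)
    if (!is.null(keyset[[key]])) next
    assign(key, TRUE, envir = keyset)
    i <- c(i, lo); j <- c(j, hi)
    extra <- extra - 1L
  }
  # rewire: detach one endpoint with prob rewire_prob; reject loops/dupes
  flip <- stats::runif(length(i)) < rewire_prob
  for (k in which(flip)) {
    newb <- sample.int(n, 1L) - 1L
    keep <- i[k]
    if (newb == keep) next
    lo <- min(keep, newb); hi <- max(keep, newb)
    key <- paste(lo, hi)
    if (!is.null(keyset[[key]])) next
    rm(list = paste(i[k], j[k]), envir = keyset)
    assign(key, TRUE, envir = keyset)
    i[k] <- lo; j[k] <- hi
  }
  list(i = i, j = j)
}

.gen_random <- function(n, m_target) {
  g <- igraph::sample_gnm(n, m_target)
  el <- igraph::as_edgelist(g, names = FALSE) - 1L
  list(i = pmin(el[, 1L], el[, 2L]), j = pmax(el[, 1L], el[, 2L]))
}

.gen_preferential <- function(n, mean_degree) {
  g <- igraph::sample_pa(n, m = max(1L, round(mean_degree / 2)),
                         directed = FALSE)
  g <- igraph::simplify(g)
  el <- igraph::as_edgelist(g, names = FALSE) - 1L
  list(i = pmin(el[, 1L], el[, 2L]), j = pmax(el[, 1L], el[, 2L]))
}
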
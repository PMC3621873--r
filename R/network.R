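#' Weighted undirected contact network
#'
#' A `contact_network` stores the social interaction structure over which
#' vaccination decisions and social influence propagate: nodes are
#' individuals, edges are interaction relationships, and the positive edge
#' weight is the social closeness (interaction frequency) between the two
#' endpoints.
#'
#' Nodes are canonicalized to contiguous 0-based integer ids; the original
#' labels (if any) are kept in the `labels` attribute, indexed by id + 1.
#' Edges are stored once with `from < to`; the network is undirected, has no
#' self-loops and no duplicate pairs.
#'
#' @param from,to integer node ids (0-based) of each edge's endpoints.
#' @param weight strictly positive numeric edge weights.
#' @param n_nodes total number of nodes (isolated nodes are allowed at
#'   construction but the loader and generator warn about / avoid them).
#' @param labels optional character vector of original node labels, one per
#'   node.
#'
#' @return An object of class `contact_network`: a list with elements
#'   `edges` (data.frame with columns `from`, `to`, `weight`), `n_nodes`,
#'   and `labels`.
#' @export
#' @examples
#' net <- contact_network(from = c(0, 1, 0), to = c(1, 2, 2),
#'                        weight = c(5, 3, 1), n_nodes = 3)
#' summarize_network(net)
contact_network <- function(from, to, weight, n_nodes = NULL, labels = NULL) {
  from <- as.integer(from)
  to <- as.integer(to)
  weight <- as.numeric(weight)
  if (length(from) != length(to) || length(from) != length(weight))
    stop("'from', 'to' and 'weight' must have equal length")
  if (any(!is.finite(weight)) || any(weight <= 0))
    stop("all edge weights must be finite and strictly positive")
  if (any(from == to))
    stop("self-loops are not allowed")
  if (is.null(n_nodes))
    n_nodes <- if (length(from) == 0L) 0L else max(from, to) + 1L
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 1L)
    stop("a contact network must contain at least one node")
  if (length(from) > 0L && (min(from, to) < 0L || max(from, to) >= n_nodes))
    stop("node ids must lie in 0..n_nodes-1")
  # canonical orientation from < to, canonical row order
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  key <- from * as.numeric(n_nodes) + to
  if (anyDuplicated(key))
    stop("duplicate edges after canonicalization; merge them before construction")
  ord <- order(from, to)
  edges <- data.frame(from = from[ord], to = to[ord], weight = weight[ord])
  if (!is.null(labels) && length(labels) != n_nodes)
    stop("'labels' must have one entry per node")
  structure(list(edges = edges, n_nodes = n_nodes, labels = labels),
            class = "contact_network")
}

#' @export
print.contact_network <- function(x, ...) {
  s <- summarize_network(x)
  cat(sprintf(
    "contact_network: %d nodes, %d edges (mean degree %.2f, mean weight %.2f)\n",
    s$n_nodes, s$n_edges, s$mean_degree, s$mean_edge_weight))
  invisible(x)
}

#' Node degrees of a contact network
#'
#' @param net a [contact_network()].
#' @return Integer vector of (unweighted) degrees, one per node id 0..N-1.
#' @export
network_degrees <- function(net) {
  stopifnot(inherits(net, "contact_network"))
  tabulate(c(net$edges$from, net$edges$to) + 1L, nbins = net$n_nodes)
}

#' Summary statistics of a contact network
#'
#' Computes the node and edge counts, the mean (unweighted) node degree
#' `2 * n_edges / n_nodes`, the mean edge weight (mean social closeness), and
#' the minimum degree.
#'
#' @param net a [contact_network()].
#' @return A list of class `network_summary` with fields `n_nodes`,
#'   `n_edges`, `mean_degree`, `mean_edge_weight`, `min_degree`.
#' @export
#' @examples
#' net <- contact_network(c(0, 1, 0), c(1, 2, 2), c(5, 3, 1))
#' summarize_network(net)$mean_edge_weight  # 3
summarize_network <- function(net) {
  stopifnot(inherits(net, "contact_network"))
  deg <- network_degrees(net)
  m <- nrow(net$edges)
  structure(list(
    n_nodes = net$n_nodes,
    n_edges = m,
    mean_degree = 2 * m / net$n_nodes,
    mean_edge_weight = if (m > 0L) mean(net$edges$weight) else NaN,
    min_degree = if (net$n_nodes > 0L) min(deg) else NA_integer_
  ), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf(
    paste0("network summary: %d nodes, %d edges\n",
           "  mean degree:      %.3f (min %d)\n",
           "  mean edge weight: %.3f\n"),
    x$n_nodes, x$n_edges, x$mean_degree, x$min_degree, x$mean_edge_weight))
  invisible(x)
}

#' Read a weighted edge list
#'
#' Reads a whitespace- or tab-separated edge list (`node_a node_b weight`,
#' `#`-comments and blank lines ignored), canonicalizes node labels to
#' contiguous 0-based integer ids, and merges duplicate `(i,j)`/`(j,i)` lines
#' according to `dialect`. The default dialect sums the weights of repeated
#' pairs, treating each line as one batch of interactions so the stored
#' closeness is the total interaction frequency between the two individuals.
#'
#' @param path path to the edge-list file.
#' @param dialect how to merge duplicate pairs: `"sum"` (default), `"max"`,
#'   or `"error"` to refuse duplicates.
#' @return A [contact_network()]; original labels are kept in `$labels`.
#' @export
read_edge_list <- function(path, dialect = c("sum", "max", "error")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop("edge-list file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- seq_along(raw)[keep]
  if (length(lines) == 0L)
    stop("edge-list file contains no edges (empty network): ", path)
  toks <- strsplit(trimws(lines), "\\s+")
  nt <- lengths(toks)
  if (any(nt != 3L))
    stop(sprintf("malformed edge line %d: expected 'node node weight', got %d token(s)",
                 lineno[which(nt != 3L)[1L]], nt[which(nt != 3L)[1L]]))
  a <- vapply(toks, `[`, character(1), 1L)
  b <- vapply(toks, `[`, character(1), 2L)
  w <- suppressWarnings(as.numeric(vapply(toks, `[`, character(1), 3L)))
  if (anyNA(w))
    stop(sprintf("malformed edge line %d: non-numeric weight", lineno[which(is.na(w))[1L]]))
  if (any(w <= 0))
    stop(sprintf("invalid edge line %d: weight must be strictly positive",
                 lineno[which(w <= 0)[1L]]))
  if (any(a == b))
    stop(sprintf("invalid edge line %d: self-loop", lineno[which(a == b)[1L]]))
  labels <- unique(c(a, b))
  # numeric labels sort numerically so ids survive write/read round trips
  labels <- if (all(grepl("^-?[0-9]+$", labels)))
    labels[order(as.numeric(labels))] else sort(labels)
  i <- match(a, labels) - 1L
  j <- match(b, labels) - 1L
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  key <- paste(i, j)
  if (anyDuplicated(key)) {
    if (dialect == "error") {
      dup <- which(duplicated(key))[1L]
      stop(sprintf("duplicate edge at line %d under dialect 'error'", lineno[dup]))
    }
    agg <- if (dialect == "sum") rowsum(w, key) else as.matrix(tapply(w, key, max))
    parts <- strsplit(rownames(agg), " ")
    i <- as.integer(vapply(parts, `[`, character(1), 1L))
    j <- as.integer(vapply(parts, `[`, character(1), 2L))
    w <- as.numeric(agg[, 1L])
  }
  net <- contact_network(i, j, w, n_nodes = length(labels), labels = labels)
  if (min(network_degrees(net)) == 0L)
    warning("network contains isolated nodes; they take part in cost-based decisions only")
  net
}

#' Write a weighted edge list
#'
#' Writes the network in the canonical order (`from < to`, rows sorted), one
#' edge per line as `from\tto\tweight`. Original labels, when present, are
#' written instead of the integer ids. A write followed by [read_edge_list()]
#' reproduces an equal network.
#'
#' @param net a [contact_network()] with at least one edge.
#' @param path output file path.
#' @param use_labels write original labels when available (default `TRUE`).
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(net, path, use_labels = TRUE) {
  stopifnot(inherits(net, "contact_network"))
  if (nrow(net$edges) == 0L)
    stop("refusing to write a network with no edges")
  e <- net$edges
  if (use_labels && !is.null(net$labels)) {
    a <- net$labels[e$from + 1L]
    b <- net$labels[e$to + 1L]
  } else {
    a <- e$from
    b <- e$to
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(a, b, sprintf("%.15g", e$weight), sep = "\t"), con)
  invisible(path)
}

# adjacency in sparse form; cached on the network object by callers that
# iterate (weights matrix A and its 0/1 pattern B, both symmetric dgCMatrix)
network_adjacency <- function(net) {
  e <- net$edges
  n <- net$n_nodes
  i <- c(e$from, e$to) + 1L
  j <- c(e$to, e$from) + 1L
  A <- Matrix::sparseMatrix(i = i, j = j, x = rep(e$weight, 2L), dims = c(n, n))
  B <- Matrix::sparseMatrix(i = i, j = j, x = rep(1, 2L * nrow(e)), dims = c(n, n))
  list(A = A, B = B)
}

# neighbour lists for asynchronous updates
network_neighbors <- function(net) {
  e <- net$edges
  n <- net$n_nodes
  nb <- split(c(e$to, e$from), factor(c(e$from, e$to), levels = 0:(n - 1L)))
  wt <- split(c(e$weight, e$weight), factor(c(e$from, e$to), levels = 0:(n - 1L)))
  list(nbr = lapply(nb, as.integer), wt = lapply(wt, as.numeric))
}
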
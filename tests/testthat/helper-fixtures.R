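# small programmatic fixtures shared across test files

make_triangle <- function(weights = c(5, 3, 1)) {
  contact_network(from = c(0, 1, 0), to = c(1, 2, 2), weight = weights)
}

# hub is node 0; leaves 1..n_leaves
make_star <- function(n_leaves = 4, weight = 1) {
  contact_network(from = rep(0, n_leaves), to = seq_len(n_leaves),
                  weight = rep(weight, n_leaves))
}

write_edges_tmp <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# modest test network: connected, clustered, fast to simulate on
test_network <- function(seed = 1, n = 120, d = 10, w = 20) {
  generate_network(n_nodes = n, mean_degree = d, mean_weight = w, seed = seed)
}
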
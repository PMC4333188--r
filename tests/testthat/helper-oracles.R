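# Brute-force oracles kept independent of the package's code paths: they
# work on plain adjacency matrices and use exhaustive enumeration only.

oracle_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\t")

# G(n, p) with named nodes; returns the igraph object (input construction)
# together with the raw adjacency matrix the oracles consume
rand_adj_graph <- function(n, p) {
  nodes <- sprintf("v%02d", seq_len(n))
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  ut <- upper.tri(adj)
  adj[ut] <- stats::runif(sum(ut)) < p
  adj <- adj | t(adj)
  g <- igraph::graph_from_adjacency_matrix(1 * adj, mode = "undirected")
  list(graph = g, adj = adj, nodes = nodes)
}

oracle_subset_is_clique <- function(adj, members) {
  sub <- adj[members, members, drop = FALSE]
  all(sub[upper.tri(sub)])
}

oracle_has_k_clique <- function(adj, k) {
  n <- nrow(adj)
  if (n < k) return(FALSE)
  hits <- utils::combn(n, k, FUN = function(idx) {
    oracle_subset_is_clique(adj, idx)
  })
  any(hits)
}

oracle_density <- function(adj, members) {
  sub <- adj[members, members, drop = FALSE]
  n <- length(members)
  2 * sum(sub[upper.tri(sub)]) / (n * (n - 1))
}

# convenience: small named test network from parallel endpoint vectors
toy_net <- function(a, b) network_from_pairs(a, b, quiet = TRUE)

# complete graph on the given identifiers
toy_clique <- function(ids) {
  cmb <- utils::combn(ids, 2L)
  toy_net(cmb[1L, ], cmb[2L, ])
}
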
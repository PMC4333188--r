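#' Density of an induced subnetwork
#'
#' The density of a node set is `2m / (n(n-1))`, where `n` is the number of
#' members and `m` the number of network edges induced on them: the fraction
#' of possible member pairs that interact. A clique has density 1.
#'
#' @param network An igraph network with named vertices.
#' @param members Character vector of member identifiers (at least 2, all
#'   present in the network).
#' @return A single number in `[0, 1]`.
#' @examples
#' g <- network_from_pairs(c("a", "a", "b"), c("b", "c", "c"), quiet = TRUE)
#' subnet_density(g, c("a", "b", "c"))  # 1
#' @export
subnet_density <- function(network, members) {
  members <- unique(as.character(members))
  n <- length(members)
  if (n < 2L) stop("density is undefined for fewer than 2 members")
  missing <- setdiff(members, igraph::V(network)$name)
  if (length(missing)) {
    stop("member(s) not in the network: ", paste(missing, collapse = ", "))
  }
  m <- igraph::ecount(igraph::induced_subgraph(network, members))
  2 * m / (n * (n - 1))
}

#' Find a k-clique among candidate nodes
#'
#' Searches the subgraph induced on `candidates` for a complete subnetwork of
#' `k` nodes to serve as an extension seed. In the adaptive k-core
#' decomposition this seed is called a "k-core": a complete subnet of k
#' nodes, i.e. a k-clique -- not the graph-theoretic k-core (maximal subgraph
#' of minimum degree k). Clique semantics are used throughout.
#'
#' With `mode = "deterministic"` the clique whose sorted member tuple is
#' lexicographically smallest is returned, which makes whole runs
#' reproducible without an RNG. With `mode = "random"` one clique is drawn
#' uniformly from the enumeration using R's RNG (use [set.seed()] for
#' reproducibility).
#'
#' Enumeration is exhaustive over the induced subgraph; detected complexes
#' are small, so this is fast in practice.
#'
#' @param network An igraph network with named vertices.
#' @param candidates Character vector of candidate node identifiers
#'   (silently intersected with the network's node set).
#' @param k Seed clique size, an integer `>= 2`.
#' @param mode `"deterministic"` (default) or `"random"`.
#' @return Sorted character vector of `k` members, or `NULL` if the induced
#'   subgraph contains no k-clique.
#' @export
find_k_clique <- function(network, candidates,
                          k, mode = c("deterministic", "random")) {
  mode <- match.arg(mode)
  if (!is.numeric(k) || length(k) != 1L || k < 2L || k != round(k)) {
    stop("'k' must be a single integer >= 2")
  }
  k <- as.integer(k)
  candidates <- intersect(unique(as.character(candidates)),
                          igraph::V(network)$name)
  if (length(candidates) < k) return(NULL)
  sub <- igraph::induced_subgraph(network, candidates)
  cl <- igraph::cliques(sub, min = k, max = k)
  if (!length(cl)) return(NULL)
  tuples <- lapply(cl, function(v) sort(igraph::V(sub)$name[v]))
  if (mode == "random") {
    return(tuples[[sample.int(length(tuples), 1L)]])
  }
  ord <- do.call(order, as.data.frame(do.call(rbind, tuples),
                                      stringsAsFactors = FALSE))
  tuples[[ord[1L]]]
}

#' Greedily extend a clique seed under a density threshold
#'
#' Starting from a clique seed, repeatedly picks the candidate node with the
#' most connections into the current subnet (ties broken by lexicographically
#' smallest identifier) and appends it if the extended subnet's density stays
#' strictly above `lambda`. Extension stops at the first rejection, when the
#' best candidate has no connection into the subnet, or when the candidate
#' pool is exhausted. The returned subnet always has density `> lambda`
#' because a clique has density 1.
#'
#' @param network An igraph network with named vertices.
#' @param seed Character vector forming a clique in the network.
#' @param candidates Pool the extension may draw from (must contain the
#'   seed); in complex decomposition this is the remaining complex members,
#'   never the whole network.
#' @param lambda Density threshold in `(0, 1]`; a candidate is accepted only
#'   if the extended density is strictly greater than `lambda`.
#' @return A `ppi_subnet`: list with `members` (sorted), `n`, `edge_count`,
#'   and `density`.
#' @export
greedy_extend <- function(network, seed, candidates, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0 || lambda > 1) {
    stop("'lambda' must be a single number in (0, 1]")
  }
  seed <- unique(as.character(seed))
  candidates <- unique(as.character(candidates))
  if (!all(seed %in% candidates)) stop("'seed' must be contained in 'candidates'")
  n0 <- length(seed)
  if (n0 < 2L) stop("seed must have at least 2 members")
  m <- igraph::ecount(igraph::induced_subgraph(network, seed))
  if (m != choose(n0, 2L)) stop("'seed' is not a clique in the network")

  current <- seed
  pool <- setdiff(candidates, current)
  while (length(pool)) {
    conn <- vapply(pool, function(v) {
      sum(igraph::as_ids(igraph::neighbors(network, v)) %in% current)
    }, integer(1))
    best <- max(conn)
    if (best == 0L) break
    node <- sort(pool[conn == best])[1L]
    n2 <- length(current) + 1L
    m2 <- m + best
    if (2 * m2 / (n2 * (n2 - 1)) > lambda) {
      current <- c(current, node)
      m <- m2
      pool <- setdiff(pool, node)
    } else {
      break
    }
  }
  new_subnet(current, m)
}

new_subnet <- function(members, edge_count) {
  members <- sort(members)
  n <- length(members)
  structure(list(members = members, n = n, edge_count = edge_count,
                 density = 2 * edge_count / (n * (n - 1))),
            class = "ppi_subnet")
}

#' @export
print.ppi_subnet <- function(x, ...) {
  cat(sprintf("Subnet: %d proteins, %d edges, density %.3f\n",
              x$n, x$edge_count, x$density))
  cat(" ", paste(x$members, collapse = " "), "\n")
  invisible(x)
}

#' Decompose one protein complex into dense subnetworks
#'
#' The adaptive k-core decomposition: find a k-clique among the remaining
#' complex members; extend it greedily under the density threshold
#' ([greedy_extend()]); prune the resulting subnet from the complex; repeat
#' on the residue. When no k-clique remains, the residue is abandoned --
#' loosely connected proteins take no part in prediction.
#'
#' Complex members absent from the network are ignored with a warning
#' (complex detectors and networks may come from different snapshots).
#'
#' @param network An igraph network with named vertices.
#' @param members Character vector: the complex's member proteins.
#' @param k Seed clique size (the paper's runs used 4 or 7 depending on the
#'   scale of the detected complexes).
#' @param lambda Density threshold; retained subnets have density strictly
#'   greater than `lambda`. Default 0.7, the usual trade-off for judging a
#'   PPI subnet dense.
#' @param mode Seed selection mode, see [find_k_clique()].
#' @return List of `ppi_subnet` objects (pairwise node-disjoint, each with at
#'   least `k` members and density `> lambda`), with the abandoned members in
#'   `attr(, "abandoned")`.
#' @export
decompose_complex <- function(network, members, k, lambda = 0.7,
                              mode = c("deterministic", "random")) {
  mode <- match.arg(mode)
  members <- unique(as.character(members))
  known <- members %in% igraph::V(network)$name
  if (any(!known)) {
    warning(sum(!known), " complex member(s) absent from the network; ignored")
  }
  remaining <- members[known]
  subnets <- list()
  repeat {
    seed <- find_k_clique(network, remaining, k, mode)
    if (is.null(seed)) break
    sn <- greedy_extend(network, seed, remaining, lambda)
    subnets[[length(subnets) + 1L]] <- sn
    remaining <- setdiff(remaining, sn$members)
  }
  attr(subnets, "abandoned") <- sort(remaining)
  subnets
}

#' Decompose every complex of a complex set
#'
#' @param network An igraph network with named vertices.
#' @param complexes A `complex_set` (or named list of member vectors).
#' @inheritParams decompose_complex
#' @return Named list (one element per complex) of [decompose_complex()]
#'   results.
#' @export
decompose_complexes <- function(network, complexes, k, lambda = 0.7,
                                mode = c("deterministic", "random")) {
  mode <- match.arg(mode)
  if (is.null(names(complexes))) {
    names(complexes) <- sprintf("C%04d", seq_along(complexes))
  }
  lapply(complexes, function(m) {
    decompose_complex(network, m, k = k, lambda = lambda, mode = mode)
  })
}
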
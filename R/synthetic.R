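#' Simulate a PPI network with planted complexes and held-out edges
#'
#' Generates the full benchmark bundle for the prediction pipeline: a network
#' in which dense "complexes" are planted on a sparse background, the
#' complex membership lists (the analogue of detector output), a set of
#' within-complex edges removed from the network ("held-out" edges, the
#' recoverable ground truth for link prediction), and evaluation references.
#'
#' Construction, fully reproducible from `seed`:
#' * complex member sets are minted first; with `overlap_fraction > 0`,
#'   consecutive complexes share `ceiling(overlap_fraction * size)` nodes,
#'   which exercises repetition counting;
#' * each distinct within-complex pair becomes an edge independently with
#'   probability `p_within`; every other node pair becomes a background edge
#'   with probability `p_background` (`p_within > p_background` is required:
#'   planted modules must be denser than the background);
#' * per complex, `floor(holdout_fraction * m)` of its realized edges are
#'   removed uniformly at random and recorded as held-out;
#' * the gold-standard positive set is the held-out edges plus a sample of
#'   the kept within-complex edges; the gold-standard negative set is a
#'   sample of cross-complex pairs that are not edges (the natural analogue
#'   of a different-compartment negative set); the reference interactome is
#'   the full realized within-complex edge set (kept and held-out);
#' * each complex contributes an annotation term named
#'   `"protein complex <i>"` for its members, plus a generic `"cytoplasm"`
#'   term for every protein.
#'
#' @param n_background Number of background proteins (default 150).
#' @param p_background Background edge probability (default 0.02).
#' @param complex_sizes Integer sizes of the planted complexes
#'   (default `c(8, 9, 10, 11, 12)`).
#' @param p_within Within-complex edge probability (default 1: planted
#'   complexes are cliques before holdout).
#' @param holdout_fraction Fraction of each complex's edges removed
#'   (default 0.1).
#' @param overlap_fraction Fraction of each complex shared with its
#'   predecessor (default 0).
#' @param seed Optional integer; when given, the generator runs under
#'   [withr::with_seed()] and is fully reproducible.
#' @return A `planted_ppi` list: `network` (igraph), `complexes`
#'   (`complex_set`), `held_out`, `gs_positive`, `gs_negative`, `reference`
#'   (canonical pair keys), `annotations` (data frame), and `params`.
#' @export
simulate_ppi <- function(n_background = 150L, p_background = 0.02,
                         complex_sizes = c(8L, 9L, 10L, 11L, 12L),
                         p_within = 1, holdout_fraction = 0.1,
                         overlap_fraction = 0, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, simulate_ppi(
      n_background = n_background, p_background = p_background,
      complex_sizes = complex_sizes, p_within = p_within,
      holdout_fraction = holdout_fraction,
      overlap_fraction = overlap_fraction, seed = NULL)))
  }
  if (p_within <= p_background) {
    stop("'p_within' must exceed 'p_background': planted complexes must be ",
         "denser than the background")
  }
  if (holdout_fraction < 0 || holdout_fraction >= 1) {
    stop("'holdout_fraction' must be in [0, 1)")
  }
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("'overlap_fraction' must be in [0, 1)")
  }
  if (any(complex_sizes < 2L)) stop("complex sizes must be >= 2")

  # mint complex members, chaining overlaps between consecutive complexes
  comps <- vector("list", length(complex_sizes))
  next_id <- 1L
  for (i in seq_along(complex_sizes)) {
    size <- as.integer(complex_sizes[i])
    n_share <- if (i > 1L) {
      min(ceiling(overlap_fraction * size), length(comps[[i - 1L]]), size - 1L)
    } else 0L
    shared <- if (n_share) utils::tail(comps[[i - 1L]], n_share) else character(0)
    fresh <- sprintf("P%04d", next_id + seq_len(size - n_share) - 1L)
    next_id <- next_id + size - n_share
    comps[[i]] <- c(shared, fresh)
  }
  comps <- complex_set(comps)
  complex_nodes <- sort(unique(unlist(comps)))
  background <- if (n_background > 0L) {
    sprintf("B%04d", seq_len(n_background))
  } else character(0)
  nodes <- c(complex_nodes, background)

  # one Bernoulli draw per distinct pair
  within_by_complex <- lapply(comps, all_pair_keys)
  within_all <- sort(unique(unlist(within_by_complex)))
  within_realized <- within_all[stats::runif(length(within_all)) < p_within]
  bg_candidates <- setdiff(all_pair_keys(nodes), within_all)
  bg_edges <- bg_candidates[stats::runif(length(bg_candidates)) < p_background]

  # per-complex edge holdout
  held <- character(0)
  for (pk in within_by_complex) {
    realized <- intersect(pk, within_realized)
    n_rm <- floor(holdout_fraction * length(realized))
    if (n_rm > 0L) {
      held <- union(held, realized[sample.int(length(realized), n_rm)])
    }
  }
  edges <- setdiff(c(within_realized, bg_edges), held)
  if (!length(edges)) stop("simulated network has no edges; increase sizes")
  ef <- pair_frame(edges)
  network <- network_from_pairs(ef$protein_a, ef$protein_b, quiet = TRUE)

  # gold standard: held-out + kept-within sample vs cross-complex non-edges
  kept_within <- setdiff(within_realized, held)
  pos_extra <- if (length(kept_within)) {
    kept_within[sample.int(length(kept_within),
                           ceiling(length(kept_within) / 4))]
  } else character(0)
  gs_positive <- union(held, pos_extra)
  member_of <- split(rep(seq_along(comps), lengths(comps)), unlist(comps))
  cpairs <- setdiff(all_pair_keys(complex_nodes), within_all)
  cf <- pair_frame(cpairs)
  cross_nonedge <- cpairs[!cpairs %in% edges &
                            !mapply(function(a, b) {
                              length(intersect(member_of[[a]],
                                               member_of[[b]])) > 0L
                            }, cf$protein_a, cf$protein_b)]
  n_neg <- min(length(cross_nonedge), 10L * max(1L, length(gs_positive)))
  gs_negative <- if (n_neg > 0L) {
    cross_nonedge[sample.int(length(cross_nonedge), n_neg)]
  } else character(0)

  annotations <- rbind(
    do.call(rbind, lapply(seq_along(comps), function(i) {
      data.frame(protein = comps[[i]],
                 term_id = sprintf("T%04d", i),
                 term_name = sprintf("protein complex %d", i),
                 stringsAsFactors = FALSE)
    })),
    data.frame(protein = nodes, term_id = "T0000",
               term_name = "cytoplasm", stringsAsFactors = FALSE))

  structure(list(network = network, complexes = comps,
                 held_out = sort(held), gs_positive = sort(gs_positive),
                 gs_negative = sort(gs_negative),
                 reference = sort(within_realized),
                 annotations = annotations,
                 params = list(n_background = n_background,
                               p_background = p_background,
                               complex_sizes = as.integer(complex_sizes),
                               p_within = p_within,
                               holdout_fraction = holdout_fraction,
                               overlap_fraction = overlap_fraction)),
            class = "planted_ppi")
}

#' @export
print.planted_ppi <- function(x, ...) {
  cat("Planted PPI benchmark:",
      igraph::vcount(x$network), "proteins,",
      igraph::ecount(x$network), "edges,",
      length(x$complexes), "planted complexes,",
      length(x$held_out), "held-out edges\n")
  invisible(x)
}

#' Precision and recall against held-out edges
#'
#' The parameter-recovery harness: precision is the fraction of predictions
#' that are held-out edges, recall the fraction of held-out edges that were
#' predicted. An empty prediction set leaves precision undefined (`NA`, with
#' a warning); recall is still computed.
#'
#' @param pred Predictions in any representation accepted by
#'   [as_pair_keys()].
#' @param truth Held-out edges: a `planted_ppi` object or a pair set.
#' @return List with `precision` and `recall`.
#' @export
recovery_metrics <- function(pred, truth) {
  held <- if (inherits(truth, "planted_ppi")) truth$held_out else truth
  held <- as_pair_keys(held)
  keys <- as_pair_keys(pred)
  hits <- length(intersect(keys, held))
  precision <- if (length(keys)) {
    hits / length(keys)
  } else {
    warning("empty prediction set: precision undefined")
    NA_real_
  }
  recall <- if (length(held)) hits / length(held) else NaN
  list(precision = precision, recall = recall)
}

#' Size-matched random link predictor
#'
#' Baseline comparator: draws `size` pairs uniformly without replacement from
#' the non-adjacent node pairs of the network. Enumerates all pairs, so it is
#' intended for benchmark-scale networks.
#'
#' @param network An igraph network with named vertices.
#' @param size Number of pairs to draw (uses R's RNG; set a seed for
#'   reproducibility).
#' @return Character vector of `size` canonical pair keys.
#' @export
random_predictor <- function(network, size) {
  nonedges <- setdiff(all_pair_keys(igraph::V(network)$name),
                      network_edge_keys(network))
  if (size > length(nonedges)) {
    stop("requested more pairs than there are non-edges")
  }
  if (size == 0L) return(character(0))
  nonedges[sample.int(length(nonedges), size)]
}
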
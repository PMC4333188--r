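#' Predict the missing interactions inside one subnet
#'
#' Every unordered pair of subnet members that is not an edge of the original
#' network is emitted as a predicted interaction: proteins in a dense,
#' tightly connected subnet are expected to interact, so the absent pairs are
#' the candidate false negatives. The count always equals
#' `n(n-1)/2 - m` for a subnet of `n` members inducing `m` edges.
#'
#' @param network An igraph network with named vertices.
#' @param members Subnet member identifiers (a `ppi_subnet`'s `members`, or
#'   any character vector of network nodes).
#' @return Character vector of canonical pair keys (possibly empty).
#' @export
predict_subnet_pairs <- function(network, members) {
  if (inherits(members, "ppi_subnet")) members <- members$members
  members <- unique(as.character(members))
  missing <- setdiff(members, igraph::V(network)$name)
  if (length(missing)) {
    stop("member(s) not in the network: ", paste(missing, collapse = ", "))
  }
  if (length(members) < 2L) return(character(0))
  sub <- igraph::induced_subgraph(network, members)
  setdiff(all_pair_keys(members), network_edge_keys(sub))
}

#' Construct a prediction set
#'
#' A prediction set maps each unique canonical pair to its repetition count
#' `h` (how many subnets predicted it) and its provenance. It is a data frame
#' with columns `protein_a`, `protein_b`, `h`, `sources`, ordered by
#' decreasing `h` and then by pair.
#'
#' @param protein_a,protein_b Identifier vectors (canonicalized on input).
#' @param h Integer repetition counts (`>= 1`).
#' @param sources Semicolon-joined `complex/subnet` provenance strings.
#' @return A `prediction_set` data frame.
#' @export
prediction_set <- function(protein_a = character(0),
                           protein_b = character(0),
                           h = integer(0), sources = character(0)) {
  if (length(protein_a)) {
    pf <- pair_frame(pair_keys(protein_a, protein_b))
  } else {
    pf <- pair_frame(character(0))
  }
  df <- data.frame(protein_a = pf$protein_a, protein_b = pf$protein_b,
                   h = as.integer(h), sources = as.character(sources),
                   stringsAsFactors = FALSE)
  if (any(df$h < 1L)) stop("repetition counts must be >= 1")
  if (anyDuplicated(paste(df$protein_a, df$protein_b))) {
    stop("duplicate pairs in prediction set")
  }
  df <- df[order(-df$h, df$protein_a, df$protein_b), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("prediction_set", "data.frame")
  df
}

#' @export
print.prediction_set <- function(x, n = 10L, ...) {
  cat("PPI prediction set:", nrow(x), "pair(s)")
  if (nrow(x)) cat(", h in [", min(x$h), ",", max(x$h), "]")
  cat("\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), n))
  if (nrow(x) > n) cat("...", nrow(x) - n, "more row(s)\n")
  invisible(x)
}

#' Aggregate per-subnet predictions with repetition counting
#'
#' Merges the pair sets predicted by individual subnets into one prediction
#' set. Each pair starts with `h = 1`; every additional subnet (typically
#' from another, overlapping complex) that predicts the same pair increments
#' `h` by one. The provenance of each pair is recorded in input order, so
#' `h` always equals the number of recorded sources and the sum of `h` over
#' unique pairs equals the total number of pair-predictions emitted.
#'
#' @param per_subnet List of entries `list(complex = <id>, subnet = <index>,
#'   pairs = <canonical keys>)`, one per retained subnet.
#' @return A `prediction_set`.
#' @export
aggregate_predictions <- function(per_subnet) {
  if (!length(per_subnet)) return(prediction_set())
  keys <- unlist(lapply(per_subnet, function(e) as_pair_keys(e$pairs)),
                 use.names = FALSE)
  src <- unlist(lapply(per_subnet, function(e) {
    rep(paste0(e$complex, "/", e$subnet), length(as_pair_keys(e$pairs)))
  }), use.names = FALSE)
  if (!length(keys)) return(prediction_set())
  grp <- split(src, keys)  # within-group order follows input order
  pf <- pair_frame(names(grp))
  prediction_set(pf$protein_a, pf$protein_b,
                 h = lengths(grp),
                 sources = vapply(grp, paste, character(1), collapse = ";"))
}

#' Filter predictions by repetition count
#'
#' Keeps the pairs predicted by at least `min_h` subnets. Repeatedly
#' predicted pairs are more reliable, so `min_h = 2` selects the
#' high-confidence subset (the "h > 1" adjustment); `min_h = 1` is the
#' identity.
#'
#' @param pred A `prediction_set`.
#' @param min_h Minimum repetition count, an integer `>= 1`.
#' @return The filtered `prediction_set` (sources preserved).
#' @export
filter_by_repetition <- function(pred, min_h) {
  stopifnot(inherits(pred, "prediction_set"))
  if (!is.numeric(min_h) || length(min_h) != 1L || min_h < 1L) {
    stop("'min_h' must be a single integer >= 1")
  }
  out <- pred[pred$h >= min_h, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict interactions from a complex set: the full pipeline
#'
#' Runs the adaptive k-core decomposition over every complex, predicts the
#' missing pairs inside each retained subnet, aggregates them with repetition
#' counting, and applies the `min_h` filter. A run report (complex, subnet
#' and abandoned-protein counts, the h histogram before filtering, and all
#' parameters) is attached as `attr(, "report")`.
#'
#' @param network An igraph network with named vertices.
#' @param complexes A `complex_set`, a named list of member vectors, or a
#'   single character vector (treated as one complex).
#' @inheritParams decompose_complex
#' @param min_h Repetition filter applied to the aggregate, see
#'   [filter_by_repetition()].
#' @return A `prediction_set` with a `"report"` attribute.
#' @export
predict_interactions <- function(network, complexes, k, lambda = 0.7,
                                 min_h = 1L,
                                 mode = c("deterministic", "random")) {
  mode <- match.arg(mode)
  if (is.character(complexes)) complexes <- list(complexes)
  if (is.null(names(complexes))) {
    names(complexes) <- sprintf("C%04d", seq_along(complexes))
  }
  decomp <- decompose_complexes(network, complexes, k = k, lambda = lambda,
                                mode = mode)
  per <- list()
  for (id in names(decomp)) {
    sns <- decomp[[id]]
    for (i in seq_along(sns)) {
      per[[length(per) + 1L]] <-
        list(complex = id, subnet = i,
             pairs = predict_subnet_pairs(network, sns[[i]]))
    }
  }
  agg <- aggregate_predictions(per)
  out <- filter_by_repetition(agg, min_h)
  attr(out, "report") <- list(
    k = k, lambda = lambda, min_h = min_h, mode = mode,
    n_complexes = length(complexes),
    n_subnets = sum(vapply(decomp, length, integer(1))),
    n_abandoned = sum(vapply(decomp, function(d) {
      length(attr(d, "abandoned"))
    }, integer(1))),
    n_emitted = sum(vapply(per, function(e) length(e$pairs), integer(1))),
    h_histogram = if (nrow(agg)) table(h = agg$h) else table(h = integer(0)))
  out
}
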
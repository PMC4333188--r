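#' Read a protein-protein interaction network from an edge list
#'
#' Reads a two-column delimited edge list (DIP-style export: one interacting
#' pair per line, identifiers separated by tabs or spaces; lines starting with
#' `#` are comments) and returns a cleaned undirected network. Cleaning
#' mirrors the usual preprocessing of high-throughput interactomes:
#' self-interactions are dropped and duplicate records -- including reversed
#' duplicates -- are collapsed to a single canonical edge. The number of
#' records dropped by each rule is reported with a message.
#'
#' @param path Path to the edge-list file.
#' @return An [igraph][igraph::graph_from_edgelist] object: simple, undirected,
#'   with protein identifiers as vertex names.
#' @examples
#' f <- tempfile()
#' writeLines(c("A\tB", "B\tA", "C\tC", "B\tC"), f)
#' g <- read_network(f)
#' igraph::vcount(g)  # 3
#' igraph::ecount(g)  # 2
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    stop("no interaction records found in '", path, "'")
  }
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  bad <- which(lengths(fields) != 2L)
  if (length(bad)) {
    stop(sprintf("malformed line %d in '%s': expected 2 columns, found %d",
                 which(keep)[bad[1L]], path, lengths(fields)[bad[1L]]))
  }
  a <- vapply(fields, `[[`, character(1), 1L)
  b <- vapply(fields, `[[`, character(1), 2L)
  network_from_pairs(a, b)
}

#' Build a cleaned network from identifier vectors
#'
#' Worker behind [read_network()], exposed because synthetic data and tests
#' build networks programmatically. Self-pairs are removed, and duplicate or
#' reversed-duplicate pairs are collapsed.
#'
#' @param a,b Equal-length character vectors: endpoints of each record.
#' @param quiet Suppress the message about dropped records.
#' @return A simple undirected igraph object with named vertices.
#' @export
network_from_pairs <- function(a, b, quiet = FALSE) {
  a <- as.character(a)
  b <- as.character(b)
  self <- a == b
  keys <- pair_keys(a[!self], b[!self])
  dup <- duplicated(keys)
  if (!quiet && (any(self) || any(dup))) {
    message("dropped ", sum(self), " self-interaction(s) and ",
            sum(dup), " duplicate record(s)")
  }
  keys <- keys[!dup]
  if (!length(keys)) stop("network has no edges after cleaning")
  el <- pair_frame(keys)
  igraph::graph_from_edgelist(as.matrix(el), directed = FALSE)
}

#' Canonical edge keys of a network
#'
#' @param network An igraph network with named vertices.
#' @return Character vector of canonical pair keys, one per edge.
#' @export
network_edge_keys <- function(network) {
  el <- igraph::as_edgelist(network, names = TRUE)
  if (!nrow(el)) return(character(0))
  pair_keys(el[, 1L], el[, 2L])
}

#' Write a network as a canonical two-column edge list
#'
#' Output round-trips losslessly through [read_network()].
#'
#' @param network An igraph network with named vertices.
#' @param path Output file path.
#' @export
write_network <- function(network, path) {
  writeLines(c("# protein_a\tprotein_b", sort(network_edge_keys(network))),
             path)
  invisible(path)
}

#' Read a set of detected protein complexes
#'
#' One complex per line, members separated by tabs or spaces (the layout of
#' typical complex-detector output). Complexes are assigned the identifiers
#' `"C0001"`, `"C0002"`, ... in file order; duplicate members within one line
#' are collapsed. Empty lines are skipped with a warning. Identical lines
#' yield distinct complexes with identical member sets -- complexes may
#' overlap or repeat.
#'
#' @param path Path to the complex file.
#' @return A `complex_set`: a named list of character vectors of members.
#' @export
read_complexes <- function(path) {
  lines <- readLines(path)
  comment <- grepl("^\\s*#", lines)
  blank <- !nzchar(trimws(lines)) & !comment
  if (any(blank)) {
    warning("skipped ", sum(blank), " empty line(s) in '", path, "'")
  }
  keep <- !comment & !blank
  if (!any(keep)) stop("no complexes found in '", path, "'")
  members <- lapply(strsplit(trimws(lines[keep]), "[ \t]+"), unique)
  complex_set(members)
}

#' Construct a complex set
#'
#' @param members List of character vectors (one per complex).
#' @param ids Optional complex identifiers; defaults to `"C0001"`, ...
#' @return A named list with class `complex_set`.
#' @export
complex_set <- function(members, ids = NULL) {
  members <- lapply(members, function(m) unique(as.character(m)))
  if (any(lengths(members) < 1L)) stop("every complex needs at least one member")
  if (is.null(ids)) ids <- sprintf("C%04d", seq_along(members))
  if (length(ids) != length(members)) stop("one id per complex required")
  names(members) <- ids
  structure(members, class = "complex_set")
}

#' @export
print.complex_set <- function(x, ...) {
  cat("Complex set:", length(x), "complexes,",
      length(unique(unlist(x))), "distinct proteins\n")
  sizes <- lengths(x)
  cat("  sizes: min", min(sizes), "/ median", stats::median(sizes),
      "/ max", max(sizes), "\n")
  invisible(x)
}

#' Write a complex set
#'
#' One complex per line, tab-separated members; round-trips through
#' [read_complexes()] (ids are positional and therefore preserved).
#'
#' @param complexes A `complex_set` or list of member vectors.
#' @param path Output file path.
#' @export
write_complexes <- function(complexes, path) {
  writeLines(vapply(complexes, paste, character(1), collapse = "\t"), path)
  invisible(path)
}

#' Read a two-column reference pair set
#'
#' For gold-standard positive/negative sets and reference interactomes.
#' Pairs are canonicalized and deduplicated; self-pairs are dropped with a
#' warning.
#'
#' @param path Path to a two-column delimited file (`#` comments allowed).
#' @return Sorted character vector of unique canonical pair keys.
#' @export
read_pairs <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  if (!any(keep)) return(character(0))
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  bad <- which(lengths(fields) != 2L)
  if (length(bad)) {
    stop(sprintf("malformed line %d in '%s': expected 2 columns, found %d",
                 which(keep)[bad[1L]], path, lengths(fields)[bad[1L]]))
  }
  a <- vapply(fields, `[[`, character(1), 1L)
  b <- vapply(fields, `[[`, character(1), 2L)
  self <- a == b
  if (any(self)) warning("dropped ", sum(self), " self-pair(s) in '", path, "'")
  sort(unique(pair_keys(a[!self], b[!self])))
}

#' Write a pair set as two-column TSV
#'
#' @param keys Interactions in any representation accepted by
#'   [as_pair_keys()].
#' @param path Output file path.
#' @export
write_pairs <- function(keys, path) {
  writeLines(c("# protein_a\tprotein_b", sort(as_pair_keys(keys))), path)
  invisible(path)
}

#' Read a protein annotation table
#'
#' Three tab-separated columns: protein identifier, term identifier, term
#' name (term names may contain spaces). Used by [annotation_hit_ratio()].
#'
#' @param path Path to the annotation TSV.
#' @return Data frame with columns `protein`, `term_id`, `term_name`.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                           comment.char = "#", stringsAsFactors = FALSE,
                           col.names = c("protein", "term_id", "term_name"))
  ann
}

#' Write a protein annotation table
#'
#' @param annotations Data frame with columns `protein`, `term_id`,
#'   `term_name`.
#' @param path Output file path.
#' @export
write_annotations <- function(annotations, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# protein\tterm_id\tterm_name", con)
  utils::write.table(annotations[, c("protein", "term_id", "term_name")],
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a prediction set as TSV
#'
#' One row per unique canonical pair with columns `protein_a`, `protein_b`,
#' `h` (repetition count), and `sources` (semicolon-joined
#' `complex/subnet` provenance). Rows are ordered by decreasing `h`, then by
#' pair. Round-trips losslessly through [read_predictions()].
#'
#' @param pred A `prediction_set`.
#' @param path Output file path.
#' @export
write_predictions <- function(pred, path) {
  stopifnot(inherits(pred, "prediction_set"))
  utils::write.table(as.data.frame(pred)[, c("protein_a", "protein_b",
                                             "h", "sources")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a prediction set written by [write_predictions()]
#'
#' @param path Path to the prediction TSV.
#' @return A `prediction_set`.
#' @export
read_predictions <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character",
                                         "integer", "character"))
  if (!identical(names(df), c("protein_a", "protein_b", "h", "sources"))) {
    stop("'", path, "' is not a prediction file (unexpected columns)")
  }
  prediction_set(df$protein_a, df$protein_b, df$h, df$sources)
}
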
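#' Canonical interaction keys
#'
#' A protein-protein interaction is an unordered pair of protein identifiers:
#' `(a, b)` and `(b, a)` denote the same interaction, and only one of them is
#' kept. Pairs are stored canonically, with the lexicographically smaller
#' identifier first and a single tab separating the two, so that a set of
#' interactions can be handled as a plain character vector and written
#' directly as two-column TSV rows.
#'
#' @param a,b Character vectors of protein identifiers, of equal length.
#' @return A character vector of canonical pair keys.
#' @seealso [pair_frame()] for the inverse operation.
#' @examples
#' pair_keys(c("B", "C"), c("A", "D"))
#' @export
pair_keys <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  if (length(a) != length(b)) {
    stop("'a' and 'b' must have the same length")
  }
  if (any(a == b)) {
    stop("self-pairs are not valid interactions")
  }
  paste(pmin(a, b), pmax(a, b), sep = "\t")
}

#' Split canonical pair keys into a two-column data frame
#'
#' @param keys Character vector of canonical keys as produced by
#'   [pair_keys()].
#' @return A data frame with columns `protein_a` and `protein_b`
#'   (`protein_a < protein_b` for every row).
#' @export
pair_frame <- function(keys) {
  if (!length(keys)) {
    return(data.frame(protein_a = character(0), protein_b = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(keys, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("malformed pair key: expected exactly one tab separator")
  }
  data.frame(protein_a = vapply(parts, `[[`, character(1), 1L),
             protein_b = vapply(parts, `[[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

#' Coerce interaction containers to canonical pair keys
#'
#' All evaluation functions accept interaction sets in any of the package's
#' representations: a character vector of canonical keys, a two-column data
#' frame of identifiers, or a [prediction set][aggregate_predictions]. This
#' generic funnels them into one deduplicated canonical form.
#'
#' @param x Interactions in any supported representation.
#' @param ... Passed on to methods.
#' @return Character vector of unique canonical pair keys.
#' @export
as_pair_keys <- function(x, ...) UseMethod("as_pair_keys")

#' @export
as_pair_keys.character <- function(x, ...) {
  if (length(x) && !all(grepl("\t", x, fixed = TRUE))) {
    stop("character input must contain canonical tab-separated pair keys")
  }
  unique(unname(x))
}

#' @export
as_pair_keys.data.frame <- function(x, ...) {
  if (ncol(x) < 2L) stop("need at least two identifier columns")
  if (!nrow(x)) return(character(0))
  unique(pair_keys(x[[1L]], x[[2L]]))
}

#' @export
as_pair_keys.prediction_set <- function(x, ...) {
  if (!nrow(x)) return(character(0))
  unique(pair_keys(x$protein_a, x$protein_b))
}

#' @export
as_pair_keys.default <- function(x, ...) {
  stop("cannot interpret an object of class '", class(x)[1L],
       "' as a set of interactions")
}

# canonical keys for every unordered pair of a node set (members sorted, so
# combn() output is already canonical)
all_pair_keys <- function(members) {
  members <- sort(unique(as.character(members)))
  if (length(members) < 2L) return(character(0))
  cmb <- utils::combn(members, 2L)
  paste(cmb[1L, ], cmb[2L, ], sep = "\t")
}
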
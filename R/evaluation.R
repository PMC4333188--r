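#' Gold-standard likelihood ratio
#'
#' The statistical estimator of Jansen et al. for a predicted interaction
#' set: `L = (P+/G+) / (P-/G-)`, where `P+` and `P-` are the numbers of
#' predictions falling in the gold-standard positive and negative sets and
#' `G+`, `G-` are the sizes of those sets. For the classical yeast gold
#' standard `G+ = 8250` and `G- = 2705844`, shipped here as the defaults and
#' overridable when user gold-standard files are supplied. Jansen et al.'s
#' working thresholds for an acceptable prediction set are `L` of 300 and
#' 600; larger is better.
#'
#' Degenerate cases are flagged with a warning: `P- = 0` with `P+ > 0` gives
#' `Inf` (no prediction hits the negative set), and `P+ = P- = 0` gives `NaN`
#' (the ratio is undefined).
#'
#' @param p_plus Number of predictions in the positive set, or a
#'   `likelihood_inputs` object from [count_gs_hits()] (in which case the
#'   remaining arguments are taken from it).
#' @param p_minus Number of predictions in the negative set.
#' @param g_plus,g_minus Gold-standard set sizes (positive `> 0`).
#' @return The likelihood ratio, a single number.
#' @examples
#' likelihood_ratio(8250, 2705844)  # 1: proportional hits
#' @export
likelihood_ratio <- function(p_plus, p_minus,
                             g_plus = 8250, g_minus = 2705844) {
  if (inherits(p_plus, "likelihood_inputs")) {
    inp <- p_plus
    p_minus <- inp$p_minus
    g_plus <- inp$g_plus
    g_minus <- inp$g_minus
    p_plus <- inp$p_plus
  }
  counts <- c(p_plus = p_plus, p_minus = p_minus,
              g_plus = g_plus, g_minus = g_minus)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (g_plus <= 0 || g_minus <= 0) stop("gold-standard sizes must be positive")
  if (p_minus == 0) {
    if (p_plus > 0) {
      warning("no predictions in the negative set; likelihood ratio is infinite")
      return(Inf)
    }
    warning("no predictions in either gold-standard set; ratio undefined")
    return(NaN)
  }
  (p_plus / g_plus) / (p_minus / g_minus)
}

#' Count prediction hits in the gold standard
#'
#' Intersects a prediction set with the gold-standard positive and negative
#' pair sets (all pairs compared in canonical unordered form). By default the
#' gold-standard sizes `G+`/`G-` are the sizes of the supplied sets; pass
#' explicit `g_plus`/`g_minus` to use published constants instead.
#'
#' @param pred Predictions in any representation accepted by
#'   [as_pair_keys()].
#' @param gs_positive,gs_negative Gold-standard pair sets (must be disjoint).
#' @param g_plus,g_minus Optional overrides for the gold-standard sizes.
#' @return A `likelihood_inputs` list: `p_plus`, `p_minus`, `g_plus`,
#'   `g_minus`. Feed it to [likelihood_ratio()].
#' @export
count_gs_hits <- function(pred, gs_positive, gs_negative,
                          g_plus = NULL, g_minus = NULL) {
  keys <- as_pair_keys(pred)
  pos <- as_pair_keys(gs_positive)
  neg <- as_pair_keys(gs_negative)
  if (length(intersect(pos, neg))) {
    stop("gold-standard positive and negative sets must be disjoint")
  }
  structure(list(p_plus = sum(keys %in% pos),
                 p_minus = sum(keys %in% neg),
                 g_plus = if (is.null(g_plus)) length(pos) else g_plus,
                 g_minus = if (is.null(g_minus)) length(neg) else g_minus),
            class = "likelihood_inputs")
}

#' @export
print.likelihood_inputs <- function(x, ...) {
  cat(sprintf("GS hits: P+ = %d / G+ = %d, P- = %d / G- = %d\n",
              x$p_plus, x$g_plus, x$p_minus, x$g_minus))
  invisible(x)
}

#' Hit ratio against a reference interactome
#'
#' Percentage of predictions confirmed by an independently curated
#' interaction set (a BioGRID-style database export): `100 * |pred
#' \eqn{\cap}{n} ref| / |pred|`.
#'
#' @param pred Non-empty prediction set in any representation accepted by
#'   [as_pair_keys()].
#' @param reference Reference pair set.
#' @return Percentage in `[0, 100]`.
#' @export
reference_hit_ratio <- function(pred, reference) {
  keys <- as_pair_keys(pred)
  if (!length(keys)) stop("prediction set is empty")
  ref <- as_pair_keys(reference)
  100 * sum(keys %in% ref) / length(keys)
}

#' Overlap statistics between two prediction sets
#'
#' The overlap ratio between two interaction sets is the percentage
#' `100 * |A intersect B| / |A union B|`. The union is computed by
#' inclusion-exclusion and cross-checked against the directly computed set
#' union. When both sets are empty the ratio is 0. `ratio_rounded` rounds
#' half-up to the integer percent used for reporting.
#'
#' @param set_a,set_b Interaction sets in any representation accepted by
#'   [as_pair_keys()].
#' @return One-row data frame: `size_a`, `size_b`, `intersection`, `union`,
#'   `ratio_percent` (exact), `ratio_rounded` (integer percent).
#' @export
overlap_stats <- function(set_a, set_b) {
  ka <- as_pair_keys(set_a)
  kb <- as_pair_keys(set_b)
  i <- length(intersect(ka, kb))
  u <- length(ka) + length(kb) - i
  stopifnot(u == length(union(ka, kb)))
  ratio <- if (u == 0L) 0 else 100 * i / u
  data.frame(size_a = length(ka), size_b = length(kb),
             intersection = i, union = u,
             ratio_percent = ratio,
             ratio_rounded = as.integer(floor(ratio + 0.5)))
}

#' Annotation-based complex hit ratio
#'
#' Semantic screening of predictions against a protein annotation table
#' (e.g. GO cellular-component terms): a predicted pair "hits" if its two
#' proteins share at least one annotation term whose name contains the
#' keyword (case-insensitive substring, default `"complex"`). A high ratio
#' indicates that the predictions concentrate inside annotated protein
#' complexes. Reported to two decimals by convention.
#'
#' @param pred Non-empty prediction set in any representation accepted by
#'   [as_pair_keys()].
#' @param annotations Data frame with columns `protein`, `term_id`,
#'   `term_name` (see [read_annotations()]).
#' @param keyword Substring a shared term's name must contain.
#' @return List with `hits` (count) and `ratio_percent`.
#' @export
annotation_hit_ratio <- function(pred, annotations, keyword = "complex") {
  keys <- as_pair_keys(pred)
  if (!length(keys)) stop("prediction set is empty")
  stopifnot(all(c("protein", "term_id", "term_name") %in% names(annotations)))
  ann <- annotations[grepl(keyword, annotations$term_name,
                           ignore.case = TRUE), , drop = FALSE]
  terms_by_protein <- split(as.character(ann$term_id),
                            as.character(ann$protein))
  pf <- pair_frame(keys)
  hit <- mapply(function(a, b) {
    length(intersect(terms_by_protein[[a]], terms_by_protein[[b]])) > 0L
  }, pf$protein_a, pf$protein_b, USE.NAMES = FALSE)
  list(hits = sum(hit), ratio_percent = 100 * sum(hit) / length(keys))
}
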
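# Candidate screening: the re-annotation step that selects putative
# machinery genes from mutant-screen lists by envelope/interaction
# features, plus the mutant-list bookkeeping and the qRT-PCR polar-effect
# check used when validating in-frame deletions.

#' Screen loci for envelope and interaction features
#'
#' A locus is kept iff it has a signal peptide, a lipoprotein signal, at
#' least one transmembrane segment, or a protein-protein interaction motif
#' (TPR or coiled-coil).  Reason codes record every satisfied clause.
#'
#' @param features a `feature_table`
#' @param universe locus tags to screen (must all be present in `features`)
#' @return list with `candidates` (character vector) and `reasons` (named
#'   list of reason-code vectors, one per candidate)
#' @export
screen_candidates <- function(features, universe) {
  i <- match(universe, features$locus_tag)
  if (anyNA(i))
    stop("locus missing from feature table: ",
         paste(universe[is.na(i)], collapse = ", "))
  f <- features[i, , drop = FALSE]
  reason <- lapply(seq_len(nrow(f)), function(k) {
    r <- character()
    if (isTRUE(f$signal_peptide[k]))     r <- c(r, "signal_peptide")
    if (isTRUE(f$lipoprotein_signal[k])) r <- c(r, "lipoprotein_signal")
    if (f$tm_count[k] >= 1L)             r <- c(r, "transmembrane")
    if (isTRUE(f$interaction_motif[k]))  r <- c(r, "interaction_motif")
    r
  })
  keep <- lengths(reason) > 0L
  list(candidates = universe[keep],
       reasons = setNames(reason[keep], universe[keep]))
}

#' Merge two mutant-screen gene lists
#'
#' Identifiers are normalized (trimmed, upper-cased) before comparison;
#' returns union, intersection and the inclusion-exclusion counts.
#'
#' @param list_a,list_b character vectors of gene identifiers
#' @return list with `union`, `intersection`, `n_a`, `n_b`,
#'   `n_intersection`, `n_union`
#' @export
merge_screen_lists <- function(list_a, list_b) {
  norm <- function(x) unique(toupper(trimws(x)))
  a <- norm(list_a); b <- norm(list_b)
  list(union = sort(union(a, b)), intersection = sort(intersect(a, b)),
       n_a = length(a), n_b = length(b),
       n_intersection = length(intersect(a, b)),
       n_union = length(union(a, b)))
}

#' Flag polar effects in a relative-expression table
#'
#' Scans a strain x gene table of qRT-PCR relative expression values for
#' cells outside `(low, high)` (strict inequalities); `ND` cells (the
#' deleted gene itself) are skipped.  Also returns the numeric maximum of
#' the table, the headline number when a neighbouring gene is up-regulated
#' by a deletion.
#'
#' @param expression data.frame or matrix, strains as rows and genes as
#'   columns; entries numeric or the string `"ND"`
#' @param low,high flagging bounds, `0 < low < 1 < high`
#' @return list with `flags` (data.frame `strain`, `gene`, `value`) and
#'   `max_value`
#' @export
polar_effect_screen <- function(expression, low = 0.4, high = 2.0) {
  stopifnot(low > 0, low < 1, high > 1)
  m <- as.matrix(expression)
  strains <- rownames(m) %||% as.character(seq_len(nrow(m)))
  genes <- colnames(m) %||% as.character(seq_len(ncol(m)))
  flags <- list()
  maxv <- -Inf
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    cell <- trimws(as.character(m[i, j]))
    if (toupper(cell) == "ND") next
    v <- suppressWarnings(as.numeric(sub(",", ".", cell, fixed = TRUE)))
    if (is.na(v)) stop("unreadable expression value: ", cell)
    if (v <= 0) stop("non-positive expression value at (",
                     strains[i], ", ", genes[j], "): ", v)
    maxv <- max(maxv, v)
    if (v < low || v > high)
      flags[[length(flags) + 1L]] <- data.frame(
        strain = strains[i], gene = genes[j], value = v,
        stringsAsFactors = FALSE)
  }
  list(flags = if (length(flags)) do.call(rbind, flags)
               else data.frame(strain = character(), gene = character(),
                               value = numeric()),
       max_value = maxv)
}
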
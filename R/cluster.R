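# Chromosomal cluster detection: grouping candidate hits into genomic
# regions by locus-order adjacency, and extending regions to the full
# contiguous gene set with curated pseudogene merging.

#' Group candidate loci into chromosomal clusters
#'
#' Two hits belong to the same cluster iff a chain of hits connects them in
#' which each consecutive pair is separated by at most `max_gap`
#' intervening loci (`|delta ordinal| - 1 <= max_gap`); clusters are the
#' connected components of this adjacency graph.  Singletons are clusters
#' of size 1.  Chromosomes are treated as linear.
#'
#' @param hits data.frame of loci within one genome, with columns
#'   `genome_id`, `locus_tag`, `ordinal_index`
#' @param max_gap maximum number of intervening loci (>= 0)
#' @return list of clusters; each is a list with `genome_id`,
#'   `member_loci` (data.frame sorted by index), `span` (half-open index
#'   range `c(min, max + 1)`) and `n_hits`
#' @export
detect_clusters <- function(hits, max_gap = 3L) {
  stopifnot(max_gap >= 0)
  if (nrow(hits) == 0) return(list())
  if (length(unique(hits$genome_id)) > 1L)
    stop("hits span multiple genomes: ",
         paste(unique(hits$genome_id), collapse = ", "))
  h <- hits[order(hits$ordinal_index), , drop = FALSE]
  gap_to_prev <- c(Inf, diff(h$ordinal_index) - 1L)
  comp <- cumsum(gap_to_prev > max_gap)
  lapply(split(seq_len(nrow(h)), comp), function(ix) {
    m <- h[ix, , drop = FALSE]
    list(genome_id = m$genome_id[1], member_loci = m,
         span = c(min(m$ordinal_index), max(m$ordinal_index) + 1L),
         n_hits = nrow(m))
  })
}

#' Extend a cluster to the full contiguous locus range
#'
#' Every locus between the cluster's extreme hits is pulled in; then
#' `merge_rules` fuses listed locus sets into one putative gene (curated
#' pseudogene fragments) and `discard` drops loci entirely.  Merged
#' pseudo-loci keep the joined tag (e.g. `A/B`) and the first fragment's
#' index.  Idempotent.
#'
#' @param cluster one cluster from [detect_clusters()]
#' @param genome data.frame of all loci of the genome (columns as in a
#'   `gene_table`)
#' @param merge_rules list of character vectors of locus tags to fuse
#' @param discard character vector of locus tags to drop after extension
#' @return the extended cluster; `n_genes` holds the post-merge count
#' @export
extend_cluster <- function(cluster, genome, merge_rules = list(),
                           discard = character()) {
  g <- genome[genome$genome_id == cluster$genome_id, , drop = FALSE]
  lo <- cluster$span[1]; hi <- cluster$span[2] - 1L
  m <- g[g$ordinal_index >= lo & g$ordinal_index <= hi, , drop = FALSE]
  m <- m[order(m$ordinal_index), , drop = FALSE]
  for (rule in merge_rules) {
    if (!any(rule %in% m$locus_tag)) next
    if (!all(rule %in% m$locus_tag))
      stop("merge rule references loci outside the cluster span: ",
           paste(setdiff(rule, m$locus_tag), collapse = ", "))
    sel <- match(rule, m$locus_tag)
    keep <- min(sel)
    m$locus_tag[keep] <- paste(sort(rule), collapse = "/")
    m <- m[-setdiff(sel, keep), , drop = FALSE]
  }
  m <- m[!(m$locus_tag %in% discard), , drop = FALSE]
  hit_tags <- cluster$member_loci$locus_tag
  list(genome_id = cluster$genome_id, member_loci = m,
       span = c(min(m$ordinal_index), max(m$ordinal_index) + 1L),
       n_hits = cluster$n_hits,
       n_genes = nrow(m),
       is_hit = m$locus_tag %in% hit_tags |
         vapply(strsplit(m$locus_tag, "/", fixed = TRUE),
                function(p) any(p %in% hit_tags), logical(1)))
}

#' Cluster table across genomes
#'
#' Convenience wrapper: detects clusters of the given hit loci in every
#' genome and returns a tidy table.
#'
#' @param gene_tab a `gene_table`
#' @param hit_tags locus tags treated as hits
#' @param max_gap see [detect_clusters()]
#' @return data.frame with `cluster_id`, `genome_id`, `locus_tag`,
#'   `ordinal_index`, `n_hits`
#' @export
cluster_table <- function(gene_tab, hit_tags, max_gap = 3L) {
  out <- list()
  for (g in unique(gene_tab$genome_id)) {
    hits <- gene_tab[gene_tab$genome_id == g &
                     gene_tab$locus_tag %in% hit_tags, , drop = FALSE]
    if (!nrow(hits)) next
    cl <- detect_clusters(hits, max_gap)
    for (k in seq_along(cl)) {
      m <- cl[[k]]$member_loci
      out[[length(out) + 1L]] <- data.frame(
        cluster_id = paste0(g, ".cl", k), genome_id = g,
        locus_tag = m$locus_tag, ordinal_index = m$ordinal_index,
        n_hits = cl[[k]]$n_hits, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(cluster_id = character(),
    genome_id = character(), locus_tag = character(),
    ordinal_index = integer(), n_hits = integer()))
  do.call(rbind, out)
}
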
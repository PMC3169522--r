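# Supermatrix construction: grouping families that share an evolutionary
# history (tree congruence + physical linkage) and concatenating their
# alignments with paralogous copies assigned to rows by chromosomal
# cluster co-membership.

#' Group families by shared evolutionary history
#'
#' Two families are grouped iff they co-occur in a detected chromosomal
#' cluster in at least one genome AND their gene trees, restricted to
#' genomes carrying exactly one copy of each (at least `min_shared_taxa`
#' of them), have Robinson-Foulds distance <= `rf_max`.  Groups are the
#' transitive closures of this relation.
#'
#' @param gene_trees named list of `phylo` per family, tips being locus
#'   tags; a family with `NULL` tree is an error
#' @param membership data.frame `locus_tag`, `family_id`, `genome_id`
#' @param colocated data.frame of family pairs (`family_a`, `family_b`)
#'   co-occurring in a cluster in >= 1 genome
#' @param rf_max congruence tolerance
#' @param min_shared_taxa minimum single-copy genomes shared by both trees
#' @return list of character vectors (the groups)
#' @export
congruence_groups <- function(gene_trees, membership, colocated,
                              rf_max = 2L, min_shared_taxa = 4L) {
  fams <- sort(unique(membership$family_id))
  nul <- fams[vapply(fams, function(f) is.null(gene_trees[[f]]), TRUE)]
  if (length(nul))
    stop("family without a gene tree: ", paste(nul, collapse = ", "))
  single_copy_tree <- function(f) {
    mem <- membership[membership$family_id == f, , drop = FALSE]
    tab <- table(mem$genome_id)
    keep_g <- names(tab)[tab == 1]
    tips <- mem$locus_tag[mem$genome_id %in% keep_g]
    tr <- gene_trees[[f]]
    tips <- intersect(tr$tip.label, tips)
    tr <- ape::keep.tip(tr, tips)
    tr$tip.label <- mem$genome_id[match(tr$tip.label, mem$locus_tag)]
    tr
  }
  sc <- lapply(setNames(fams, fams), single_copy_tree)
  congruent <- function(a, b) {
    shared <- intersect(sc[[a]]$tip.label, sc[[b]]$tip.label)
    if (length(shared) < min_shared_taxa) return(FALSE)
    ta <- ape::keep.tip(sc[[a]], shared)
    tb <- ape::keep.tip(sc[[b]], shared)
    robinson_foulds(ta, tb) <= rf_max
  }
  parent <- setNames(fams, fams)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  if (nrow(colocated)) for (k in seq_len(nrow(colocated))) {
    a <- colocated$family_a[k]; b <- colocated$family_b[k]
    if (!a %in% fams || !b %in% fams || a == b) next
    if (congruent(a, b)) parent[find(a)] <- find(b)
  }
  roots <- vapply(fams, find, character(1))
  unname(split(fams, roots))
}

#' Family pairs co-located in detected clusters
#'
#' @param membership data.frame `locus_tag`, `family_id`, `genome_id`,
#'   `ordinal_index`
#' @param max_gap cluster adjacency parameter
#' @return data.frame `family_a`, `family_b` (each unordered pair once)
#' @export
colocated_pairs <- function(membership, max_gap = 3L) {
  pairs <- character()
  for (g in unique(membership$genome_id)) {
    m <- membership[membership$genome_id == g, , drop = FALSE]
    if (nrow(m) < 2) next
    cl <- detect_clusters(m, max_gap)
    for (c1 in cl) {
      fams <- sort(unique(m$family_id[match(c1$member_loci$locus_tag,
                                            m$locus_tag)]))
      if (length(fams) >= 2) {
        cmb <- utils::combn(fams, 2)
        pairs <- c(pairs, paste(cmb[1, ], cmb[2, ], sep = "\r"))
      }
    }
  }
  pairs <- unique(pairs)
  if (!length(pairs))
    return(data.frame(family_a = character(), family_b = character()))
  sp <- strsplit(pairs, "\r", fixed = TRUE)
  data.frame(family_a = vapply(sp, `[`, "", 1),
             family_b = vapply(sp, `[`, "", 2), stringsAsFactors = FALSE)
}

#' Resolve paralogous copies into linked tuples for one genome
#'
#' When a genome holds several copies of a group's families, the copies
#' residing in one detected chromosomal cluster form one row tuple
#' (ordered by family); clusters lacking exactly one copy of every group
#' family yield no tuple and their loci are reported unassigned.  A copy
#' can therefore never join two tuples.
#'
#' @param members data.frame for one genome: `locus_tag`, `family_id`,
#'   `ordinal_index`, `genome_id`
#' @param group character vector of family ids in the group
#' @param max_gap cluster adjacency parameter
#' @return list with `tuples` (list of named locus-tag vectors, names =
#'   family) and `unassigned` (data.frame)
#' @export
link_paralogues <- function(members, group, max_gap = 3L) {
  m <- members[members$family_id %in% group, , drop = FALSE]
  if (!nrow(m)) return(list(tuples = list(), unassigned = m))
  cl <- detect_clusters(m, max_gap)
  tuples <- list()
  unassigned <- list()
  for (c1 in cl) {
    loci <- c1$member_loci$locus_tag
    fam <- m$family_id[match(loci, m$locus_tag)]
    if (length(loci) == length(group) && setequal(fam, group) &&
        !anyDuplicated(fam)) {
      tuples[[length(tuples) + 1L]] <-
        setNames(loci[match(sort(group), fam)], sort(group))
    } else {
      unassigned[[length(unassigned) + 1L]] <-
        m[match(loci, m$locus_tag), , drop = FALSE]
    }
  }
  assigned <- unlist(lapply(tuples, unname))
  if (anyDuplicated(assigned)) stop("internal error: copy in two tuples")
  list(tuples = tuples,
       unassigned = if (length(unassigned)) do.call(rbind, unassigned)
                    else m[0, , drop = FALSE])
}

#' Concatenate family alignments over linked tuples
#'
#' One row per tuple; each row is the concatenation of the tuple members'
#' aligned sequences in sorted family order.  Genomes lacking a complete
#' linked tuple are simply absent (no gap padding).
#'
#' @param tuples named list: row id -> named locus-tag vector (names =
#'   family ids); every family must appear in every tuple
#' @param alignments named list of [alignment_block()]s per family, rows
#'   keyed by locus tag
#' @return list of class `supermatrix`: `alignment` (an
#'   `alignment_block`), `partitions` (data.frame `family_id`, `start`,
#'   `end`, half-open 0-based), `n_sequences`, `n_positions`
#' @export
concatenate_alignments <- function(tuples, alignments) {
  if (!length(tuples)) stop("no tuples to concatenate")
  fams <- sort(unique(names(tuples[[1]])))
  widths <- integer(length(fams))
  for (k in seq_along(fams)) {
    ab <- alignments[[fams[k]]]
    if (is.null(ab)) stop("no alignment for family ", fams[k])
    widths[k] <- ncol(ab)
  }
  starts <- cumsum(c(0L, widths[-length(widths)]))
  partitions <- data.frame(family_id = fams, start = starts,
                           end = starts + widths, stringsAsFactors = FALSE)
  rows <- matrix("", length(tuples), sum(widths))
  rownames(rows) <- names(tuples)
  for (i in seq_along(tuples)) {
    tp <- tuples[[i]]
    if (!setequal(names(tp), fams))
      stop("tuple ", names(tuples)[i], " does not cover the family set")
    for (k in seq_along(fams)) {
      ab <- alignments[[fams[k]]]
      r <- match(tp[[fams[k]]], rownames(ab))
      if (is.na(r)) stop("tuple member ", tp[[fams[k]]],
                         " missing from alignment of ", fams[k])
      rows[i, (partitions$start[k] + 1L):partitions$end[k]] <-
        unclass(ab)[r, ]
    }
  }
  structure(list(alignment = alignment_block(rows),
                 partitions = partitions,
                 n_sequences = nrow(rows), n_positions = ncol(rows)),
            class = "supermatrix")
}

#' Extract one family's columns back out of a supermatrix
#'
#' Partition bookkeeping is lossless: this recovers the family alignment
#' restricted to tuple members exactly.
#'
#' @param sm a `supermatrix`
#' @param family_id family to extract
#' @return an `alignment_block` (rows keyed by tuple id)
#' @export
deconcatenate <- function(sm, family_id) {
  p <- sm$partitions[sm$partitions$family_id == family_id, , drop = FALSE]
  if (!nrow(p)) stop("family not in supermatrix: ", family_id)
  alignment_block(unclass(sm$alignment)[, (p$start + 1L):p$end,
                                        drop = FALSE])
}

#' Write a supermatrix as relaxed PHYLIP plus a partition table
#'
#' @param sm a `supermatrix`
#' @param path_phy,path_parts output paths
#' @return `path_phy`, invisibly
#' @export
write_supermatrix <- function(sm, path_phy, path_parts) {
  con <- file(path_phy, "w")
  on.exit(close(con))
  writeLines(paste(sm$n_sequences, sm$n_positions), con)
  sq <- ab_strings(sm$alignment)
  writeLines(paste(names(sq), sq), con)
  write.table(sm$partitions, path_parts, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path_phy)
}
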
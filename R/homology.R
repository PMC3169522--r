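# Iterative homologue detection, phyletic profiles and taxonomic-breadth
# classification (Group A: clade-restricted; Group B: broadly
# distributed).

#' Find homologues of seed proteins by iterative similarity expansion
#'
#' Starting from the seed copies, every proteome sequence whose normalized
#' local-alignment score against a family representative reaches
#' `threshold` joins the family; newly joined divergent members become
#' representatives in later rounds, mimicking iterative PSI-BLAST seed
#' expansion.  With `max_reps = Inf` every member is a representative and
#' the procedure is exact symmetric single-linkage; the default caps the
#' representative set (seeds first, then the most divergent members) to
#' keep the search near-linear.  A shared-k-mer word prefilter
#' (`kmer_prefilter > 0`) skips alignment of pairs with no word-level
#' signal.  Deterministic: candidates and representatives are processed in
#' sorted order.
#'
#' @param seeds locus tags of the seed copies (must be in `proteomes`)
#' @param proteomes named character vector: locus tag -> residue sequence
#' @param scheme a [scoring_scheme()]
#' @param threshold normalized-score threshold in (0, 1]
#' @param max_iters maximum expansion rounds
#' @param max_reps maximum representatives aligned per family
#' @param kmer_prefilter word size for the prefilter (0 disables it)
#' @param family_id identifier for the returned family
#' @return list of class `homology_family`: `family_id`, `seeds`,
#'   `members` (data.frame `locus_tag`, `norm_score`: best normalized
#'   score against a representative; seeds score 1), `n_iters`
#' @export
find_homologues <- function(seeds, proteomes, scheme = scoring_scheme(),
                            threshold = 0.3, max_iters = 5L,
                            max_reps = 4L, kmer_prefilter = 4L,
                            family_id = seeds[1]) {
  if (!length(seeds)) stop("empty seed set")
  stopifnot(threshold > 0, threshold <= 1, max_iters >= 1)
  seeds <- sort(unique(seeds))
  if (!all(seeds %in% names(proteomes)))
    stop("seed not in proteomes: ",
         paste(setdiff(seeds, names(proteomes)), collapse = ", "))
  ids <- sort(names(proteomes))
  codes <- lapply(proteomes[ids], encode_residues, scheme = scheme)
  selfs <- vapply(codes, self_score, numeric(1), scheme = scheme)
  member <- setNames(ids %in% seeds, ids)
  best <- setNames(ifelse(member, 1, 0), ids)
  scored_reps <- character()
  iters <- 0L
  repeat {
    iters <- iters + 1L
    mem_ids <- ids[member]
    # representatives: seeds first, then members by ascending best score
    others <- setdiff(mem_ids, seeds)
    others <- others[order(best[others], others)]
    reps <- c(seeds, others)
    if (is.finite(max_reps)) reps <- head(reps, max_reps)
    new_reps <- setdiff(reps, scored_reps)
    if (!length(new_reps) || iters > max_iters) break
    for (r in new_reps) {
      cand <- ids[!member & ids != r]
      if (length(cand)) {
        qc <- codes[cand]
        if (kmer_prefilter > 0) {
          hits <- kmer_hits(qc, codes[[r]], kmer_prefilter)
          nq <- lengths(qc) - kmer_prefilter + 1L
          ns <- length(codes[[r]]) - kmer_prefilter + 1L
          pass <- hits >= kmer_threshold(pmax(nq, 0L), max(ns, 0L),
                                         kmer_prefilter)
          cand <- cand[pass]; qc <- qc[pass]
        }
        if (length(cand)) {
          raw <- local_align_raw_many(qc, codes[[r]], scheme)
          norm <- raw / pmin(selfs[cand], selfs[[r]])
          add <- norm >= threshold
          member[cand[add]] <- TRUE
          best[cand] <- pmax(best[cand], norm)
        }
      }
      scored_reps <- c(scored_reps, r)
    }
  }
  members <- data.frame(locus_tag = ids[member],
                        norm_score = unname(best[ids[member]]),
                        stringsAsFactors = FALSE)
  structure(list(family_id = family_id, seeds = seeds, members = members,
                 n_iters = iters),
            class = "homology_family")
}

#' Build a phyletic profile from homology families
#'
#' @param families list of `homology_family` objects
#' @param gene_tab a `gene_table` covering every member locus
#' @return integer matrix (family x genome) of copy counts, with
#'   `attr(, "clade_paths")` carrying the genomes' clade paths
#' @export
build_profile <- function(families, gene_tab) {
  genomes <- sort(unique(gene_tab$genome_id))
  loc2gen <- setNames(gene_tab$genome_id, gene_tab$locus_tag)
  fids <- vapply(families, `[[`, "", "family_id")
  if (anyDuplicated(fids)) stop("duplicate family ids")
  prof <- matrix(0L, length(families), length(genomes),
                 dimnames = list(fids, genomes))
  for (fam in families) {
    g <- loc2gen[fam$members$locus_tag]
    if (anyNA(g))
      stop("family ", fam$family_id, " member not in gene table: ",
           fam$members$locus_tag[which(is.na(g))[1]])
    tab <- table(g)
    prof[fam$family_id, names(tab)] <- as.integer(tab)
  }
  cp <- vapply(genomes, function(g)
    gene_tab$clade_path[match(g, gene_tab$genome_id)], character(1))
  attr(prof, "clade_paths") <- cp
  prof
}

#' Classify a family's taxonomic distribution
#'
#' `GroupA` iff every genome carrying the family lies inside a focal clade
#' (clade membership is by any element of the genome's clade path matching
#' a focal label); `GroupB` iff at least one carrier lies outside all
#' focal clades; `absent` iff no genome carries it.
#'
#' @param counts named integer vector: genome -> copy count
#' @param clade_paths named character vector: genome -> `/`-joined path
#' @param focal_clades non-empty character vector of clade labels
#' @return `"GroupA"`, `"GroupB"` or `"absent"`
#' @export
classify_distribution <- function(counts, clade_paths, focal_clades) {
  if (!length(focal_clades)) stop("focal_clades must be non-empty")
  pos <- names(counts)[counts >= 1]
  if (!length(pos)) return("absent")
  in_focal <- vapply(pos, function(g) {
    path <- strsplit(clade_paths[[g]], "/", fixed = TRUE)[[1]]
    any(path %in% focal_clades)
  }, logical(1))
  if (all(in_focal)) "GroupA" else "GroupB"
}

#' Classify every row of a phyletic profile
#'
#' @param profile matrix from [build_profile()]
#' @param focal_clades see [classify_distribution()]
#' @return named character vector of group labels
#' @export
classify_profile <- function(profile, focal_clades) {
  cp <- attr(profile, "clade_paths")
  vapply(rownames(profile), function(f)
    classify_distribution(profile[f, ], cp, focal_clades), character(1))
}
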
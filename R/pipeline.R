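# End-to-end orchestration: screen -> cluster -> homology/profile ->
# classify -> trees -> supermatrix -> scenario, with recovery scoring
# against the simulator's truth log in synthetic mode.

# top-level clade of each genome: element `level` of its clade path
# (1 = domain root); paths shorter than `level` use their last element
genome_clades <- function(gene_tab, level = 2L) {
  g <- unique(gene_tab$genome_id)
  setNames(vapply(g, function(x) {
    p <- strsplit(gene_tab$clade_path[match(x, gene_tab$genome_id)],
                  "/", fixed = TRUE)[[1]]
    p[min(level, length(p))]
  }, character(1)), g)
}

#' Run the full comparative-genomics pipeline
#'
#' Executes every inference stage on one dataset.  In synthetic mode the
#' input is a [simulate_dataset()] result and recovery metrics against the
#' truth log are attached; in real mode supply `gene_tab`, `features`,
#' `proteome` (locus tag -> sequence), `species_tree` and `focal_genome`.
#'
#' @param x a `glide_sim` (synthetic mode) or a list of real-mode inputs
#' @param config a [default_config()]; in synthetic mode `focal_clades`
#'   and the outgroup default to the simulated focal/most-distant clades
#' @param scheme a [scoring_scheme()]
#' @return a list of class `glide_run`: stage artifacts plus `report`
#' @export
run_pipeline <- function(x, config = default_config(),
                         scheme = scoring_scheme()) {
  synthetic <- inherits(x, "glide_sim")
  if (synthetic) {
    gene_tab <- x$genomes; features <- x$features
    proteome <- x$proteome; species_tree <- x$tree
    focal_genome <- x$focal_genome
    if (!length(config$focal_clades)) config$focal_clades <- x$focal_clade
  } else {
    need <- c("gene_tab", "features", "proteome", "species_tree",
              "focal_genome")
    miss <- setdiff(need, names(x))
    if (length(miss)) stop("real mode requires inputs: ",
                           paste(miss, collapse = ", "))
    gene_tab <- x$gene_tab; features <- x$features
    proteome <- x$proteome; species_tree <- x$species_tree
    focal_genome <- x$focal_genome
    if (!length(config$focal_clades)) stop("config$focal_clades is empty")
  }
  species_tree <- label_nodes(species_tree)
  clades <- genome_clades(gene_tab)
  seed <- config$random_seed

  # -- stage 1: feature screen --------------------------------------------
  # universe: the union of the two mutant-screen gene lists when supplied
  # (the re-annotation screen of the motility-mutant hits), otherwise the
  # whole focal genome
  focal_loci <- gene_tab[gene_tab$genome_id == focal_genome, , drop = FALSE]
  lists <- x$screen_lists
  if (!is.null(lists)) {
    merged <- merge_screen_lists(lists$list_a, lists$list_b)
    universe <- focal_loci$locus_tag[toupper(focal_loci$locus_tag) %in%
                                     merged$union]
  } else {
    merged <- NULL
    universe <- focal_loci$locus_tag
  }
  scr <- screen_candidates(features, universe)
  log_msg("screen: ", length(scr$candidates), "/", length(universe),
          " candidate loci")

  # -- stage 2: chromosomal clustering of the candidates --------------------
  hits <- focal_loci[focal_loci$locus_tag %in% scr$candidates, , drop = FALSE]
  cl <- detect_clusters(hits, config$max_gap)
  multi <- Filter(function(c1) c1$n_hits >= 2L, cl)
  ext <- lapply(multi, extend_cluster, genome = focal_loci,
                merge_rules = config$merge_rules, discard = config$discard)
  seeds <- sort(unique(unlist(lapply(ext, function(e)
    e$member_loci$locus_tag))))
  log_msg("cluster: ", length(cl), " regions, ", length(multi),
          " with >= 2 hits; ", length(seeds), " seed loci")

  # -- stage 3: homologue families and phyletic profile ---------------------
  families <- list()
  assigned <- character()
  for (s in seeds) {
    if (s %in% assigned) next
    fam <- find_homologues(s, proteome, scheme,
                           threshold = config$sim_score_threshold,
                           max_iters = config$max_iters,
                           max_reps = config$max_reps,
                           kmer_prefilter = config$kmer_prefilter,
                           family_id = s)
    # keep only full-length members: fragments and chance short-sequence
    # hits cannot enter the gap-free alignments
    lens <- nchar(proteome[fam$members$locus_tag])
    modal <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
    fam$members <- fam$members[lens == modal, , drop = FALSE]
    if (nrow(fam$members) < config$min_family_size) next
    dupfam <- Filter(function(f0)
      setequal(f0$members$locus_tag, fam$members$locus_tag), families)
    if (length(dupfam)) {
      assigned <- c(assigned, s)
      next
    }
    families[[fam$family_id]] <- fam
    assigned <- c(assigned, fam$members$locus_tag)
  }
  if (!length(families)) stop("homology: no families recovered")
  profile <- build_profile(families, gene_tab)
  groups_label <- classify_profile(profile, config$focal_clades)
  membership <- do.call(rbind, lapply(families, function(f)
    data.frame(locus_tag = f$members$locus_tag, family_id = f$family_id,
               stringsAsFactors = FALSE)))
  membership$genome_id <- gene_tab$genome_id[match(membership$locus_tag,
                                                   gene_tab$locus_tag)]
  membership$ordinal_index <- gene_tab$ordinal_index[match(
    membership$locus_tag, gene_tab$locus_tag)]
  rownames(membership) <- NULL
  log_msg("homology: ", length(families), " families; GroupA=",
          sum(groups_label == "GroupA"), " GroupB=",
          sum(groups_label == "GroupB"))

  # -- stage 4: per-family alignments, trees, displacement ------------------
  outgroup <- config$outgroup_clade %||% {
    # most distant top-level clade from the focal genome's clade
    tabclades <- clades[names(clades) != focal_genome]
    names(sort(table(tabclades)))[1]
    # (any non-focal clade works for midpoint fallback; prefer smallest)
  }
  alignments <- list(); trees <- list(); displacements <- list()
  for (f in names(families)) {
    mem <- membership[membership$family_id == f, , drop = FALSE]
    if (nrow(mem) < 3) { trees[f] <- list(NULL); next }
    ab <- as_alignment_block(setNames(proteome[mem$locus_tag],
                                      mem$locus_tag))
    ab <- mask_columns(ab, config$mask_max_missing)
    alignments[[f]] <- ab
    tr <- bootstrap_support(ab, model = config$distance_model,
                            alpha = config$gamma_alpha,
                            n_reps = config$n_bootstrap,
                            seed = substream_seed(seed, paste0("bs_", f)))
    leaf_clades <- setNames(clades[mem$genome_id], mem$locus_tag)
    rooted <- root_gene_tree(tr, leaf_clades, outgroup)
    trees[[f]] <- rooted
    d <- displacement_test(rooted, leaf_clades, config$support_min)
    d$taxon <- mem$genome_id[match(d$leaf, mem$locus_tag)]
    displacements[[f]] <- d
  }

  # -- stage 5: supermatrices by congruence + linkage -----------------------
  with_tree <- names(Filter(Negate(is.null), trees))
  supermatrices <- list()
  if (length(with_tree) >= 2) {
    mem_t <- membership[membership$family_id %in% with_tree, , drop = FALSE]
    coloc <- colocated_pairs(mem_t, config$max_gap)
    grp <- congruence_groups(trees[with_tree], mem_t, coloc,
                             rf_max = config$rf_congruence_max,
                             min_shared_taxa = config$min_shared_taxa)
    for (g in grp) {
      if (length(g) < 2) next
      tuples <- list()
      for (gm in unique(mem_t$genome_id)) {
        lp <- link_paralogues(
          mem_t[mem_t$genome_id == gm, , drop = FALSE], g, config$max_gap)
        for (k in seq_along(lp$tuples))
          tuples[[paste0(gm, ".", k)]] <- lp$tuples[[k]]
      }
      if (length(tuples) < 3) next
      sm <- concatenate_alignments(tuples, alignments)
      sm$tree <- bootstrap_support(
        sm$alignment, model = config$distance_model,
        alpha = config$gamma_alpha, n_reps = config$n_bootstrap,
        seed = substream_seed(seed, paste0("bs_sm_", g[1])))
      sm$families <- g
      supermatrices[[paste(g, collapse = "+")]] <- sm
    }
  }
  log_msg("supermatrix: ", length(supermatrices), " group matrices")

  # -- stage 6: evolutionary scenarios --------------------------------------
  scenarios <- assemble_scenario(profile, membership, trees, displacements,
                                 species_tree, config$focal_clades)
  events <- scenario_events(scenarios)

  report <- list(
    seed = seed,
    focal_genome = focal_genome,
    n_list_a = if (!is.null(merged)) merged$n_a else NA_integer_,
    n_list_b = if (!is.null(merged)) merged$n_b else NA_integer_,
    n_list_overlap = if (!is.null(merged)) merged$n_intersection
                     else NA_integer_,
    n_screen_input = length(universe),
    n_candidates = length(scr$candidates),
    n_clusters = length(cl),
    n_clusters_multi = length(multi),
    n_clustered_candidates = sum(vapply(multi, `[[`, 1L, "n_hits")),
    cluster_gene_counts = vapply(ext, `[[`, 1L, "n_genes"),
    n_families = length(families),
    n_groupA = sum(groups_label == "GroupA"),
    n_groupB = sum(groups_label == "GroupB"),
    supermatrix_shapes = lapply(supermatrices, function(s)
      c(n_sequences = s$n_sequences, n_positions = s$n_positions)),
    n_events = table(events$type))

  res <- list(config = config, screen = scr, clusters = cl,
              clusters_ext = ext, families = families, profile = profile,
              groups = groups_label, membership = membership,
              alignments = alignments, trees = trees,
              displacements = displacements,
              supermatrices = supermatrices, scenarios = scenarios,
              events = events, report = report)
  if (synthetic) {
    res$recovery <- evaluate_recovery(res, x)
    res$report$recovery <- res$recovery$summary
  }
  class(res) <- c("glide_run", "list")
  res
}

#' Score a pipeline run against the simulator truth
#'
#' Inferred families are matched to truth families by maximal Jaccard
#' overlap of their member locus sets; family-membership precision/recall
#' are micro-averaged over member loci, and event-level metrics delegate
#' to [recovery_metrics()].
#'
#' @param run a `glide_run`
#' @param sim the `glide_sim` it was computed on
#' @return list with `family_map`, `membership_precision`,
#'   `membership_recall`, `events` (per-type metrics) and `summary`
#' @export
evaluate_recovery <- function(run, sim) {
  truth_fam <- split(sim$locus_map$locus_tag, sim$locus_map$family_id)
  fam_map <- character()
  for (f in names(run$families)) {
    mem <- run$families[[f]]$members$locus_tag
    jac <- vapply(truth_fam, function(tl)
      length(intersect(mem, tl)) / length(union(mem, tl)), numeric(1))
    fam_map[f] <- if (max(jac) > 0) names(truth_fam)[which.max(jac)]
                  else NA_character_
  }
  inf_pairs <- 0L; correct <- 0L
  truth_of <- setNames(sim$locus_map$family_id, sim$locus_map$locus_tag)
  for (f in names(run$families)) {
    mem <- run$families[[f]]$members$locus_tag
    inf_pairs <- inf_pairs + length(mem)
    correct <- correct +
      sum(!is.na(truth_of[mem]) & truth_of[mem] == fam_map[f])
  }
  total_true <- nrow(sim$locus_map)
  prec <- correct / inf_pairs
  rec <- correct / total_true
  ev <- recovery_metrics(run$events, sim$events, family_map = fam_map,
                         species_tree = sim$tree)
  list(family_map = fam_map,
       membership_precision = prec, membership_recall = rec,
       events = ev,
       summary = c(membership_precision = prec, membership_recall = rec,
                   setNames(ev$precision, paste0(ev$type, "_precision")),
                   setNames(ev$recall, paste0(ev$type, "_recall"))))
}

#' One-line-per-number run report
#'
#' @param run a `glide_run`
#' @param path optional file to write the key-value report to
#' @return named character vector of the report lines, invisibly
#' @export
write_report <- function(run, path = NULL) {
  r <- run$report
  flat <- c(
    seed = r$seed, focal_genome = r$focal_genome,
    n_screen_input = r$n_screen_input, n_candidates = r$n_candidates,
    n_clusters = r$n_clusters, n_clusters_multi = r$n_clusters_multi,
    n_clustered_candidates = r$n_clustered_candidates,
    cluster_gene_counts = paste(r$cluster_gene_counts, collapse = ","),
    n_families = r$n_families, n_groupA = r$n_groupA,
    n_groupB = r$n_groupB,
    supermatrix_shapes = paste(vapply(r$supermatrix_shapes, paste,
                                      "", collapse = "x"), collapse = ";"),
    n_events = paste(names(r$n_events), as.integer(r$n_events),
                     sep = "=", collapse = ","))
  if (!is.null(r$recovery))
    flat <- c(flat, setNames(format(r$recovery, digits = 4),
                             paste0("recovery_", names(r$recovery))))
  lines <- paste(names(flat), unname(flat), sep = "\t")
  if (!is.null(path)) writeLines(lines, path)
  invisible(flat)
}
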
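# End-to-end synthetic dataset: a radiation-shaped species panel carrying
# a linked "core machinery" module with broad, transfer-punctuated
# distribution (the Agl/Glt core-complex analogue), clade-restricted
# accessory families gained on nested branches of the focal clade (the
# Group A analogue), and a whole-module duplication on the focal subclade
# stem (the WGD / M2-nfs analogue), plus background genes.

#' Default simulation conditions
#'
#' The study conditions for all recovery experiments: 20 taxa in 5
#' top-level clades (the largest is the focal, gliding-clade stand-in); a
#' 6-family core module with a shared operon-like history originating at
#' the root, transferred across clades and duplicated wholesale on the
#' focal subclade stem; 3 accessory families gained on three nested focal
#' branches; proteins of 2000 residues evolving at 0.3 substitutions per
#' site per unit depth; 40 background genes per genome.  Rates were chosen
#' once for signal strength (recent cross-clade transfers, low loss) and
#' are discussed in the methods vignette.
#'
#' @param ... named overrides
#' @return a list of class `sim_config`
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_taxa = 20L,
    n_clades = 5L,
    clade_sizes = c(6L, 4L, 4L, 3L, 3L),
    clade_cut = NULL,   # default: midway between the two depth windows
    backbone_window = c(0, 0.06),
    clade_window = c(0.22, 0.34),
    n_core = 6L,
    n_acc = 3L,
    core_rates = list(dup_rate = 0.03, loss_rate = 0.05,
                      transfer_rate = 0.05),
    core_shared_history = FALSE,
    acc_rates = list(dup_rate = 0.03, loss_rate = 0.03,
                     transfer_rate = 0),
    transfer_recipients = "cross_clade",
    wgd = TRUE,
    subst_rate = 0.3,
    seq_length = 2000L,
    p_linkage = 0.9,
    n_background = 60L,
    filler_len = 60L,
    flip_noise = 0.05,
    screen_hit_rates = list(machinery_a = 0.7, machinery_b = 0.4,
                            filler_a = 0.12, filler_b = 0.08),
    max_attempts = 100L,
    seed = 1L
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown sim_config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  class(cfg) <- c("sim_config", "list")
  cfg
}

# nested focal branches: the focal-clade stem, the stem of the larger
# child of the focal MRCA, and the stem of that node's larger child
resolve_focal_branches <- function(tree, clades, focal_label) {
  focal_tips <- names(clades)[clades == focal_label]
  m1 <- mrca_node(tree, focal_tips)
  larger_child <- function(node) {
    ch <- tree$edge[tree$edge[, 1] == node, 2]
    sizes <- vapply(ch, function(x) length(tips_below(tree, x)), 1L)
    ch[order(-sizes, ch)][1]
  }
  m2 <- larger_child(m1)
  m3 <- larger_child(m2)
  nm <- node_names(tree)
  list(focal = nm[m1], focal_sub = nm[m2], focal_sub2 = nm[m3],
       focal_tips = focal_tips,
       sub_tips = tips_below(tree, m2),
       sub2_tips = tips_below(tree, m3))
}

#' Simulate a complete pipeline input dataset with ground truth
#'
#' Runs the species-tree, gene-content, sequence, genome-assembly and
#' feature stages and bundles every pipeline input together with the true
#' event log.  The content stage is conditioned on the focal genome (the
#' study organism) carrying at least one copy of every machinery family --
#' the organism is chosen *because* it displays the machinery -- by
#' redrawing histories up to `max_attempts` times.
#'
#' @param config a [sim_config()]
#' @return a list of class `glide_sim`; see Details
#' @details Components: `tree` (species tree), `clades` (tip -> top-level
#'   clade), `genomes` (`gene_table` with truth columns), `features`
#'   (`feature_table`), `proteome` (locus tag -> sequence), `alignments`
#'   (per family, rows `genome|copy`), `gene_trees` (true gene trees),
#'   `events` (true event log), `counts` (true copy-count matrix),
#'   `locus_map` (locus tag <-> family copy), `origins` (resolved origin
#'   branch per family), `focal_genome`, `focal_clade`, `wgd_branch`,
#'   `modules`, `t_origin`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  seed <- config$seed
  tree <- simulate_clade_tree(config$n_taxa, config$n_clades, seed = seed,
                              backbone_window = config$backbone_window,
                              clade_window = config$clade_window,
                              clade_sizes = config$clade_sizes)
  cut <- config$clade_cut %||%
    mean(c(config$backbone_window[2], config$clade_window[1]))
  clades <- top_clades(tree, cut)
  focal_clade <- unname(clades[tree$tip.label[1]])
  fb <- resolve_focal_branches(tree, clades, focal_clade)
  focal_genome <- sort(fb$sub2_tips)[1]
  clade_paths <- setNames(paste0("Bacteria/", clades), names(clades))

  core_fams <- sprintf("F%02d", seq_len(config$n_core))
  acc_fams <- if (config$n_acc > 0) paste0("A", seq_len(config$n_acc))
              else character()
  nm <- node_names(tree)
  root_branch <- nm[ape::Ntip(tree) + 1L]
  acc_origin_pool <- c(fb$focal, fb$focal_sub, fb$focal_sub2)
  params <- list()
  for (f in core_fams)
    params[[f]] <- c(list(origin_branch = root_branch,
                          forced_dup_branches =
                            if (isTRUE(config$wgd)) fb$focal_sub
                            else character()),
                     if (isTRUE(config$core_shared_history))
                       list(history_group = "core"),
                     config$core_rates)
  for (i in seq_along(acc_fams))
    params[[acc_fams[i]]] <- c(list(
      origin_branch = acc_origin_pool[(i - 1L) %% 3L + 1L]),
      config$acc_rates)
  fams <- names(params)

  content <- NULL
  for (attempt in seq_len(config$max_attempts)) {
    cand <- evolve_gene_content(
      tree, params, seed = substream_seed(seed, paste0("content", attempt)),
      transfer_recipients = config$transfer_recipients, clades = clades)
    ok <- all(cand$counts[, focal_genome] >= 1L)
    if (ok) { content <- cand; break }
  }
  if (is.null(content))
    stop("could not condition on focal-genome presence after ",
         config$max_attempts, " attempts")

  alignments <- list()
  for (f in fams) {
    gt <- content$gene_trees[[f]]
    if (!is.null(gt)) {
      alignments[[f]] <- evolve_sequences(
        gt, config$seq_length, config$subst_rate,
        seed = substream_seed(seed, paste0("seq_", f)))
    } else if (nrow(content$tips[[f]]) == 1L) {
      tp <- content$tips[[f]]
      alignments[[f]] <- evolve_single_sequence(
        1 - content$t_origin[[f]], config$seq_length, config$subst_rate,
        seed = substream_seed(seed, paste0("seq_", f)),
        label = paste0(tp$genome, "|", tp$copy_id))
    }
  }

  modules <- list(core = core_fams)
  if (length(acc_fams)) modules$acc <- acc_fams
  genomes <- assemble_genomes(content$tips, modules, clade_paths,
                              p_linkage = config$p_linkage,
                              n_background = config$n_background,
                              seed = substream_seed(seed, "assembly"),
                              force_linked = focal_genome,
                              genomes = tree$tip.label)
  templates <- default_feature_templates(fams)
  seq_lengths <- setNames(rep(config$seq_length, length(fams)), fams)
  features <- annotate_features(genomes, templates,
                                flip_noise = config$flip_noise,
                                seq_lengths = seq_lengths,
                                filler_len = config$filler_len,
                                seed = substream_seed(seed, "features"))

  # proteome keyed by locus tag; machinery loci carry their copy sequence
  isfam <- !is.na(genomes$family_id)
  locus_map <- data.frame(
    locus_tag = genomes$locus_tag[isfam],
    genome_id = genomes$genome_id[isfam],
    family_id = genomes$family_id[isfam],
    copy_id = genomes$copy_id[isfam],
    row_id = paste0(genomes$genome_id[isfam], "|", genomes$copy_id[isfam]),
    stringsAsFactors = FALSE)
  proteome <- character(nrow(genomes))
  names(proteome) <- genomes$locus_tag
  nbg <- sum(!isfam)
  proteome[!isfam] <- unname(random_proteins(
    nbg, config$filler_len, seed = substream_seed(seed, "fillers")))
  for (f in fams) {
    ab <- alignments[[f]]
    if (is.null(ab)) next
    rows <- ab_strings(ab)
    sel <- locus_map$family_id == f
    proteome[locus_map$locus_tag[sel]] <- rows[locus_map$row_id[sel]]
  }

  # two synthetic transposon-screen gene lists over the focal genome:
  # machinery loci are hit often, background loci rarely; every machinery
  # block is guaranteed two hits so the screens mark each region (the
  # screens are unsaturated but not blind, as in the source mutant hunts)
  screen_lists <- with_substream(seed, "mutant_lists", {
    fl <- genomes[genomes$genome_id == focal_genome, , drop = FALSE]
    mach <- fl$locus_tag[!is.na(fl$family_id)]
    fill <- fl$locus_tag[is.na(fl$family_id)]
    hr <- config$screen_hit_rates
    la <- c(mach[runif(length(mach)) < hr$machinery_a],
            fill[runif(length(fill)) < hr$filler_a])
    lb <- c(mach[runif(length(mach)) < hr$machinery_b],
            fill[runif(length(fill)) < hr$filler_b])
    blocks <- split(fl$locus_tag[!is.na(fl$family_id)],
                    paste(vapply(fl$family_id[!is.na(fl$family_id)],
                                 function(x) names(which(vapply(modules,
                                   function(m) x %in% m, logical(1))))[1],
                                 character(1)),
                          fl$copy_id[!is.na(fl$family_id)]))
    for (b in blocks) {
      hit <- intersect(b, union(la, lb))
      if (length(hit) < 2) la <- union(la, head(sort(b), 2))
    }
    list(list_a = sort(unique(la)), list_b = sort(unique(lb)))
  })

  structure(list(
    config = config, seed = seed, tree = tree, clades = clades,
    screen_lists = screen_lists,
    clade_paths = clade_paths, genomes = genomes, features = features,
    proteome = proteome, alignments = alignments,
    gene_trees = content$gene_trees, events = content$events,
    counts = content$counts, locus_map = locus_map,
    origins = setNames(vapply(params, `[[`, "", "origin_branch"), fams),
    t_origin = content$t_origin,
    focal_genome = focal_genome, focal_clade = focal_clade,
    focal_branches = fb[c("focal", "focal_sub", "focal_sub2")],
    wgd_branch = if (isTRUE(config$wgd)) fb$focal_sub else NA_character_,
    modules = modules), class = "glide_sim")
}

#' Write a simulated dataset to plain-text pipeline inputs
#'
#' Emits per-genome protein FASTA, the gene table, the feature table, the
#' species tree and the true event log under one directory.
#'
#' @param sim a `glide_sim`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in unique(sim$genomes$genome_id)) {
    tags <- sim$genomes$locus_tag[sim$genomes$genome_id == g]
    write_fasta(sim$proteome[tags], file.path(dir, paste0(g, ".faa")))
  }
  write_gene_table(sim$genomes, file.path(dir, "gene_table.tsv"))
  write_feature_table(sim$features, file.path(dir, "features.tsv"))
  write_newick(sim$tree, file.path(dir, "species_tree.nwk"))
  write.table(sim$events, file.path(dir, "true_events.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
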
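# Evolutionary-scenario reconstruction: single-gain Dollo parsimony for
# origins and losses, species-overlap duplications, displacement-derived
# transfers, and recovery scoring against a simulator truth log.

#' Single-gain (Dollo) reconstruction of a presence/absence profile
#'
#' The origin is the branch above the MRCA of all present tips; losses are
#' the minimal set of branches below the origin whose removal explains all
#' absent tips (the maximal presence-free subtrees under the origin).
#' This loss count is minimal among all single-gain explanations.
#'
#' @param presence named 0/1 (or logical) vector over tip labels; tips
#'   missing from the vector count as absent
#' @param tree rooted `phylo`
#' @return list with `origin_branch`, `loss_branches`, `n_losses`
#' @export
dollo_reconstruct <- function(presence, tree) {
  tree <- label_nodes(tree)
  pres_tips <- intersect(names(presence)[presence >= 1], tree$tip.label)
  if (!length(pres_tips)) stop("all-absent profile")
  org <- mrca_node(tree, pres_tips)
  nm <- node_names(tree)
  nt <- ape::Ntip(tree)
  losses <- character()
  has_present <- function(node) {
    any(tips_below(tree, node) %in% pres_tips)
  }
  walk <- function(node) {
    for (ch in tree$edge[tree$edge[, 1] == node, 2]) {
      if (has_present(ch)) {
        if (ch > nt) walk(ch)
      } else {
        losses <<- c(losses, nm[ch])
      }
    }
  }
  if (org > nt) walk(org)
  list(origin_branch = nm[org], loss_branches = losses,
       n_losses = length(losses))
}

#' Fitch small-parsimony change count for a binary profile
#'
#' Minimal number of state changes with unconstrained gains and losses; a
#' QC comparator for the single-gain Dollo count (profiles where free
#' gains beat a single gain markedly are suspect).
#'
#' @inheritParams dollo_reconstruct
#' @return non-negative integer
#' @export
fitch_count <- function(presence, tree) {
  tree <- label_nodes(tree)
  nt <- ape::Ntip(tree)
  state <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) {
    p <- presence[tree$tip.label[i]]
    state[[i]] <- if (!is.na(p) && p >= 1) 1L else 0L
  }
  changes <- 0L
  post <- rev(ape::reorder.phylo(tree, "cladewise")$edge[, 2])
  for (node in c(post[post > nt], nt + 1L)) {
    if (!is.null(state[[node]])) next
    ch <- tree$edge[tree$edge[, 1] == node, 2]
    ss <- lapply(ch, function(x) state[[x]])
    inter <- Reduce(intersect, ss)
    if (length(inter)) state[[node]] <- inter
    else {
      state[[node]] <- Reduce(union, ss)
      changes <- changes + 1L
    }
  }
  changes
}

#' Species-overlap duplication inference
#'
#' An internal node of a rooted gene tree is a duplication iff its two
#' child subtrees share at least one species; each duplication is mapped
#' to the species-tree branch above the MRCA of the node's species set.
#'
#' @param gene_tree rooted `phylo`
#' @param leaf_species named vector: leaf -> species (every leaf mapped)
#' @param species_tree rooted `phylo`
#' @return data.frame `node`, `branch` (species-tree branch), `n_species`
#' @export
infer_duplications <- function(gene_tree, leaf_species, species_tree) {
  unmapped <- setdiff(gene_tree$tip.label, names(leaf_species))
  if (length(unmapped))
    stop("unmapped leaf/leaves: ", paste(unmapped, collapse = ", "))
  species_tree <- label_nodes(species_tree)
  nt <- ape::Ntip(gene_tree)
  out <- list()
  for (node in (nt + 1L):(nt + gene_tree$Nnode)) {
    ch <- gene_tree$edge[gene_tree$edge[, 1] == node, 2]
    if (length(ch) < 2) next
    sets <- lapply(ch, function(x)
      unique(leaf_species[tips_below(gene_tree, x)]))
    if (length(Reduce(intersect, sets)) >= 1) {
      spp <- unique(unlist(sets))
      m <- mrca_node(species_tree, spp)
      out[[length(out) + 1L]] <- data.frame(
        node = node, branch = branch_above(species_tree, m),
        n_species = length(spp), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(node = integer(), branch = character(),
                      n_species = integer()))
  do.call(rbind, out)
}

#' Turn displacement reports into transfer events
#'
#' Each displaced leaf yields one transfer: the recipient is the displaced
#' taxon's terminal branch and the source the observed sister clade.
#' Genomes whose every copy is transfer-derived are excluded from the
#' presence profile handed to Dollo, so vertical origin and losses are
#' re-estimated without transfer-derived tips.
#'
#' @param displacements data.frame from [displacement_test()] plus a
#'   `taxon` column (leaf -> genome)
#' @param presence named copy-count vector (genome -> count)
#' @param copies_per_genome named count of the family's leaves per genome
#' @return list with `transfers` (data.frame `recipient_branch`,
#'   `source_clade`, `support`) and `presence_vertical` (presence with
#'   fully transfer-derived genomes zeroed)
#' @export
infer_transfers <- function(displacements, presence, copies_per_genome) {
  if (!nrow(displacements)) {
    return(list(transfers = data.frame(recipient_branch = character(),
                                       source_clade = character(),
                                       support = numeric()),
                presence_vertical = presence))
  }
  tr <- data.frame(recipient_branch = displacements$taxon,
                   source_clade = displacements$observed_clade,
                   support = displacements$support,
                   stringsAsFactors = FALSE)
  displaced_n <- table(displacements$taxon)
  pv <- presence
  for (g in names(displaced_n)) {
    if (!is.na(copies_per_genome[g]) &&
        displaced_n[[g]] >= copies_per_genome[[g]])
      pv[g] <- 0
  }
  list(transfers = tr, presence_vertical = pv)
}

#' Assemble per-family evolutionary scenarios
#'
#' Combines the phyletic profile, rooted gene trees with supports,
#' displacement reports and the species tree into one scenario per family:
#' origin branch, loss branches, duplication branches, transfer events and
#' the taxonomic-breadth group label.  Displaced (transfer-derived) leaves
#' are pruned before duplication inference so a transferred copy is not
#' misread as an ancient duplication.
#'
#' @param profile phyletic profile matrix (with `clade_paths` attribute)
#' @param membership data.frame `locus_tag`, `family_id`, `genome_id`
#' @param gene_trees named list of rooted, support-annotated gene trees
#'   (`NULL` allowed for tiny families)
#' @param displacements named list of displacement reports per family
#'   (with `taxon` column)
#' @param species_tree rooted species tree
#' @param focal_clades clade labels counted as focal
#' @return list of class `evolutionary_scenario_set`: per family a list
#'   with `origin_branch`, `loss_branches`, `duplications`, `transfers`,
#'   `group`
#' @export
assemble_scenario <- function(profile, membership, gene_trees,
                              displacements, species_tree, focal_clades) {
  species_tree <- label_nodes(species_tree)
  fams <- rownames(profile)
  if (!setequal(fams, unique(membership$family_id)))
    stop("family universes of profile and membership differ")
  groups <- classify_profile(profile, focal_clades)
  out <- list()
  for (f in fams) {
    counts <- profile[f, ]
    mem <- membership[membership$family_id == f, , drop = FALSE]
    cpg <- table(mem$genome_id)
    disp <- displacements[[f]] %||%
      data.frame(leaf = character(), taxon = character(),
                 expected_clade = character(), observed_clade = character(),
                 support = numeric())
    tr <- infer_transfers(disp, counts, cpg)
    dup <- data.frame(node = integer(), branch = character(),
                      n_species = integer())
    gt <- gene_trees[[f]]
    if (!is.null(gt)) {
      keep <- setdiff(gt$tip.label, disp$leaf)
      gtp <- if (length(keep) >= 2 && length(keep) < ape::Ntip(gt))
        ape::keep.tip(gt, keep) else gt
      if (length(keep) >= 2) {
        leaf_species <- setNames(mem$genome_id, mem$locus_tag)
        dup <- infer_duplications(gtp, leaf_species, species_tree)
      }
    }
    pv <- tr$presence_vertical
    dollo <- if (any(pv >= 1)) dollo_reconstruct(pv, species_tree)
             else list(origin_branch = NA_character_,
                       loss_branches = character(), n_losses = 0L)
    out[[f]] <- list(family_id = f, origin_branch = dollo$origin_branch,
                     loss_branches = dollo$loss_branches,
                     duplications = dup, transfers = tr$transfers,
                     group = unname(groups[f]))
  }
  class(out) <- c("evolutionary_scenario_set", "list")
  out
}

#' Flatten a scenario set into an event table
#'
#' @param scenarios an `evolutionary_scenario_set`
#' @return data.frame `family_id`, `type`, `branch`, `source`, `support`
#' @export
scenario_events <- function(scenarios) {
  rows <- list()
  add <- function(f, type, branch, source = NA_character_, support = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      family_id = f, type = type, branch = branch, source = source,
      support = support, stringsAsFactors = FALSE)
  }
  for (s in scenarios) {
    if (!is.na(s$origin_branch)) add(s$family_id, "gain", s$origin_branch)
    for (b in s$loss_branches) add(s$family_id, "loss", b)
    if (nrow(s$duplications))
      for (b in s$duplications$branch) add(s$family_id, "duplication", b)
    if (nrow(s$transfers))
      for (k in seq_len(nrow(s$transfers)))
        add(s$family_id, "transfer", s$transfers$recipient_branch[k],
            s$transfers$source_clade[k], s$transfers$support[k])
  }
  if (!length(rows))
    return(data.frame(family_id = character(), type = character(),
                      branch = character(), source = character(),
                      support = numeric()))
  do.call(rbind, rows)
}

#' Score inferred events against a true event log
#'
#' Exact multiset matching on (family, event type, branch) for gains,
#' losses and duplications.  Transfers match on the recipient branch only
#' (the donor is not compared); because displacement localizes a transfer
#' to the displaced tip, an inferred recipient on or below the true
#' recipient branch matches it, and several displaced descendants of one
#' internal-branch transfer all count as manifestations of that single
#' event (precision = inferred events compatible with some true event,
#' recall = true events with at least one compatible inferred event).
#' A family-id translation can map inferred family names onto truth names.
#'
#' @param inferred data.frame from [scenario_events()]
#' @param truth true event log (from the simulator)
#' @param family_map optional named vector inferred id -> truth id
#' @param species_tree species tree used for descendant matching of
#'   transfer recipients; when `NULL`, transfers match on exact branch
#' @return data.frame per event type: `type`, `n_true`, `n_inferred`,
#'   `n_matched`, `precision`, `recall`, `f1` (`n_matched` is the matched
#'   true-event count)
#' @export
recovery_metrics <- function(inferred, truth, family_map = NULL,
                             species_tree = NULL) {
  inf <- inferred
  if (!is.null(family_map))
    inf$family_id <- unname(family_map[inf$family_id])
  if (!is.null(species_tree)) species_tree <- label_nodes(species_tree)
  below <- function(b) {
    # tips at or below a branch of the species tree
    node <- node_of_branch(species_tree, b)
    tips_below(species_tree, node)
  }
  key <- function(df) paste(df$family_id, df$type, df$branch, sep = "\r")
  out <- list()
  for (ty in c("gain", "loss", "duplication", "transfer")) {
    ti <- inf[inf$type == ty & !is.na(inf$family_id), , drop = FALSE]
    tt <- truth[truth$type == ty, , drop = FALSE]
    if (ty == "transfer" && !is.null(species_tree)) {
      compat <- function(bi, bt) bi %in% below(bt)
      m_true <- logical(nrow(tt)); m_inf <- logical(nrow(ti))
      for (k in seq_len(nrow(ti))) for (j in seq_len(nrow(tt))) {
        if (ti$family_id[k] == tt$family_id[j] &&
            compat(ti$branch[k], tt$branch[j])) {
          m_inf[k] <- TRUE; m_true[j] <- TRUE
        }
      }
      matched <- sum(m_true)
      prec <- if (nrow(ti)) sum(m_inf) / nrow(ti) else NA_real_
      rec <- if (nrow(tt)) sum(m_true) / nrow(tt) else NA_real_
    } else {
      ki <- table(key(ti)); kt <- table(key(tt))
      shared <- intersect(names(ki), names(kt))
      matched <- sum(pmin(ki[shared], kt[shared]))
      prec <- if (nrow(ti)) matched / nrow(ti) else NA_real_
      rec <- if (nrow(tt)) matched / nrow(tt) else NA_real_
    }
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
      2 * prec * rec / (prec + rec) else NA_real_
    out[[ty]] <- data.frame(type = ty, n_true = nrow(tt),
                            n_inferred = nrow(ti), n_matched = matched,
                            precision = prec, recall = rec, f1 = f1,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Plain-text rendering of a scenario on the species tree
#'
#' An indented traversal of the species tree with per-branch event
#' annotations: families gained (+), lost (-), duplicated (D) and
#' received by transfer (T) on each branch.
#'
#' @param scenarios an `evolutionary_scenario_set`
#' @param species_tree rooted `phylo`
#' @return character vector of lines, invisibly; also printed
#' @export
render_scenario_tree <- function(scenarios, species_tree) {
  species_tree <- label_nodes(species_tree)
  ev <- scenario_events(scenarios)
  tag <- c(gain = "+", loss = "-", duplication = "D:", transfer = "T:")
  ann <- function(branch) {
    e <- ev[ev$branch == branch, , drop = FALSE]
    if (!nrow(e)) return("")
    paste0("  [", paste(paste0(tag[e$type], e$family_id), collapse = " "),
           "]")
  }
  nt <- ape::Ntip(species_tree)
  nm <- node_names(species_tree)
  lines <- character()
  walk <- function(node, depth) {
    lines <<- c(lines, paste0(strrep("  ", depth), nm[node],
                              ann(nm[node])))
    for (ch in species_tree$edge[species_tree$edge[, 1] == node, 2])
      walk(ch, depth + 1L)
  }
  walk(nt + 1L, 0L)
  cat(lines, sep = "\n")
  invisible(lines)
}
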
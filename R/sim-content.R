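# Gene-content evolution along a species tree: per-copy Gillespie
# simulation of duplication, loss and additive horizontal transfer, with a
# complete event log and full copy ancestry (the family's true gene tree).

#' Simulate one gene-family history along a species tree
#'
#' Each extant copy independently duplicates (rate `dup_rate`), dies
#' (`loss_rate`) or emits a transferred copy (`transfer_rate`) per unit
#' branch length; at speciations a copy passes into both daughter lineages.
#' Transfers are additive: the recipient gains an extra copy and the donor
#' keeps its own.  Recipient branches are drawn uniformly among branches
#' alive at the donor time, either over all of them (`"uniform"`) or only
#' those outside the donor's top-level clade (`"cross_clade"`, the
#' observable regime for displacement-based HGT detection).
#'
#' @param tree rooted ultrametric `phylo` with node labels
#' @param origin_branch branch name (child-node label) where the family is
#'   gained; the root's own label means presence at the root
#' @param dup_rate,loss_rate,transfer_rate event rates per copy per unit
#'   branch length
#' @param forced_dup_branches branches carrying a whole-module duplication:
#'   every copy alive at the branch midpoint duplicates once there
#' @param transfer_recipients `"uniform"` or `"cross_clade"`
#' @param clades named vector tip -> top-level clade (required for
#'   `"cross_clade"`)
#' @param family_id identifier written into the event log
#' @return list with `gene_tree` (`phylo`; `NULL` when fewer than 2 copies
#'   survive), `tips` (data.frame `genome`, `copy_id`), `events`
#'   (data.frame), `t_origin`, and `extinct`
#' @export
sim_family_history <- function(tree, origin_branch,
                               dup_rate = 0, loss_rate = 0, transfer_rate = 0,
                               forced_dup_branches = character(),
                               transfer_recipients = c("uniform", "cross_clade"),
                               clades = NULL, family_id = "F1") {
  transfer_recipients <- match.arg(transfer_recipients)
  tree <- label_nodes(tree)
  et <- edge_table(tree)
  nm <- node_names(tree)
  root <- ape::Ntip(tree) + 1L
  if (!origin_branch %in% c(nm[root], et$branch))
    stop("origin branch not in tree: ", origin_branch)
  if (transfer_recipients == "cross_clade" && is.null(clades))
    stop("cross_clade transfers require clade assignments")
  kids <- split(seq_len(nrow(et)), et$parent)
  edge_clades <- lapply(seq_len(nrow(et)), function(i)
    unique(clades[tips_below(tree, et$child[i])]))
  rho <- dup_rate + loss_rate + transfer_rate

  env <- new.env(parent = emptyenv())
  env$ev <- list()
  env$tips <- list()
  env$counter <- 0L
  new_copy <- function() { env$counter <- env$counter + 1L
                           paste0("c", env$counter) }
  log_event <- function(type, branch, time, copy_id,
                        parent_copy = NA_character_,
                        donor = NA_character_, module_dup = FALSE) {
    env$ev[[length(env$ev) + 1L]] <- data.frame(
      type = type, family_id = family_id, branch = branch, donor = donor,
      time = time, copy_id = copy_id, parent_copy_id = parent_copy,
      module_dup = module_dup, stringsAsFactors = FALSE)
  }
  join <- function(a, b, t) {
    if (is.null(a)) return(b)
    if (is.null(b)) return(a)
    list(time = t, kids = list(a, b))
  }
  pick_recipient <- function(ei, t) {
    alive <- which(et$t_start < t & t < et$t_end)
    alive <- setdiff(alive, ei)
    if (transfer_recipients == "cross_clade") {
      donor_cl <- edge_clades[[ei]]
      ok <- vapply(alive, function(j)
        !any(edge_clades[[j]] %in% donor_cl), logical(1))
      if (any(ok)) alive <- alive[ok]
    }
    if (!length(alive)) return(NA_integer_)
    alive[sample.int(length(alive), 1L)]
  }

  # whole-module duplication times: midpoint of each forced branch (all
  # copies alive on the branch at that moment duplicate once)
  edge_fd <- ifelse(et$branch %in% forced_dup_branches,
                    (et$t_start + et$t_end) / 2, NA_real_)

  sim_on_edge <- function(ei, t0, copy, fd = NA_real_) {
    t <- t0
    repeat {
      dt <- if (rho > 0) rexp(1, rho) else Inf
      if (!is.na(fd) && t + dt >= fd) {
        nid <- new_copy()
        log_event("duplication", et$branch[ei], fd, nid, parent_copy = copy,
                  module_dup = TRUE)
        a <- sim_on_edge(ei, fd, copy)
        b <- sim_on_edge(ei, fd, nid)
        return(join(a, b, fd))
      }
      if (t + dt >= et$t_end[ei]) {
        child <- et$child[ei]
        if (et$is_tip[ei]) {
          env$tips[[length(env$tips) + 1L]] <-
            data.frame(genome = et$branch[ei], copy_id = copy,
                       stringsAsFactors = FALSE)
          return(list(time = et$t_end[ei],
                      label = paste0(et$branch[ei], "|", copy)))
        }
        ke <- kids[[as.character(child)]]
        a <- sim_enter_edge(ke[1], copy)
        b <- sim_enter_edge(ke[2], copy)
        return(join(a, b, et$t_end[ei]))
      }
      t <- t + dt
      u <- runif(1) * rho
      if (u < loss_rate) {
        log_event("loss", et$branch[ei], t, copy)
        return(NULL)
      } else if (u < loss_rate + dup_rate) {
        nid <- new_copy()
        log_event("duplication", et$branch[ei], t, nid, parent_copy = copy)
        a <- sim_on_edge(ei, t, copy, fd)
        b <- sim_on_edge(ei, t, nid, fd)
        return(join(a, b, t))
      } else {
        rec <- pick_recipient(ei, t)
        if (is.na(rec)) next  # no contemporaneous eligible recipient
        nid <- new_copy()
        log_event("transfer", et$branch[rec], t, nid, parent_copy = copy,
                  donor = et$branch[ei])
        fd_rec <- if (!is.na(edge_fd[rec]) && edge_fd[rec] > t)
          edge_fd[rec] else NA_real_
        a <- sim_on_edge(ei, t, copy, fd)
        b <- sim_on_edge(rec, t, nid, fd_rec)
        return(join(a, b, t))
      }
    }
  }
  sim_enter_edge <- function(ei, copy) {
    sim_on_edge(ei, et$t_start[ei], copy, edge_fd[ei])
  }

  first <- new_copy()
  if (origin_branch == nm[root]) {
    t_origin <- 0
    log_event("gain", origin_branch, 0, first)
    ke <- kids[[as.character(root)]]
    a <- sim_enter_edge(ke[1], first)
    b <- sim_enter_edge(ke[2], first)
    res <- join(a, b, 0)
  } else {
    ei0 <- match(origin_branch, et$branch)
    t_origin <- et$t_start[ei0]
    log_event("gain", origin_branch, t_origin, first)
    res <- sim_on_edge(ei0, t_origin, first, edge_fd[ei0])
  }

  tips <- if (length(env$tips)) do.call(rbind, env$tips)
          else data.frame(genome = character(), copy_id = character())
  events <- do.call(rbind, env$ev)
  events <- events[order(events$time), , drop = FALSE]
  rownames(events) <- NULL
  gene_tree <- NULL
  if (nrow(tips) >= 2) {
    render <- function(node) {
      if (!is.null(node$label)) return(node$label)
      parts <- vapply(node$kids, function(k)
        paste0(render(k), ":", format(k$time - node$time, digits = 12)),
        character(1))
      paste0("(", paste(parts, collapse = ","), ")")
    }
    gene_tree <- read_newick_text(paste0(render(res), ";"))
  }
  list(gene_tree = gene_tree, tips = tips, events = events,
       t_origin = t_origin, extinct = nrow(tips) == 0)
}

#' Simulate gene content for a set of families
#'
#' Families sharing a `history_group` (e.g. the members of one co-evolving
#' gene module transferred and duplicated as an operon unit) are simulated
#' once and replicated, so their true gene trees are identical; other
#' families evolve independently.  All randomness derives from `seed`
#' through per-group substreams.
#'
#' @param tree rooted ultrametric `phylo`
#' @param params named list (one element per family) of lists with fields
#'   `origin_branch`, `dup_rate`, `loss_rate`, `transfer_rate`, optional
#'   `history_group` and `forced_dup_branches`
#' @param seed master integer seed
#' @param transfer_recipients,clades see [sim_family_history()]
#' @return list with `counts` (family x genome copy-count matrix over all
#'   tips), `gene_trees` (named list), `tips` (named list of data.frames),
#'   `events` (one data.frame, time-ordered), `t_origin` (named vector)
#' @export
evolve_gene_content <- function(tree, params, seed,
                                transfer_recipients = "uniform",
                                clades = NULL) {
  stopifnot(length(names(params)) == length(params))
  tree <- label_nodes(tree)
  groups <- vapply(names(params), function(f)
    params[[f]]$history_group %||% f, character(1))
  hist_res <- list()
  for (g in unique(groups)) {
    f1 <- names(params)[groups == g][1]
    p <- params[[f1]]
    hist_res[[g]] <- with_substream(seed, paste0("content_", g),
      sim_family_history(tree,
        origin_branch = p$origin_branch,
        dup_rate = p$dup_rate %||% 0,
        loss_rate = p$loss_rate %||% 0,
        transfer_rate = p$transfer_rate %||% 0,
        forced_dup_branches = p$forced_dup_branches %||% character(),
        transfer_recipients = transfer_recipients,
        clades = clades, family_id = f1))
  }
  genomes <- tree$tip.label
  counts <- matrix(0L, length(params), length(genomes),
                   dimnames = list(names(params), genomes))
  gene_trees <- list(); tips <- list(); evs <- list()
  t_origin <- setNames(numeric(length(params)), names(params))
  for (f in names(params)) {
    h <- hist_res[[groups[f]]]
    gene_trees[[f]] <- h$gene_tree
    tips[[f]] <- h$tips
    t_origin[f] <- h$t_origin
    if (nrow(h$tips)) {
      tab <- table(h$tips$genome)
      counts[f, names(tab)] <- as.integer(tab)
    }
    e <- h$events
    e$family_id <- f
    evs[[f]] <- e
  }
  events <- do.call(rbind, evs)
  events <- events[order(events$time, events$family_id), , drop = FALSE]
  rownames(events) <- NULL
  list(counts = counts, gene_trees = gene_trees, tips = tips,
       events = events, t_origin = t_origin)
}

#' Replay an event log to recover per-tip copy counts
#'
#' Independent accounting of the simulator: walks the species tree from the
#' root carrying the set of alive copy lineages per family and applies the
#' logged events on each branch in time order.  An event referencing a copy
#' that is not alive is an error (the log must be self-consistent).
#'
#' @param tree the species tree the log was generated on
#' @param events event log from [evolve_gene_content()]
#' @return a family x genome copy-count matrix
#' @export
replay_event_log <- function(tree, events) {
  tree <- label_nodes(tree)
  et <- edge_table(tree)
  nm <- node_names(tree)
  root <- ape::Ntip(tree) + 1L
  kids <- split(seq_len(nrow(et)), et$parent)
  fams <- unique(events$family_id)
  genomes <- tree$tip.label
  counts <- matrix(0L, length(fams), length(genomes),
                   dimnames = list(fams, genomes))
  for (f in fams) {
    ev <- events[events$family_id == f, , drop = FALSE]
    ev <- ev[order(ev$time), , drop = FALSE]
    walk <- function(ei, alive) {
      here <- ev[ev$branch == et$branch[ei], , drop = FALSE]
      for (k in seq_len(nrow(here))) {
        e <- here[k, ]
        if (e$type %in% c("gain", "duplication", "transfer")) {
          if (e$copy_id %in% alive)
            stop("log replay: copy already alive: ", e$copy_id)
          alive <- c(alive, e$copy_id)
        } else if (e$type == "loss") {
          if (!e$copy_id %in% alive)
            stop("log replay: losing a copy that is not alive: ", e$copy_id)
          alive <- setdiff(alive, e$copy_id)
        }
      }
      child <- et$child[ei]
      if (et$is_tip[ei]) {
        counts[f, et$branch[ei]] <<- length(alive)
      } else {
        for (j in kids[[as.character(child)]]) walk(j, alive)
      }
    }
    alive0 <- ev$copy_id[ev$type == "gain" & ev$branch == nm[root]]
    for (j in kids[[as.character(root)]]) walk(j, alive0)
  }
  counts
}
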
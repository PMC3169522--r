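#' Simulate a rooted ultrametric species tree
#'
#' Draws a random coalescent topology and rescales the total root-to-tip
#' depth to 1, so branch lengths are in units of tree depth and
#' per-unit-length rates are comparable across replicates.
#'
#' @param n_taxa number of tips (>= 3)
#' @param seed integer seed; the same seed always yields the same tree
#' @return a rooted binary ultrametric `phylo` with tips `t01`, `t02`, ...
#'   and labelled internal nodes
#' @export
simulate_species_tree <- function(n_taxa, seed) {
  if (n_taxa < 3) stop("n_taxa must be >= 3")
  with_substream(seed, "species_tree", {
    phy <- ape::rcoal(n_taxa, tip.label = sprintf("t%02d", seq_len(n_taxa)))
    depth <- max(node_times(phy))
    phy$edge.length <- phy$edge.length / depth
    label_nodes(phy)
  })
}

#' Simulate a radiation-structured species panel
#'
#' Emulates a panel of deeply divergent bacterial orders: a small number of
#' top-level clades split near the root (an ancient radiation), splits
#' within each clade fall in a mid-depth window, and the sampled
#' representatives sit on long terminal branches reaching depth 1.  This is
#' the shape of a sparse cross-phylum genome sample, where inter-order
#' divergences are old relative to the tips.
#'
#' @param n_taxa total number of tips
#' @param n_clades number of top-level clades
#' @param seed integer seed
#' @param backbone_window depth window (from the root) for the inter-clade
#'   radiation
#' @param clade_window depth window for splits within clades
#' @param clade_sizes optional integer vector (length `n_clades`, summing
#'   to `n_taxa`); defaults to a near-even split with the first clade
#'   largest
#' @return a rooted binary ultrametric `phylo` of depth 1; tips are named
#'   `t01`, ... clade by clade, so `top_clades(tree, mean(c(backbone_window[2],
#'   clade_window[1])))` recovers the built-in clades
#' @export
simulate_clade_tree <- function(n_taxa, n_clades = 5L, seed = 1L,
                                backbone_window = c(0, 0.12),
                                clade_window = c(0.35, 0.55),
                                clade_sizes = NULL) {
  stopifnot(n_clades >= 2, n_taxa >= n_clades,
            backbone_window[2] < clade_window[1], clade_window[2] < 1)
  if (is.null(clade_sizes)) {
    base <- n_taxa %/% n_clades
    clade_sizes <- rep(base, n_clades)
    extra <- n_taxa - sum(clade_sizes)
    if (extra > 0) clade_sizes[seq_len(extra)] <- base + 1L
    # make the first clade the largest (the focal-clade stand-in)
    clade_sizes <- sort(clade_sizes, decreasing = TRUE)
  }
  stopifnot(sum(clade_sizes) == n_taxa, length(clade_sizes) == n_clades)
  with_substream(seed, "clade_tree", {
    backbone <- ape::rcoal(n_clades, tip.label = paste0("K", seq_len(n_clades)))
    bt <- node_times(backbone)
    bdepth <- max(bt)
    # map backbone node times into the backbone window
    bt2 <- backbone_window[1] +
      bt / bdepth * (backbone_window[2] - backbone_window[1])
    backbone$edge.length <- bt2[backbone$edge[, 2]] - bt2[backbone$edge[, 1]]
    tip_counter <- 0L
    out <- backbone
    for (k in seq_len(n_clades)) {
      m <- clade_sizes[k]
      tipnames <- sprintf("t%02d", tip_counter + seq_len(m))
      tip_counter <- tip_counter + m
      where <- match(paste0("K", k), out$tip.label)
      b_k <- bt2[match(paste0("K", k), backbone$tip.label)]
      if (m == 1L) {
        # extend the backbone terminal edge to depth 1 and rename
        ei <- which(out$edge[, 2] == where)
        out$edge.length[ei] <- out$edge.length[ei] + (1 - b_k)
        out$tip.label[where] <- tipnames
        next
      }
      cr <- runif(1, clade_window[1],
                  clade_window[1] + 0.4 * diff(clade_window))
      sub <- ape::rcoal(m, tip.label = tipnames)
      st <- node_times(sub)
      sdepth <- max(st)
      # clade root at depth cr, internal splits within the clade window,
      # tips at depth 1
      nt <- ape::Ntip(sub)
      newt <- numeric(length(st))
      newt[seq_len(nt)] <- 1
      internal <- (nt + 1):(nt + sub$Nnode)
      # st measures depth from the clade root (0 at root, sdepth at tips);
      # map internal depths proportionally into [cr, clade_window[2]]
      newt[internal] <- cr + (st[internal] / sdepth) * (clade_window[2] - cr)
      sub$edge.length <- newt[sub$edge[, 2]] - newt[sub$edge[, 1]]
      sub$root.edge <- cr - b_k
      out <- ape::bind.tree(out, sub, where = match(paste0("K", k), out$tip.label))
    }
    out <- ape::reorder.phylo(out, "cladewise")
    out$node.label <- NULL
    label_nodes(out)
  })
}
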
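# Shared helpers for working with rooted ape::phylo trees.  Branches are
# identified throughout the package by the label of the node they lead to
# (tip label for terminal branches, node label for internal ones); "above
# the root" is identified by the root's own label so that a family present
# at the root can carry its gain there.

#' Ensure a tree has stable node labels
#'
#' Internal nodes without labels get `N<node number>`; existing labels are
#' kept.  Tip labels must be unique and distinct from node labels.
#'
#' @param phy rooted `phylo`
#' @param prefix label prefix for unnamed internal nodes
#' @return the relabelled tree
#' @export
label_nodes <- function(phy, prefix = "N") {
  nn <- phy$Nnode
  lab <- phy$node.label
  if (is.null(lab) || !length(lab)) lab <- rep("", nn)
  empty <- is.na(lab) | lab == ""
  lab[empty] <- paste0(prefix, ape::Ntip(phy) + which(empty))
  phy$node.label <- lab
  all <- c(phy$tip.label, lab)
  if (anyDuplicated(all))
    stop("duplicate node/tip labels: ", all[duplicated(all)][1])
  phy
}

#' Labels of every node, indexed by node number
#'
#' Tips first, then internal nodes; the vector of valid branch names.
#' @param phy rooted `phylo`
#' @return character vector of length `Ntip + Nnode`
#' @export
node_names <- function(phy) {
  if (is.null(phy$node.label)) phy <- label_nodes(phy)
  c(phy$tip.label, phy$node.label)
}

#' Node times measured from the root
#' @param phy rooted `phylo` with branch lengths
#' @return numeric vector indexed by node number
#' @export
node_times <- function(phy) {
  ape::node.depth.edgelength(phy)
}

#' Edge table of a rooted tree
#'
#' @param phy rooted `phylo` with branch lengths and node labels
#' @return data.frame with one row per edge: `parent`, `child` (node
#'   numbers), `branch` (child label), `t_start`, `t_end`, `length`,
#'   `is_tip`
#' @export
edge_table <- function(phy) {
  phy <- label_nodes(phy)
  nm <- node_names(phy)
  tt <- node_times(phy)
  data.frame(parent = phy$edge[, 1], child = phy$edge[, 2],
             branch = nm[phy$edge[, 2]],
             t_start = tt[phy$edge[, 1]], t_end = tt[phy$edge[, 2]],
             length = phy$edge.length,
             is_tip = phy$edge[, 2] <= ape::Ntip(phy),
             stringsAsFactors = FALSE)
}

# tip labels below a node (the node itself if it is a tip)
tips_below <- function(phy, node) {
  nt <- ape::Ntip(phy)
  if (node <= nt) return(phy$tip.label[node])
  phy$tip.label[phangorn::Descendants(phy, node, type = "tips")[[1]]]
}

# node number of the MRCA of a set of tip labels (the tip itself for one)
mrca_node <- function(phy, tips) {
  tips <- unique(tips)
  stopifnot(all(tips %in% phy$tip.label))
  if (length(tips) == 1L) return(match(tips, phy$tip.label))
  ape::getMRCA(phy, tips)
}

# branch name of the edge above a node (root -> its own label)
branch_above <- function(phy, node) {
  node_names(phy)[node]
}

# node number carrying a given branch name
node_of_branch <- function(phy, branch) {
  i <- match(branch, node_names(phy))
  if (is.na(i)) stop("unknown branch: ", branch)
  i
}

# is `anc` (node number) an ancestor of (or equal to) `node`?
is_ancestor <- function(phy, anc, node) {
  if (anc == node) return(TRUE)
  root <- ape::Ntip(phy) + 1L
  while (node != root) {
    node <- phy$edge[phy$edge[, 2] == node, 1]
    if (node == anc) return(TRUE)
  }
  anc == root
}

#' Assign top-level clade labels by cutting the tree at a depth
#'
#' Every tip is assigned the label of its most rootward ancestor whose
#' subtree starts after `depth_cut` (i.e. the lineage crossing the cut);
#' clades are labelled `C1`, `C2`, ... in the order their first tip appears
#' in `phy$tip.label`.
#'
#' @param phy rooted ultrametric `phylo`
#' @param depth_cut depth from the root at which to cut
#' @return named character vector: tip label -> clade label
#' @export
top_clades <- function(phy, depth_cut) {
  phy <- label_nodes(phy)
  et <- edge_table(phy)
  nt <- ape::Ntip(phy)
  # edges crossing the cut define the clades
  cross <- et[et$t_start < depth_cut & et$t_end >= depth_cut, , drop = FALSE]
  assign <- setNames(rep(NA_character_, nt), phy$tip.label)
  for (i in seq_len(nrow(cross))) {
    tips <- tips_below(phy, cross$child[i])
    assign[tips] <- cross$branch[i]
  }
  if (anyNA(assign)) stop("depth_cut does not separate all tips")
  first <- order(match(names(assign), phy$tip.label))
  lev <- unique(assign[first])
  setNames(paste0("C", match(assign, lev)), names(assign))
}
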
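# Desk-scale tree inference and comparison: column masking, corrected
# distances under the uniform 20-state model, classical neighbour joining,
# nonparametric bootstrap, Robinson-Foulds distance and the
# taxon-displacement test used as the HGT signal.

GAPCHARS <- c("-", "X")

#' Mask alignment columns by missing-data fraction
#'
#' Drops every column whose fraction of gap/unknown symbols exceeds
#' `max_missing` (the automated proxy for removing positions of doubtful
#' homology before tree building).
#'
#' @param ab an [alignment_block()]
#' @param max_missing fraction in `[0, 1]`
#' @return the masked `alignment_block`; `attr(, "kept")` gives the number
#'   of retained positions
#' @export
mask_columns <- function(ab, max_missing = 0.5) {
  stopifnot(max_missing >= 0, max_missing <= 1)
  if (nrow(ab) == 0 || ncol(ab) == 0) stop("empty alignment")
  frac <- colMeans(matrix(unclass(ab) %in% GAPCHARS, nrow(ab)))
  keep <- frac <= max_missing
  out <- unclass(ab)[, keep, drop = FALSE]
  out <- alignment_block(out)
  attr(out, "kept") <- sum(keep)
  out
}

# per-pair mismatch and shared-coverage count matrices (pairs x columns),
# reused by the bootstrap so replicate distances are one matrix product
pair_comparison <- function(ab) {
  m <- unclass(ab)
  n <- nrow(m)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ok <- !(m %in% GAPCHARS)
  dim(ok) <- dim(m)
  M <- matrix(0, nrow(pairs), ncol(m))
  V <- matrix(0, nrow(pairs), ncol(m))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    both <- ok[i, ] & ok[j, ]
    V[k, ] <- as.numeric(both)
    M[k, ] <- as.numeric(both & (m[i, ] != m[j, ]))
  }
  list(pairs = pairs, mismatch = M, valid = V, labels = rownames(m))
}

correct_distance <- function(p, model, alpha, cap) {
  arg <- 1 - (20 / 19) * p
  ok <- arg > 0
  d <- switch(model,
    p = p,
    poisson = ifelse(ok, -(19 / 20) * log(pmax(arg, 1e-300)), NA_real_),
    gamma = ifelse(ok, (19 / 20) * alpha *
                     (pmax(arg, 1e-300)^(-1 / alpha) - 1), NA_real_))
  sat <- !is.finite(d) | (model != "p" & !ok)
  if (any(sat)) {
    warning(sum(sat), " saturated pair(s) capped at ", cap)
    d[sat] <- cap
  }
  d
}

#' Pairwise distances from an alignment
#'
#' Pairwise deletion: each pair uses only the columns where both rows are
#' non-gap.  `p` is the raw mismatch fraction; `poisson` applies the
#' 20-state uniform-model correction `-(19/20) log(1 - (20/19) p)` (the
#' inverse of the simulator's substitution model); `gamma` its
#' Gamma-rate-heterogeneity generalization with shape `alpha`.  Saturated
#' pairs are capped at `cap` with a warning.
#'
#' @param ab an [alignment_block()] with >= 2 rows
#' @param model `"p"`, `"poisson"` or `"gamma"`
#' @param alpha Gamma shape (used by `model = "gamma"`)
#' @param cap distance assigned to saturated pairs
#' @return symmetric distance matrix with zero diagonal
#' @export
pairwise_distance <- function(ab, model = c("poisson", "p", "gamma"),
                              alpha = 1, cap = 5) {
  model <- match.arg(model)
  if (nrow(ab) < 2) stop("need at least 2 rows")
  pc <- pair_comparison(ab)
  shared <- rowSums(pc$valid)
  if (any(shared == 0)) {
    k <- which(shared == 0)[1]
    stop("no shared columns between ", pc$labels[pc$pairs[k, 1]], " and ",
         pc$labels[pc$pairs[k, 2]])
  }
  p <- rowSums(pc$mismatch) / shared
  d <- correct_distance(p, model, alpha, cap)
  n <- length(pc$labels)
  D <- matrix(0, n, n, dimnames = list(pc$labels, pc$labels))
  D[pc$pairs] <- d
  D[pc$pairs[, c(2, 1), drop = FALSE]] <- d
  D
}

#' Neighbour-joining tree
#'
#' Classical NJ (Saitou-Nei Q criterion with Studier-Keppler updates).
#' Deterministic: ties in Q are broken towards the lexicographically
#' smallest label pair.  Negative branch lengths are clamped to zero and
#' the total clamped deficit recorded in `attr(, "clamped")`.
#'
#' @param D symmetric distance matrix with labels (>= 3)
#' @param tol asymmetry tolerance
#' @return an unrooted `phylo` tree
#' @export
neighbor_joining <- function(D, tol = 1e-8) {
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("L", seq_len(nrow(D)))
  if (nrow(D) < 3) stop("need at least 3 labels")
  if (max(abs(D - t(D))) > tol) stop("distance matrix is asymmetric")
  labels <- rownames(D)
  nwk <- setNames(labels, labels)
  clamped <- 0
  bl <- function(x) {
    if (x < 0) { clamped <<- clamped - x; x <- 0 }
    format(x, digits = 12)
  }
  while (nrow(D) > 3) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)))
    if (length(cand) > 2L) {  # tie: lexicographically smallest label pair
      ij <- arrayInd(cand, dim(Q))
      ij <- ij[ij[, 1] < ij[, 2], , drop = FALSE]
      key <- vapply(seq_len(nrow(ij)), function(k) {
        p <- sort(rownames(D)[ij[k, ]]); paste(p[1], p[2]) }, character(1))
      sel <- ij[order(key)[1], ]
    } else {
      sel <- sort(arrayInd(cand[1], dim(Q)))
    }
    i <- sel[1]; j <- sel[2]
    dij <- D[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- dij - li
    la <- rownames(D)[i]; lb <- rownames(D)[j]
    newlab <- paste0("(", la, ",", lb, ")")
    newnwk <- paste0("(", nwk[[la]], ":", bl(li), ",",
                     nwk[[lb]], ":", bl(lj), ")")
    dnew <- (D[i, ] + D[j, ] - dij) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- D[keep, keep, drop = FALSE]
    D2 <- rbind(cbind(D2, dnew[keep]), c(dnew[keep], 0))
    rownames(D2)[n - 1] <- colnames(D2)[n - 1] <- newlab
    D <- D2
    nwk <- c(nwk[setdiff(names(nwk), c(la, lb))], setNames(newnwk, newlab))
  }
  l <- rownames(D)
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- paste0("(", nwk[[l[1]]], ":", bl(la), ",", nwk[[l[2]]], ":",
                bl(lb), ",", nwk[[l[3]]], ":", bl(lc), ");")
  tr <- ape::read.tree(text = txt)
  attr(tr, "clamped") <- clamped
  tr
}

# canonical keys of the non-trivial bipartitions of an unrooted tree
bipartition_keys <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  nt <- length(tips)
  pp <- ape::prop.part(tree)
  labels <- attr(pp, "labels")
  keys <- character()
  for (part in pp) {
    side <- labels[part]
    if (length(side) <= 1 || length(side) >= nt - 1) next
    if (tips[1] %in% side) side <- setdiff(tips, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Robinson-Foulds distance
#'
#' Number of non-trivial bipartitions present in exactly one of the two
#' unrooted trees.  Zero iff the unrooted topologies are identical.
#'
#' @param t1,t2 `phylo` trees on the same leaf set
#' @return non-negative integer
#' @export
robinson_foulds <- function(t1, t2) {
  d <- c(setdiff(t1$tip.label, t2$tip.label),
         setdiff(t2$tip.label, t1$tip.label))
  if (length(d))
    stop("leaf sets differ: ", paste(d, collapse = ", "))
  k1 <- bipartition_keys(t1); k2 <- bipartition_keys(t2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Nonparametric bootstrap supports for a neighbour-joining tree
#'
#' Columns are resampled with replacement `n_reps` times; each replicate
#' is run through [pairwise_distance()] and [neighbor_joining()], and each
#' internal edge of the reference tree (from the unresampled alignment) is
#' annotated with the percentage of replicates containing the same
#' bipartition (stored in `node.label`).
#'
#' @inheritParams pairwise_distance
#' @param n_reps number of bootstrap replicates (>= 1)
#' @param seed integer seed
#' @return the reference tree with supports in `node.label`
#' @export
bootstrap_support <- function(ab, model = "poisson", alpha = 1,
                              n_reps = 100L, seed = 1L, cap = 5) {
  if (ncol(ab) < 1) stop("empty alignment")
  stopifnot(n_reps >= 1)
  ref <- neighbor_joining(pairwise_distance(ab, model, alpha, cap))
  pc <- pair_comparison(ab)
  L <- ncol(ab)
  counts <- new.env(parent = emptyenv())
  with_substream(seed, "bootstrap", {
    W <- matrix(0, L, n_reps)
    for (b in seq_len(n_reps))
      W[, b] <- tabulate(sample.int(L, L, replace = TRUE), L)
    MM <- pc$mismatch %*% W
    VV <- pc$valid %*% W
    n <- length(pc$labels)
    for (b in seq_len(n_reps)) {
      vv <- VV[, b]
      p <- ifelse(vv > 0, MM[, b] / pmax(vv, 1), 1)
      d <- suppressWarnings(correct_distance(p, model, alpha, cap))
      D <- matrix(0, n, n, dimnames = list(pc$labels, pc$labels))
      D[pc$pairs] <- d
      D[pc$pairs[, c(2, 1), drop = FALSE]] <- d
      tr <- neighbor_joining(D)
      for (k in bipartition_keys(tr))
        assign(k, (counts[[k]] %||% 0) + 1, envir = counts)
    }
  })
  # attach supports to the reference tree's internal nodes
  nt <- ape::Ntip(ref)
  tips <- sort(ref$tip.label)
  lab <- rep("", ref$Nnode)
  for (node in (nt + 1):(nt + ref$Nnode)) {
    side <- sort(tips_below(ref, node))
    if (length(side) <= 1 || length(side) >= nt - 1) next
    if (tips[1] %in% side) side <- setdiff(tips, side)
    k <- paste(side, collapse = "|")
    lab[node - nt] <- format(round(100 * (counts[[k]] %||% 0) / n_reps, 1))
  }
  ref$node.label <- lab
  attr(ref, "n_reps") <- n_reps
  ref
}

#' Root a gene tree for clade-based interpretation
#'
#' Roots on the outgroup clade when its leaves are monophyletic in the
#' unrooted tree, otherwise falls back to midpoint rooting (appropriate
#' for clock-like simulated data).  `edgelabel = TRUE` keeps bootstrap
#' labels attached to the correct edges through rerooting.
#'
#' @param tree unrooted `phylo` (supports in `node.label` allowed)
#' @param leaf_clades named vector: leaf -> top-level clade
#' @param outgroup_clade clade label to root on, or `NULL`
#' @return a rooted tree
#' @export
root_gene_tree <- function(tree, leaf_clades, outgroup_clade = NULL) {
  if (!is.null(outgroup_clade)) {
    og <- names(leaf_clades)[leaf_clades == outgroup_clade]
    og <- intersect(og, tree$tip.label)
    if (length(og) && length(og) < ape::Ntip(tree) &&
        ape::is.monophyletic(tree, og)) {
      return(ape::root(tree, outgroup = og, resolve.root = TRUE,
                       edgelabel = TRUE))
    }
  }
  phangorn::midpoint(tree)
}

#' Taxon-displacement test for horizontal transfer
#'
#' A leaf is displaced iff its smallest enclosing gene-tree clade with at
#' least 3 leaves and support >= `support_min` consists otherwise entirely
#' of leaves from top-level clades different from the leaf's own.  When
#' those foreign leaves come from a single clade it is reported as the
#' observed (source) clade; when they are mixed -- e.g. several transfers
#' landed in the same gene-tree neighbourhood -- the displacement is still
#' called but its source is `"unresolved"`.  Missing/blank supports are
#' treated as certain (100), and the root as certain.
#'
#' @param gene_tree rooted `phylo` with bootstrap supports in `node.label`
#' @param leaf_clades named vector: leaf -> top-level clade (every leaf
#'   must be mapped)
#' @param support_min support threshold (percentage)
#' @return data.frame `leaf`, `expected_clade`, `observed_clade`,
#'   `support`; zero rows when nothing is displaced
#' @export
displacement_test <- function(gene_tree, leaf_clades, support_min = 70) {
  unmapped <- setdiff(gene_tree$tip.label, names(leaf_clades))
  if (length(unmapped))
    stop("unmapped leaf/leaves: ", paste(unmapped, collapse = ", "))
  nt <- ape::Ntip(gene_tree)
  lab <- gene_tree$node.label
  support_of <- function(node) {
    if (node == nt + 1L) return(100)           # root
    if (is.null(lab)) return(100)
    s <- suppressWarnings(as.numeric(lab[node - nt]))
    if (is.na(s)) 100 else s
  }
  out <- list()
  for (leaf in seq_len(nt)) {
    node <- leaf
    repeat {
      node <- gene_tree$edge[gene_tree$edge[, 2] == node, 1]
      if (!length(node)) break
      members <- tips_below(gene_tree, node)
      if (length(members) >= 3 && support_of(node) >= support_min) break
    }
    if (!length(node)) next
    members <- tips_below(gene_tree, node)
    others <- setdiff(members, gene_tree$tip.label[leaf])
    oc <- unique(leaf_clades[others])
    own <- leaf_clades[[gene_tree$tip.label[leaf]]]
    if (length(oc) >= 1 && !own %in% oc) {
      out[[length(out) + 1L]] <- data.frame(
        leaf = gene_tree$tip.label[leaf], expected_clade = own,
        observed_clade = if (length(oc) == 1) unname(oc) else "unresolved",
        support = support_of(node),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(leaf = character(), expected_clade = character(),
                      observed_clade = character(), support = numeric()))
  do.call(rbind, out)
}
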
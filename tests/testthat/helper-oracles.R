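# Independent oracles used by the unit and acceptance tests.  These are
# deliberately written as brute-force enumerations, separate from the
# implementations they check.

# Brute-force local alignment score: enumerates every local alignment as
# an increasing sequence of aligned residue pairs with affine-priced gap
# runs between consecutive pairs (terminal gaps never help, so optimal
# local alignments start and end with an aligned pair).  Exponential --
# only for short sequences.
oracle_sw <- function(a, b, smat, gap_open, gap_extend) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  gapcost <- function(k) if (k == 0) 0 else gap_open + k * gap_extend
  best <- 0
  g <- function(i, j, s) {
    best <<- max(best, s)
    if (i < n && j < m) {
      for (di in seq_len(n - i)) for (dj in seq_len(m - j)) {
        g(i + di, j + dj,
          s + gapcost(di - 1L) + gapcost(dj - 1L) +
            smat[ca[i + di], cb[j + dj]])
      }
    }
  }
  for (i in seq_len(n)) for (j in seq_len(m))
    g(i, j, smat[ca[i], cb[j]])
  best
}

# Exhaustive single-gain (Dollo) minimisation: tries every gain node and
# every presence assignment to the internal nodes, keeping assignments
# with no secondary gain, and returns the minimal loss count.
oracle_dollo_losses <- function(presence, tree) {
  tree <- glidevol::label_nodes(tree)
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  tipstate <- integer(nt)
  for (i in seq_len(nt)) {
    p <- presence[tree$tip.label[i]]
    tipstate[i] <- if (!is.na(p) && p >= 1) 1L else 0L
  }
  if (!any(tipstate == 1)) stop("all-absent profile")
  parent_of <- integer(nn)
  for (e in seq_len(nrow(tree$edge)))
    parent_of[tree$edge[e, 2]] <- tree$edge[e, 1]
  root <- nt + 1L
  internals <- (nt + 1L):nn
  best <- Inf
  for (assign_bits in 0:(2^length(internals) - 1L)) {
    state <- integer(nn)
    state[seq_len(nt)] <- tipstate
    bits <- assign_bits
    for (k in seq_along(internals)) {
      state[internals[k]] <- bits %% 2L
      bits <- bits %/% 2L
    }
    # count gains (0 -> 1 down an edge, or presence at the root) and
    # losses (1 -> 0); valid single-gain histories have exactly one gain
    gains <- if (state[root] == 1L) 1L else 0L
    losses <- 0L
    ok <- TRUE
    for (e in seq_len(nrow(tree$edge))) {
      ps <- state[tree$edge[e, 1]]; cs <- state[tree$edge[e, 2]]
      if (ps == 0L && cs == 1L) gains <- gains + 1L
      if (ps == 1L && cs == 0L) losses <- losses + 1L
    }
    if (ok && gains == 1L) best <- min(best, losses)
  }
  best
}

# Brute-force connected components of the hit adjacency graph
# (|delta index| - 1 <= max_gap), used against detect_clusters.
oracle_components <- function(idx, max_gap) {
  n <- length(idx)
  adj <- abs(outer(idx, idx, `-`)) - 1 <= max_gap
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] > comp[i]) { comp[j] <- comp[i]; changed <- TRUE }
      if (adj[i, j] && comp[i] > comp[j]) { comp[i] <- comp[j]; changed <- TRUE }
    }
    if (!changed) break
  }
  # canonical: sorted sizes of components
  sort(table(comp), decreasing = TRUE)
}

# small simulated dataset used across tests (kept light)
small_sim_config <- function(seed = 1L, ...) {
  glidevol::sim_config(
    n_taxa = 12L, n_clades = 4L, clade_sizes = c(4L, 3L, 3L, 2L),
    seq_length = 400L, n_background = 30L, seed = seed, ...)
}

small_run_config <- function(...) {
  glidevol::default_config(n_bootstrap = 30L, ...)
}

# keep pipeline progress logging out of the test output
glidevol::set_quiet(TRUE)
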
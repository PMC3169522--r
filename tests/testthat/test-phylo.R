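test_that("column masking drops exactly the gappy columns", {
  m <- rbind(a = c("M", "-", "K", "-"),
             b = c("M", "-", "K", "V"),
             c = c("M", "X", "R", "V"))
  ab <- alignment_block(m)
  masked <- mask_columns(ab, 0.5)
  expect_equal(ncol(masked), 3)        # column 2 is 2/3 gaps
  expect_equal(attr(masked, "kept"), 3)
  gapless <- alignment_block(m[, c(1, 3)])
  expect_equal(ncol(mask_columns(gapless, 0)), 2)
  set.seed(4)
  for (rep in 1:10) {
    mm <- matrix(sample(c(AA_ALPHABET20, "-"), 200, TRUE,
                        prob = c(rep(1, 20), 8)), 4,
                 dimnames = list(letters[1:4], NULL))
    frac <- colMeans(mm == "-")
    keep <- frac <= 0.25
    expect_equal(ncol(mask_columns(alignment_block(mm), 0.25)), sum(keep))
  }
  expect_error(mask_columns(alignment_block(m[, 0, drop = FALSE])), "empty")
})

test_that("pairwise distances invert the simulator's substitution model", {
  m <- rbind(a = c("M", "K", "V"), b = c("M", "K", "V"))
  D <- pairwise_distance(alignment_block(m), "poisson")
  expect_equal(D["a", "b"], 0)
  expect_equal(pairwise_distance(alignment_block(m), "p")["a", "b"], 0)
  expect_equal(pairwise_distance(alignment_block(m), "gamma",
                                 alpha = 0.5)["a", "b"], 0)
  # p = observed mismatch fraction under pairwise deletion
  m2 <- rbind(a = c("M", "K", "V", "A"), b = c("M", "-", "R", "A"))
  expect_equal(pairwise_distance(alignment_block(m2), "p")["a", "b"], 1 / 3)
  # saturated pairs are capped with a warning
  m3 <- rbind(a = AA_ALPHABET20[1:10], b = AA_ALPHABET20[c(2:10, 1)])
  expect_warning(D3 <- pairwise_distance(alignment_block(m3), "poisson",
                                         cap = 5), "saturated")
  expect_equal(D3["a", "b"], 5)
  # zero shared columns is an error
  m4 <- rbind(a = c("M", "-"), b = c("-", "K"))
  expect_error(pairwise_distance(alignment_block(m4)), "shared")
})

test_that("neighbour joining solves the three-taxon case exactly", {
  D <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 1, 2))
  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")
  D2 <- D; D2[1, 2] <- 5
  expect_error(neighbor_joining(D2), "asymmetric")
})

test_that("NJ recovers generating topologies from additive distances", {
  set.seed(10)
  for (rep in 1:15) {
    n <- sample(6:10, 1)
    t0 <- ape::rtree(n)
    t0$edge.length <- runif(nrow(t0$edge), 0.1, 1)
    D <- ape::cophenetic.phylo(t0)
    tnj <- neighbor_joining(D)
    expect_equal(robinson_foulds(tnj, t0), 0)
    # cross-check against the reference NJ implementation
    expect_equal(robinson_foulds(tnj, ape::nj(as.dist(D))), 0)
  }
})

test_that("NJ ties break towards the lexicographically smallest pair", {
  # four equidistant taxa: all Q values tie
  D <- matrix(2, 4, 4, dimnames = list(c("d", "c", "b", "a"),
                                       c("d", "c", "b", "a")))
  diag(D) <- 0
  tr <- neighbor_joining(D)
  # a and b must be joined first, hence they form a cherry
  cherries <- ape::prop.part(ape::unroot(tr))
  sets <- lapply(cherries, function(p) sort(attr(cherries, "labels")[p]))
  expect_true(list(c("a", "b")) %in% sets ||
                any(vapply(sets, function(s) identical(s, c("a", "b")),
                           logical(1))))
})

test_that("Robinson-Foulds distance counts bipartition differences", {
  t1 <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  expect_equal(robinson_foulds(t1, t1), 0)
  # one nearest-neighbour interchange on five leaves changes one split
  t2 <- ape::read.tree(text = "((A,B),(D,(C,E)));")
  expect_equal(robinson_foulds(t1, t2), 2)
  set.seed(12)
  for (rep in 1:10) {
    n <- sample(5:10, 1)
    a <- ape::rtree(n); b <- ape::rtree(n)
    b$tip.label <- sample(a$tip.label)
    c <- ape::rtree(n); c$tip.label <- sample(a$tip.label)
    rf <- robinson_foulds(a, b)
    expect_equal(rf, phangorn::RF.dist(ape::unroot(a), ape::unroot(b)))
    expect_lte(rf, 2 * (n - 3))                    # bipartition bound
    expect_equal(rf, robinson_foulds(b, a))        # symmetry
    expect_lte(robinson_foulds(a, c),
               rf + robinson_foulds(b, c))         # triangle inequality
  }
  expect_error(robinson_foulds(t1, ape::read.tree(text = "((A,B),C);")),
               "differ")
})

test_that("bootstrap supports are deterministic, bounded and permutation-invariant", {
  sp <- simulate_species_tree(6, 4)
  h <- with_substream(3, "bs", sim_family_history(sp, node_names(sp)[7]))
  ab <- evolve_sequences(h$gene_tree, 600, 0.3, seed = 5)
  b1 <- bootstrap_support(ab, n_reps = 25, seed = 7)
  b2 <- bootstrap_support(ab, n_reps = 25, seed = 7)
  expect_identical(ape::write.tree(b1), ape::write.tree(b2))
  # single replicate: supports are 0 or 100
  b3 <- bootstrap_support(ab, n_reps = 1, seed = 2)
  sup <- suppressWarnings(as.numeric(b3$node.label))
  expect_true(all(sup[!is.na(sup)] %in% c(0, 100)))
  # permuting the row order leaves per-bipartition supports unchanged
  abp <- alignment_block(unclass(ab)[rev(seq_len(nrow(ab))), ])
  b4 <- bootstrap_support(abp, n_reps = 25, seed = 7)
  key_sup <- function(tr) {
    nt <- ape::Ntip(tr)
    out <- c()
    for (node in (nt + 2):(nt + tr$Nnode)) {
      tips <- sort(glidevol:::tips_below(tr, node))
      out[paste(tips, collapse = "|")] <- tr$node.label[node - nt]
    }
    out
  }
  k1 <- key_sup(b1); k4 <- key_sup(b4)
  shared <- intersect(names(k1), names(k4))
  expect_gt(length(shared), 0)
  expect_identical(k1[shared], k4[shared])
})

test_that("displacement flags transferred leaves and respects thresholds", {
  # congruent tree: nothing displaced
  gt <- ape::read.tree(text = "(((a1,a2),a3),((b1,b2),b3));")
  cl <- c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B", b3 = "B")
  expect_equal(nrow(displacement_test(gt, cl, 50)), 0)
  # one taxon nested inside the other clade
  gt2 <- ape::read.tree(text = "((a1,(a2,a3)),((b1,x1),(b2,b3)));")
  cl2 <- c(cl[c("a1", "a2", "a3", "b1", "b2", "b3")], x1 = "A")
  d <- displacement_test(gt2, cl2, 50)
  expect_equal(d$leaf, "x1")
  expect_equal(d$observed_clade, "B")
  # vacuous support threshold: nothing can pass
  expect_equal(nrow(displacement_test(gt2, cl2, 101)), 0)
  expect_error(displacement_test(gt2, cl2[-7], 50), "unmapped")
  # mixed foreign neighbourhood: displaced with unresolved source
  gt3 <- ape::read.tree(text = "(((x1,b1),c1),(a1,(a2,a3)));")
  cl3 <- c(x1 = "A", b1 = "B", c1 = "C", a1 = "A", a2 = "A", a3 = "A")
  d3 <- displacement_test(gt3, cl3, 50)
  expect_true("x1" %in% d3$leaf)
  expect_equal(d3$observed_clade[d3$leaf == "x1"], "unresolved")
})

test_that("displacement recovers a simulated cross-clade transfer", {
  found <- 0; total <- 0
  for (s in 1:5) {
    sim <- simulate_dataset(small_sim_config(seed = 40 + s))
    tru <- sim$events[sim$events$type == "transfer", ]
    et <- edge_table(sim$tree)
    tru <- tru[et$is_tip[match(tru$branch, et$branch)] &
                 !(tru$parent_copy_id %in% tru$copy_id), , drop = FALSE]
    if (!nrow(tru)) next
    run <- run_pipeline(sim, small_run_config())
    inf <- run$events[run$events$type == "transfer", ]
    inf$fam <- run$recovery$family_map[inf$family_id]
    for (k in seq_len(nrow(tru))) {
      total <- total + 1
      found <- found +
        (tru$branch[k] %in% inf$branch[!is.na(inf$fam) &
                                       inf$fam == tru$family_id[k]])
    }
  }
  expect_gt(total, 0)
  expect_gte(found / total, 0.6)
})
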
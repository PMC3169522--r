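test_that("species trees are ultrametric, depth-1 and seed-deterministic", {
  tr <- simulate_species_tree(3, 9)
  expect_equal(ape::Ntip(tr), 3)
  expect_equal(tr$Nnode, 2)
  tt <- node_times(tr)
  expect_true(all(abs(tt[1:3] - 1) < 1e-9))
  expect_identical(ape::write.tree(simulate_species_tree(7, 5)),
                   ape::write.tree(simulate_species_tree(7, 5)))
  expect_error(simulate_species_tree(2, 1), "n_taxa")
  ct <- simulate_clade_tree(15, 4, seed = 2)
  expect_true(all(abs(node_times(ct)[1:15] - 1) < 1e-9))
})

test_that("zero-rate gene content yields one copy below the origin", {
  tr <- simulate_clade_tree(8, 3, seed = 3)
  nm <- node_names(tr)
  h <- with_substream(1, "t", sim_family_history(tr, nm[9]))  # root
  expect_equal(nrow(h$tips), 8)
  expect_true(all(table(h$tips$genome) == 1))
  # origin on an internal branch: present only below it
  et <- edge_table(tr)
  internal <- et$branch[!et$is_tip][1]
  h2 <- with_substream(1, "t", sim_family_history(tr, internal))
  below <- tips_below(tr, node_of_branch(tr, internal))
  expect_setequal(unique(h2$tips$genome), below)
  expect_error(sim_family_history(tr, "nonsense"), "origin")
})

test_that("vertical gene trees are congruent with the species tree", {
  for (seed in 1:3) {
    tr <- simulate_species_tree(7, seed)
    h <- with_substream(seed, "congr",
                        sim_family_history(tr, node_names(tr)[8]))
    g <- h$gene_tree
    g$tip.label <- sub("\\|.*", "", g$tip.label)
    expect_equal(robinson_foulds(g, tr), 0)
  }
})

test_that("event-log replay reproduces tip copy counts exactly", {
  tr <- simulate_clade_tree(10, 3, seed = 4)
  cl <- top_clades(tr, 0.14)
  params <- list(
    Fa = list(origin_branch = node_names(tr)[11], dup_rate = 0.3,
              loss_rate = 0.2, transfer_rate = 0.3),
    Fb = list(origin_branch = node_names(tr)[11], dup_rate = 0.1,
              loss_rate = 0.1, transfer_rate = 0.2,
              forced_dup_branches = node_names(tr)[12]))
  for (seed in c(2, 5, 8)) {
    ec <- evolve_gene_content(tr, params, seed,
                              transfer_recipients = "cross_clade",
                              clades = cl)
    expect_equal(replay_event_log(tr, ec$events)[rownames(ec$counts), ,
                                                 drop = FALSE],
                 ec$counts)
  }
})

test_that("transfer counts grow with the transfer rate", {
  tr <- simulate_clade_tree(10, 3, seed = 6)
  cl <- top_clades(tr, 0.14)
  mean_transfers <- sapply(c(0.05, 0.2, 0.8), function(tau) {
    n <- 0
    for (s in 1:40) {
      ec <- evolve_gene_content(
        tr, list(F1 = list(origin_branch = node_names(tr)[11],
                           dup_rate = 0, loss_rate = 0,
                           transfer_rate = tau)),
        seed = 1000 * tau + s, transfer_recipients = "uniform",
        clades = cl)
      n <- n + sum(ec$events$type == "transfer")
    }
    n / 40
  })
  expect_true(all(diff(mean_transfers) > 0))
})

test_that("sequence evolution matches the uniform 20-state closed form", {
  gt <- ape::read.tree(text = "(a:0.15,b:0.15);")
  ab <- evolve_sequences(gt, 10000, 1, seed = 2)
  p_obs <- mean(unclass(ab)["a", ] != unclass(ab)["b", ])
  d <- 0.3
  p_exp <- (19 / 20) * (1 - exp(-(20 / 19) * d))
  se <- sqrt(p_exp * (1 - p_exp) / 10000)
  expect_lt(abs(p_obs - p_exp), 3 * se)
  # zero rate: all rows identical; same seed: identical alignment
  ab0 <- evolve_sequences(gt, 50, 0, seed = 1)
  expect_identical(unclass(ab0)["a", ], unclass(ab0)["b", ])
  expect_identical(evolve_sequences(gt, 100, 0.5, seed = 9),
                   evolve_sequences(gt, 100, 0.5, seed = 9))
  expect_error(evolve_sequences(gt, 0, 1, seed = 1), "seq_length")
})

test_that("genome assembly honours linkage and keeps indices contiguous", {
  tips <- list(
    F1 = data.frame(genome = c("g1", "g2"), copy_id = "c1"),
    F2 = data.frame(genome = c("g1", "g2"), copy_id = "c1"),
    F3 = data.frame(genome = c("g1", "g2"), copy_id = "c1"))
  cp <- c(g1 = "Bacteria/C1", g2 = "Bacteria/C2")
  gt <- assemble_genomes(tips, list(m = c("F1", "F2", "F3")), cp,
                         p_linkage = 1, n_background = 20, seed = 3)
  for (g in c("g1", "g2")) {
    loci <- gt[gt$genome_id == g, ]
    expect_equal(loci$ordinal_index, 0:(nrow(loci) - 1))
    fam_idx <- sort(loci$ordinal_index[!is.na(loci$family_id)])
    expect_equal(diff(fam_idx), c(1L, 1L))  # one contiguous block
  }
  # a genome with no copies contains only filler loci
  tips0 <- list(F1 = data.frame(genome = "g1", copy_id = "c1"))
  gt0 <- assemble_genomes(tips0, list(m = "F1"), cp, p_linkage = 1,
                          n_background = 5, seed = 1)
  expect_true(all(is.na(gt0$family_id[gt0$genome_id == "g2"])))
  expect_equal(sum(gt0$genome_id == "g2"), 5)
})

test_that("scattered placement shows no block enrichment", {
  # under p_linkage = 0 the three module loci should sit adjacently no
  # more often than uniform placement predicts
  tips <- list(
    F1 = data.frame(genome = "g1", copy_id = "c1"),
    F2 = data.frame(genome = "g1", copy_id = "c1"),
    F3 = data.frame(genome = "g1", copy_id = "c1"))
  cp <- c(g1 = "Bacteria/C1")
  n_adj <- 0
  reps <- 120
  for (s in seq_len(reps)) {
    gt <- assemble_genomes(tips, list(m = c("F1", "F2", "F3")), cp,
                           p_linkage = 0, n_background = 60, seed = s)
    idx <- sort(gt$ordinal_index[!is.na(gt$family_id)])
    if (max(idx) - min(idx) == 2) n_adj <- n_adj + 1
  }
  # P(3 marked positions contiguous among 63) = 61 / choose(63, 3)
  p0 <- 61 / choose(63, 3)
  expect_lt(n_adj, qbinom(0.995, reps, p0) + 1)
})

test_that("feature annotation copies templates and respects flip noise", {
  gt <- as_gene_table(data.frame(
    genome_id = "g", locus_tag = sprintf("g_%05d", 1:10000),
    ordinal_index = 0:9999, strand = "+", clade_path = "B/C",
    family_id = "F1", copy_id = "c1"))
  tpl <- list(F1 = list(signal_peptide = TRUE, lipoprotein_signal = FALSE,
                        tm_count = 1L, interaction_motif = FALSE,
                        domain_names = "TPR"))
  f0 <- annotate_features(gt, tpl, flip_noise = 0, seed = 1)
  expect_true(all(f0$signal_peptide))
  expect_true(all(f0$tm_count == 1L))
  f1 <- annotate_features(gt, tpl, flip_noise = 0.1, seed = 2)
  flipped <- mean(!f1$signal_peptide)
  se <- sqrt(0.1 * 0.9 / 10000)
  expect_lt(abs(flipped - 0.1), 3 * se)
  expect_true(all(f1$tm_count >= 0L))
  expect_error(annotate_features(gt, tpl, flip_noise = 0.5, seed = 1),
               "flip_noise")
})

test_that("simulated datasets are reproducible and self-consistent", {
  cfg <- small_sim_config(seed = 4)
  sim1 <- simulate_dataset(cfg)
  sim2 <- simulate_dataset(cfg)
  expect_identical(ape::write.tree(sim1$tree), ape::write.tree(sim2$tree))
  expect_identical(sim1$events, sim2$events)
  expect_identical(sim1$proteome, sim2$proteome)
  # every machinery locus has a sequence of its family's length
  expect_true(all(nchar(sim1$proteome[sim1$locus_map$locus_tag]) ==
                    cfg$seq_length))
  # the focal genome carries every family (the conditioning target)
  expect_true(all(sim1$counts[, sim1$focal_genome] >= 1))
  # copy counts agree between the truth matrix and the gene table
  tab <- table(sim1$genomes$family_id, sim1$genomes$genome_id)
  for (f in rownames(sim1$counts))
    expect_equal(unname(tab[f, colnames(sim1$counts)]),
                 unname(sim1$counts[f, ]))
})

test_that("dataset export writes readable pipeline inputs", {
  sim <- simulate_dataset(small_sim_config(seed = 6))
  d <- tempfile()
  write_dataset(sim, d)
  gt <- read_gene_table(file.path(d, "gene_table.tsv"))
  expect_equal(nrow(gt), nrow(sim$genomes))
  ft <- read_feature_table(file.path(d, "features.tsv"))
  expect_equal(nrow(ft), nrow(sim$features))
  tr <- read_newick(file.path(d, "species_tree.nwk"))
  expect_equal(robinson_foulds(tr, sim$tree), 0)
  fg <- read_fasta(file.path(d, paste0(sim$focal_genome, ".faa")))
  expect_equal(length(fg), sum(gt$genome_id == sim$focal_genome))
})
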
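test_that("self-alignment scores 1 and scoring is symmetric", {
  sch <- scoring_scheme()
  s <- local_align_score("MKVLARNDCEQ", "MKVLARNDCEQ", sch)
  expect_equal(unname(s["normalized"]), 1)
  set.seed(2)
  for (rep in 1:10) {
    a <- paste(sample(AA_ALPHABET20, 30, TRUE), collapse = "")
    b <- paste(sample(AA_ALPHABET20, 25, TRUE), collapse = "")
    expect_equal(local_align_score(a, b, sch), local_align_score(b, a, sch))
  }
  expect_error(local_align_score("", "MKV", sch), "empty")
  expect_error(local_align_score("MKB", "MKV", sch), "B")
})

test_that("alignment scores match the brute-force path enumeration", {
  sch <- scoring_scheme()
  set.seed(5)
  sub <- c("A", "R", "N", "D")
  for (rep in 1:40) {
    a <- paste(sample(sub, sample(1:5, 1), TRUE), collapse = "")
    b <- paste(sample(sub, sample(1:5, 1), TRUE), collapse = "")
    expect_equal(unname(local_align_score(a, b, sch)["raw"]),
                 oracle_sw(a, b, sch$matrix, sch$gap_open, sch$gap_extend),
                 info = paste(a, b))
  }
})

test_that("unrelated random sequences score below the family threshold", {
  sch <- scoring_scheme()
  set.seed(9)
  norms <- replicate(100, {
    a <- paste(sample(AA_ALPHABET20, 200, TRUE), collapse = "")
    b <- paste(sample(AA_ALPHABET20, 200, TRUE), collapse = "")
    unname(local_align_score(a, b, sch)["normalized"])
  })
  expect_gte(mean(norms < 0.3), 0.95)
})

test_that("homologue expansion recovers simulated families exactly", {
  sim <- simulate_dataset(small_sim_config(seed = 2))
  truth <- split(sim$locus_map$locus_tag, sim$locus_map$family_id)
  for (f in c("F01", "A1")) {
    seed_locus <- sort(truth[[f]][startsWith(truth[[f]],
                                             sim$focal_genome)])[1]
    fam <- find_homologues(seed_locus, sim$proteome,
                           max_reps = Inf, kmer_prefilter = 0)
    expect_setequal(fam$members$locus_tag, truth[[f]])
  }
})

test_that("no cross-contamination between diverged families", {
  for (s in 1:3) {
    sim <- simulate_dataset(small_sim_config(seed = 20 + s))
    truth <- split(sim$locus_map$locus_tag, sim$locus_map$family_id)
    seed_locus <- sort(truth$F02[startsWith(truth$F02,
                                            sim$focal_genome)])[1]
    fam <- find_homologues(seed_locus, sim$proteome)
    other <- unlist(truth[setdiff(names(truth), "F02")])
    expect_length(intersect(fam$members$locus_tag, other), 0)
  }
})

test_that("expansion contracts: threshold 1 keeps seeds; lower never shrinks", {
  prot <- c(s1 = "MKVLARND", s2 = "MKVLARNE", s3 = "WWWWYYYY",
            s4 = "CCCCHHHH")
  f1 <- find_homologues("s1", prot, threshold = 1, max_reps = Inf,
                        kmer_prefilter = 0)
  expect_equal(f1$members$locus_tag, "s1")
  expect_error(find_homologues(character(), prot), "empty seed")
  fams <- lapply(c(0.9, 0.5, 0.2, 0.05), function(th)
    find_homologues("s1", prot, threshold = th, max_reps = Inf,
                    kmer_prefilter = 0)$members$locus_tag)
  for (k in seq_len(length(fams) - 1))
    expect_true(all(fams[[k]] %in% fams[[k + 1]]))
})

test_that("phyletic profiles count copies and conserve totals", {
  gt <- as_gene_table(data.frame(
    genome_id = rep(c("g1", "g2"), c(3, 2)),
    locus_tag = sprintf("l%d", 1:5), ordinal_index = c(0:2, 0:1),
    strand = "+", clade_path = rep(c("B/C1", "B/C2"), c(3, 2))))
  fam <- structure(list(family_id = "F", seeds = "l1",
                        members = data.frame(locus_tag = c("l1", "l2", "l4"),
                                             norm_score = 1)),
                   class = "homology_family")
  prof <- build_profile(list(fam), gt)
  expect_equal(unname(prof["F", c("g1", "g2")]), c(2L, 1L))
  expect_equal(sum(prof), nrow(fam$members))
  fam$members <- rbind(fam$members,
                       data.frame(locus_tag = "zzz", norm_score = 1))
  expect_error(build_profile(list(fam), gt), "zzz")
})

test_that("taxonomic-breadth classification separates the two groups", {
  fx <- gliding_fixture()
  grp <- classify_profile(fx$profile, fx$focal_clades)
  expect_equal(sum(grp == "GroupA"), 7)
  expect_equal(sum(grp == "GroupB"), 7)
  # clade-restricted rows are Group A, broad rows Group B
  expect_equal(unname(grp["gltF"]), "GroupA")
  expect_equal(unname(grp["gltD"]), "GroupB")
  expect_equal(classify_distribution(c(a = 0, b = 0),
                                     c(a = "B/X", b = "B/Y"), "X"),
               "absent")
  expect_error(classify_distribution(c(a = 1), c(a = "B/X"), character()),
               "focal")
})
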
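mk_membership <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(locus_tag = r[1], family_id = r[2], genome_id = r[3],
               ordinal_index = as.integer(r[4]), stringsAsFactors = FALSE)))
}

test_that("congruent co-located families group; never co-located stay apart", {
  sp <- simulate_species_tree(6, 2)
  mk_gt <- function(fam) {
    g <- sp
    g$tip.label <- paste0(g$tip.label, "_", fam)
    g
  }
  trees <- list(Fa = mk_gt("Fa"), Fb = mk_gt("Fb"), Fc = mk_gt("Fc"))
  mem <- do.call(rbind, lapply(names(trees), function(f)
    data.frame(locus_tag = paste0(sp$tip.label, "_", f), family_id = f,
               genome_id = sp$tip.label,
               ordinal_index = seq_along(sp$tip.label),
               stringsAsFactors = FALSE)))
  coloc <- data.frame(family_a = "Fa", family_b = "Fb")
  grp <- congruence_groups(trees, mem, coloc, rf_max = 0,
                           min_shared_taxa = 4)
  sets <- lapply(grp, sort)
  expect_true(any(vapply(sets, function(s) identical(s, c("Fa", "Fb")),
                         logical(1))))
  expect_true(any(vapply(sets, function(s) identical(s, "Fc"),
                         logical(1))))
  # a family without a tree is an error
  trees2 <- trees; trees2["Fc"] <- list(NULL)
  expect_error(congruence_groups(trees2, mem, coloc), "without a gene tree")
})

test_that("co-location pairs come from detected clusters", {
  mem <- mk_membership(c("l1", "Fa", "g1", 10), c("l2", "Fb", "g1", 11),
                       c("l3", "Fc", "g1", 50),
                       c("l4", "Fa", "g2", 5), c("l5", "Fc", "g2", 90))
  cp <- colocated_pairs(mem, max_gap = 3)
  expect_equal(nrow(cp), 1)
  expect_setequal(unlist(cp[1, ]), c("Fa", "Fb"))
})

test_that("paralogue linking builds one tuple per complete cluster", {
  # two linked motor-cluster copies, as in the duplicated aglQRS regions
  mem <- mk_membership(
    c("m6860", "aglS", "g", 6860), c("m6861", "aglQ", "g", 6861),
    c("m6862", "aglR", "g", 6862),
    c("m3003", "aglR", "g", 3003), c("m3004", "aglQ", "g", 3004),
    c("m3005", "aglS", "g", 3005))
  lp <- link_paralogues(mem, c("aglQ", "aglR", "aglS"), max_gap = 3)
  expect_length(lp$tuples, 2)
  tags <- lapply(lp$tuples, function(tp) sort(unname(tp)))
  expect_true(any(vapply(tags, function(x)
    identical(x, c("m6860", "m6861", "m6862")), logical(1))))
  expect_true(any(vapply(tags, function(x)
    identical(x, c("m3003", "m3004", "m3005")), logical(1))))
  expect_equal(nrow(lp$unassigned), 0)
  # single-copy genome: one tuple
  lp1 <- link_paralogues(mem[1:3, ], c("aglQ", "aglR", "aglS"), 3)
  expect_length(lp1$tuples, 1)
  # an orphan copy of one family only: no tuple, one unassigned report
  lp0 <- link_paralogues(mem[1, , drop = FALSE],
                         c("aglQ", "aglR", "aglS"), 3)
  expect_length(lp0$tuples, 0)
  expect_equal(nrow(lp0$unassigned), 1)
})

test_that("concatenation tiles partitions and preserves shapes", {
  set.seed(6)
  widths <- c(Fa = 200L, Fb = 186L, Fc = 200L)
  genomes <- sprintf("g%02d", 1:39)
  alns <- lapply(names(widths), function(f) {
    m <- matrix(sample(AA_ALPHABET20, 39 * widths[[f]], TRUE), 39,
                dimnames = list(paste0(genomes, "_", f), NULL))
    alignment_block(m)
  })
  names(alns) <- names(widths)
  tuples <- setNames(lapply(genomes, function(g)
    setNames(paste0(g, "_", names(widths)), names(widths))), genomes)
  sm <- concatenate_alignments(tuples, alns)
  expect_equal(sm$n_sequences, 39)
  expect_equal(sm$n_positions, 586)
  expect_equal(sm$partitions$end - sm$partitions$start,
               unname(widths[sm$partitions$family_id]))
  expect_equal(sm$partitions$start[1], 0)
  expect_equal(sm$partitions$end[nrow(sm$partitions)], sm$n_positions)
  # losslessness: each family block comes back out exactly
  for (f in names(widths)) {
    back <- deconcatenate(sm, f)
    orig <- unclass(alns[[f]])[paste0(genomes, "_", f), , drop = FALSE]
    expect_equal(unname(unclass(back)), unname(orig))
  }
  # one family only: the supermatrix equals that alignment
  sm1 <- concatenate_alignments(lapply(tuples, `[`, "Fa"), alns["Fa"])
  expect_equal(sm1$n_positions, 200)
  expect_equal(unname(unclass(sm1$alignment)),
               unname(unclass(alns$Fa)))
})

test_that("random simulated groups conserve total width", {
  set.seed(8)
  for (rep in 1:5) {
    k <- sample(2:4, 1)
    widths <- sample(50:150, k)
    fams <- paste0("F", seq_len(k))
    alns <- setNames(lapply(widths, function(w)
      alignment_block(matrix(sample(AA_ALPHABET20, 3 * w, TRUE), 3,
                             dimnames = list(paste0("r", 1:3), NULL)))),
      fams)
    tuples <- list(t1 = setNames(rep("r1", k), fams),
                   t2 = setNames(rep("r2", k), fams))
    sm <- concatenate_alignments(tuples, alns)
    expect_equal(sm$n_positions, sum(widths))
  }
})

test_that("supermatrix files round trip through PHYLIP plus partitions", {
  alns <- list(Fa = alignment_block(matrix(
    sample(AA_ALPHABET20, 4 * 30, TRUE), 4,
    dimnames = list(paste0("g", 1:4), NULL))))
  tuples <- setNames(lapply(paste0("g", 1:4), function(g)
    c(Fa = g)), paste0("g", 1:4))
  sm <- concatenate_alignments(tuples, alns)
  fp <- tempfile(); fpart <- tempfile()
  write_supermatrix(sm, fp, fpart)
  lines <- readLines(fp)
  expect_equal(strsplit(lines[1], " ")[[1]], c("4", "30"))
  parts <- read.delim(fpart)
  expect_equal(parts$end - parts$start, 30)
})
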
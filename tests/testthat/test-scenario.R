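test_that("Dollo places the origin at the MRCA of present tips", {
  tr <- ape::read.tree(text = "(((a:1,b:1):1,c:2):1,(d:2,e:2):1);")
  # presence in two sister tips: origin at their MRCA, no losses
  d <- dollo_reconstruct(c(a = 1, b = 1), tr)
  expect_equal(sort(tips_below(label_nodes(tr),
                               node_of_branch(label_nodes(tr),
                                              d$origin_branch))),
               c("a", "b"))
  expect_equal(d$n_losses, 0)
  expect_error(dollo_reconstruct(c(a = 0), tr), "all-absent")
})

test_that("Dollo reads a clade-restricted profile as a clade-ancestor gain", {
  # a panel shaped like the machinery survey: present in the gliding
  # order's genomes only, absent from the sister predator lineage outward
  tr <- ape::read.tree(text =
    "(((((Mxan:1,Saur:1):1,Anae:2):1,Bbac:3):1,Geob:4):1,(Gam1:4,Bet1:4):1);")
  pres <- c(Mxan = 1, Saur = 1, Anae = 1)
  d <- dollo_reconstruct(pres, tr)
  trl <- label_nodes(tr)
  expect_setequal(tips_below(trl, node_of_branch(trl, d$origin_branch)),
                  c("Mxan", "Saur", "Anae"))
  expect_equal(d$n_losses, 0)
  # with a loss inside the clade the origin stays, one loss is called
  d2 <- dollo_reconstruct(c(Mxan = 1, Anae = 1), tr)
  expect_setequal(tips_below(trl, node_of_branch(trl, d2$origin_branch)),
                  c("Mxan", "Saur", "Anae"))
  expect_equal(d2$loss_branches, "Saur")
})

test_that("Dollo loss counts equal the exhaustive single-gain oracle", {
  set.seed(14)
  for (rep in 1:5) {
    tr <- ape::rcoal(6)
    for (code in sample(1:63, 12)) {
      pres <- setNames(as.integer(intToBits(code))[1:6], tr$tip.label)
      if (!any(pres == 1)) next
      d <- dollo_reconstruct(pres, tr)
      expect_equal(d$n_losses, oracle_dollo_losses(pres, tr),
                   info = paste("code", code))
    }
  }
})

test_that("Fitch counts match enumeration and bound the Dollo count", {
  tr4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(fitch_count(c(A = 1, B = 1, C = 1, D = 1), tr4), 0)
  expect_equal(fitch_count(c(A = 1, B = 0, C = 1, D = 0), tr4), 2)
  set.seed(15)
  for (rep in 1:10) {
    tr <- ape::rcoal(6)
    pres <- setNames(rbinom(6, 1, 0.5), tr$tip.label)
    if (!any(pres == 1)) next
    d <- dollo_reconstruct(pres, tr)
    expect_lte(fitch_count(pres, tr), d$n_losses + 1)
  }
})

test_that("species-overlap flags duplications and maps their branch", {
  sp <- label_nodes(ape::read.tree(text = "((a:1,b:1)m:1,c:2)r;"))
  # two parallel copy blocks of (a, b): duplication at their join,
  # mapped to the (a, b) ancestor branch
  gt <- ape::read.tree(text = "(((a_1:1,b_1:1):1,(a_2:1,b_2:1):1):1,c_1:3);")
  ls <- c(a_1 = "a", b_1 = "b", a_2 = "a", b_2 = "b", c_1 = "c")
  dup <- infer_duplications(gt, ls, sp)
  expect_equal(nrow(dup), 1)
  expect_equal(dup$branch, "m")
  # one copy per species and a congruent tree: no duplications
  gt2 <- ape::read.tree(text = "((a_1:1,b_1:1):1,c_1:2);")
  expect_equal(nrow(infer_duplications(gt2, ls, sp)), 0)
  expect_error(infer_duplications(gt, ls[-1], sp), "unmapped")
})

test_that("transfer inference excludes fully transfer-derived genomes", {
  disp <- data.frame(leaf = "x_1", expected_clade = "A",
                     observed_clade = "B", support = 99, taxon = "x")
  pres <- c(x = 1, y = 1)
  out <- infer_transfers(disp, pres, c(x = 1, y = 1))
  expect_equal(out$transfers$recipient_branch, "x")
  expect_equal(out$presence_vertical[["x"]], 0)
  expect_equal(out$presence_vertical[["y"]], 1)
  # a genome with a native copy besides the transferred one stays present
  out2 <- infer_transfers(disp, pres, c(x = 2, y = 1))
  expect_equal(out2$presence_vertical[["x"]], 1)
  # no displacements: nothing changes
  out0 <- infer_transfers(disp[0, ], pres, c(x = 1, y = 1))
  expect_equal(nrow(out0$transfers), 0)
  expect_identical(out0$presence_vertical, pres)
})

test_that("removing a transfer-derived tip never moves the origin rootward", {
  set.seed(16)
  for (rep in 1:10) {
    tr <- label_nodes(ape::rcoal(8))
    pres <- setNames(rbinom(8, 1, 0.6), tr$tip.label)
    if (sum(pres) < 2) next
    d_full <- dollo_reconstruct(pres, tr)
    drop <- sample(names(pres)[pres == 1], 1)
    pres2 <- pres; pres2[drop] <- 0
    if (!any(pres2 == 1)) next
    d_red <- dollo_reconstruct(pres2, tr)
    n_full <- node_of_branch(tr, d_full$origin_branch)
    n_red <- node_of_branch(tr, d_red$origin_branch)
    expect_true(glidevol:::is_ancestor(tr, n_full, n_red))
  }
})

test_that("event metrics equal brute-force set comparison", {
  truth <- data.frame(
    type = c("gain", "loss", "duplication", "transfer", "transfer"),
    family_id = c("F1", "F1", "F2", "F1", "F2"),
    branch = c("N1", "t3", "N2", "t5", "t6"))
  inferred <- data.frame(
    family_id = c("F1", "F1", "F2", "F2", "F2"),
    type = c("gain", "loss", "duplication", "transfer", "transfer"),
    branch = c("N1", "t4", "N2", "t6", "t9"),
    source = NA, support = NA)
  m <- recovery_metrics(inferred, truth)
  expect_equal(m$n_matched[m$type == "gain"], 1)
  expect_equal(m$n_matched[m$type == "loss"], 0)
  expect_equal(m$n_matched[m$type == "duplication"], 1)
  expect_equal(m$n_matched[m$type == "transfer"], 1)
  expect_equal(m$precision[m$type == "transfer"], 1 / 2)
  expect_equal(m$recall[m$type == "transfer"], 1 / 2)
  # descendant matching credits a tip-level call below the true branch
  sp <- label_nodes(ape::read.tree(text = "((a:1,b:1)m:1,c:2)r;"))
  truth2 <- data.frame(type = "transfer", family_id = "F1", branch = "m")
  inf2 <- data.frame(family_id = "F1", type = "transfer", branch = "a",
                     source = NA, support = NA)
  m2 <- recovery_metrics(inf2, truth2, species_tree = sp)
  expect_equal(m2$recall[m2$type == "transfer"], 1)
  m2b <- recovery_metrics(inf2, truth2)   # exact matching: no credit
  expect_equal(m2b$recall[m2b$type == "transfer"], 0)
})

test_that("a vertical single-copy world yields a trivial scenario", {
  cfg <- small_sim_config(seed = 3)
  cfg$core_rates <- list(dup_rate = 0, loss_rate = 0, transfer_rate = 0)
  cfg$acc_rates <- list(dup_rate = 0, loss_rate = 0, transfer_rate = 0)
  cfg$wgd <- FALSE
  sim <- simulate_dataset(cfg)
  run <- run_pipeline(sim, small_run_config())
  ev <- run$events
  expect_equal(sum(ev$type %in% c("loss", "duplication", "transfer")), 0)
  # origins reproduce the staged gains exactly
  m <- run$recovery$events
  expect_equal(m$recall[m$type == "gain"], 1)
  expect_equal(m$precision[m$type == "gain"], 1)
})

test_that("the scenario tree rendering annotates events on branches", {
  sp <- label_nodes(ape::read.tree(text = "((a:1,b:1)m:1,c:2)r;"))
  sc <- structure(list(list(
    family_id = "F1", origin_branch = "m", loss_branches = "a",
    duplications = data.frame(node = 5L, branch = "m", n_species = 2L),
    transfers = data.frame(recipient_branch = "c", source_clade = "X",
                           support = 99),
    group = "GroupA")), class = c("evolutionary_scenario_set", "list"))
  lines <- capture.output(out <- render_scenario_tree(sc, sp))
  expect_true(any(grepl("m.*\\+F1", lines)))
  expect_true(any(grepl("a.*-F1", lines)))
  expect_true(any(grepl("c.*T:F1", lines)))
  expect_equal(length(out), 5)  # one line per node
})
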
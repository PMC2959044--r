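# Midpoint rooting, root-to-tip statistics, species-specific clade counting.

test_that("midpoint rooting balances the diameter endpoints", {
  t2 <- ape::read.tree(text = "(A:2.5,B:2.5);")  # two leaves, edge total 5
  mr <- midpoint_root(t2)
  expect_equal(unname(root_tip_lengths(mr)), c(2.5, 2.5))

  # ultrametric balanced tree: the root stays put
  tu <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  mu <- midpoint_root(tu)
  expect_equal(max(root_tip_lengths(mu)), 2)
  expect_equal(phangorn::RF.dist(mu, tu, rooted = TRUE), 0)

  expect_error(midpoint_root(ape::read.tree(text = "((A:0,B:0):0,C:0);")),
               "degenerate")
})

test_that("midpoint rooting matches the brute-force minimizer and phangorn", {
  set.seed(55)
  for (i in 1:30) {
    n <- sample(4:20, 1)
    tr <- ape::rtree(n)
    mr <- midpoint_root(tr)
    rtl <- root_tip_lengths(mr)
    diam <- max(ape::cophenetic.phylo(tr))
    expect_equal(max(rtl), diam / 2, tolerance = 1e-9)
    # no discretized alternative root position does better
    bf <- oracle_min_max_roottip(tr, npoints = 41)
    expect_lte(max(rtl), bf + 1e-9)
    # independent implementation cross-check
    ph <- phangorn::midpoint(tr)
    expect_equal(max(ape::node.depth.edgelength(ph)[seq_len(n)]), max(rtl),
                 tolerance = 1e-9)
  }
})

test_that("root-to-tip lengths equal a brute-force path walk", {
  tr <- ape::read.tree(text = "((A:0.25,B:1.0):0.5);")
  expect_equal(root_tip_lengths(tr), c(A = 0.75, B = 1.5))
  set.seed(9)
  big <- ape::rtree(20)
  expect_equal(root_tip_lengths(big), oracle_root_tip(big))
})

test_that("per-prefix averages cover singleton prefixes", {
  tr <- ape::read.tree(text = "((MlA:0.5,MlB:1.5):0.5,HsA:2.5);")
  avg <- average_root_tip_by_prefix(tr)
  expect_equal(avg[["Ml"]], 1.5)
  expect_equal(avg[["Hs"]], 2.5)
})

test_that("species-specific clade counting is maximal and never nested", {
  t1 <- ape::read.tree(text = "((Mla:1,Mlb:1):1,(Hsa:1,Hsb:1):1);")
  c1 <- count_species_specific_clades(t1)
  expect_equal(c1$n_clades[c1$prefix == "Ml"], 1L)
  expect_equal(c1$n_leaves[c1$prefix == "Ml"], 2L)
  expect_equal(c1$n_clades[c1$prefix == "Hs"], 1L)

  t2 <- ape::read.tree(text = "((Mla:1,(Mlb:1,Mlc:1):1):1,Hsa:1);")
  c2 <- count_species_specific_clades(t2)
  expect_equal(c2$n_clades[c2$prefix == "Ml"], 1L)   # nested clade not double-counted
  expect_equal(c2$n_leaves[c2$prefix == "Ml"], 3L)
  expect_equal(c2$n_clades[c2$prefix == "Hs"], 0L)

  t3 <- ape::read.tree(text = "((Mla:1,Hsa:1):1,(Hsb:1,Nva:1):1);")
  c3 <- count_species_specific_clades(t3)
  expect_true(all(c3$n_clades == 0L))
  expect_true(all(c3$n_leaves == 0L))
})

test_that("clade counting matches exhaustive node enumeration on random trees", {
  set.seed(77)
  for (i in 1:60) {
    tr <- rand_prefixed_tree(sample(4:20, 1))
    got <- count_species_specific_clades(tr)
    expect_equal(got, oracle_clade_counts(tr))
    # invariant under child-order permutation
    rot <- ape::rotateConstr(tr, sample(tr$tip.label))
    expect_equal(count_species_specific_clades(rot), got)
    # sum of clade leaves never exceeds the leaf count
    expect_lte(sum(got$n_leaves), ape::Ntip(tr))
  }
})

test_that("subset relabelling isolates a pseudo-species", {
  tr <- ape::read.tree(text = "((Mla:1,Mlb:2):1,(Mlc:3,Mld:4):1);")
  rl <- relabel_subset(tr, c("Mla", "Mlb"), "Zz")
  expect_setequal(substr(rl$tip.label, 1, 2), c("Ml", "Zz"))
  avg <- average_root_tip_by_prefix(rl)
  expect_equal(avg[["Zz"]], mean(c(2, 3)))
  expect_equal(avg[["Ml"]], mean(c(4, 5)))
  expect_equal(rl$edge.length, tr$edge.length)

  expect_identical(relabel_subset(tr, character(), "Zz")$tip.label, tr$tip.label)
  expect_error(relabel_subset(tr, "Mla", "Ml"), "collision")
  expect_error(relabel_subset(tr, "nope", "Zz"), "not in tree")
})

test_that("the clade report combines counts, averages and the grand-mean row", {
  # seven single-species stars joined at the root
  stars <- paste(vapply(1:7, function(i) {
    pfx <- sprintf("S%d", i)
    sprintf("(%sa:%d,%sb:%d):1", pfx, i, pfx, i)
  }, ""), collapse = ",")
  tr <- ape::read.tree(text = paste0("(", stars, ");"))
  recs <- lapply(tr$tip.label, function(id) hd_record(id, strrep("A", 60)))
  rep7 <- build_clade_report(midpoint_root(tr), recs)
  expect_equal(nrow(rep7), 8L)
  expect_equal(rep7$species[8], "Average")
  expect_equal(rep7$n_records[1:7], rep(2, 7))
  expect_equal(rep7$average_root_tip[8], mean(rep7$average_root_tip[1:7]))
  expect_equal(rep7$n_species_specific_clades[8],
               mean(rep7$n_species_specific_clades[1:7]))

  expect_error(build_clade_report(midpoint_root(tr), recs[-1]),
               "reconciliation")
})

test_that("the clade report matches simulator ground truth", {
  sim <- simulate_repertoire(simulation_config(duplication_rate = 0.02, seed = 404))
  rep_true <- build_clade_report(sim$true_gene_tree, sim$records)
  by_pref <- sim$truth[order(sim$truth$prefix), ]
  body <- rep_true[rep_true$species != "Average", ]
  expect_equal(body$n_species_specific_clades, as.numeric(by_pref$n_clades))
  expect_equal(body$n_in_species_specific_clades, as.numeric(by_pref$n_leaves))
  expect_equal(body$n_records, as.numeric(by_pref$n_records))
  expect_equal(root_tip_lengths(sim$true_gene_tree), sim$true_root_tip)
})
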
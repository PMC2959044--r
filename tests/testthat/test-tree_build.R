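# Protein distances and neighbor-joining.

test_that("pairwise distances apply pairwise deletion and the Poisson correction", {
  a <- hd_record("MlA1", strrep("A", 60))
  b <- hd_record("MlB1", strrep("A", 60))
  expect_equal(compute_distances(list(a, b))["MlA1", "MlB1"], 0)

  # 6 mismatches over 60 compared columns
  c6 <- hd_record("MlC1", paste0(strrep("C", 6), strrep("A", 54)))
  D <- compute_distances(list(a, c6), model = "poisson")
  expect_equal(D["MlA1", "MlC1"], -log(1 - 6 / 60), tolerance = 1e-12)

  # one gap column removes it from numerator and denominator
  g <- hd_record("MlG1", paste0("-", strrep("C", 5), strrep("A", 54)))
  Dp <- compute_distances(list(a, g), model = "p")
  expect_equal(Dp["MlA1", "MlG1"], 5 / 59)

  # zero comparable columns is an error naming the pair
  left <- hd_record("MlL1", paste0(strrep("A", 30), strrep("-", 30)))
  right <- hd_record("MlR1", paste0(strrep("-", 30), strrep("A", 30)))
  expect_error(compute_distances(list(left, right)), "MlL1.*MlR1")

  # saturation: all 60 columns differ
  sat <- hd_record("MlS1", strrep("C", 60))
  expect_warning(Ds <- compute_distances(list(a, sat)), "saturated")
  expect_equal(Ds["MlA1", "MlS1"], Inf)
})

test_that("distances are permutation-equivariant", {
  set.seed(7)
  recs <- lapply(1:8, function(i) {
    hd_record(sprintf("Ml%03d", i),
              paste(sample(c(AA20_test, "-"), 60, TRUE,
                           prob = c(rep(1, 20), 3)), collapse = ""))
  })
  D <- compute_distances(recs, model = "p")
  perm <- sample(8)
  Dp <- compute_distances(recs[perm], model = "p")
  expect_equal(Dp, D[rownames(Dp), colnames(Dp)])
})

test_that("NJ handles the small closed-form cases", {
  D2 <- matrix(c(0, 1.4, 1.4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- neighbor_joining(D2)
  expect_equal(sort(t2$tip.label), c("A", "B"))
  expect_equal(sum(t2$edge.length), 1.4)

  # n = 3: star with a = (dAB + dAC - dBC) / 2 and cyclic analogues
  lab <- c("A", "B", "C")
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, dimnames = list(lab, lab))
  t3 <- neighbor_joining(D3)
  el <- setNames(t3$edge.length[match(seq_len(3), t3$edge[, 2])], t3$tip.label)
  expect_equal(el[["A"]], (3 + 4 - 5) / 2)
  expect_equal(el[["B"]], (3 + 5 - 4) / 2)
  expect_equal(el[["C"]], (4 + 5 - 3) / 2)

  expect_error(neighbor_joining(matrix(c(0, -1, -1, 0), 2,
                                       dimnames = list(c("A", "B"), c("A", "B")))),
               "matrix-validity")
})

test_that("NJ recovers the generating tree exactly from additive matrices", {
  gen <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):1);")
  D <- ape::cophenetic.phylo(gen)
  tr <- neighbor_joining(D)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
               tolerance = 1e-12)
  expect_equal(phangorn::RF.dist(ape::unroot(gen), ape::unroot(tr)), 0)
})

test_that("NJ matches tree metrics and ape::nj on random additive inputs", {
  set.seed(33)
  for (i in 1:40) {
    n <- sample(4:10, 1)
    gen <- ape::rtree(n)
    D <- ape::cophenetic.phylo(gen)
    tr <- neighbor_joining(D)
    # leaf set and unrooted edge count
    expect_setequal(tr$tip.label, gen$tip.label)
    expect_equal(nrow(tr$edge), 2 * n - 3)
    # additive-matrix oracle: the generating tree itself
    expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
                 tolerance = 1e-9)
    # independent implementation cross-check
    expect_equal(phangorn::RF.dist(ape::unroot(ape::nj(D)), ape::unroot(tr)), 0)
  }
})
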
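# Tree data model: Newick I/O, pruning, mbl time-scaling,
# ultrametricization, patristic distances.

test_that("parse_newick reads valid strings and rejects malformed ones", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  depths <- ape::node.depth.edgelength(tr)[1:3]
  expect_equal(depths, rep(2, 3))

  expect_error(parse_newick("((A:1,B:1):1,C:2;"), "character")
  expect_error(parse_newick("(A:1,B:1)):1;"), "character 10")
  expect_error(parse_newick("(A,B);"), "branch lengths")
  tr_unit <- parse_newick("(A,B);", unit_lengths = TRUE)
  expect_equal(tr_unit$edge.length, c(1, 1))
  expect_error(parse_newick("((A:1,A:1):1,C:2);"), "Duplicate")
})

test_that("write -> parse round-trips topology and branch lengths", {
  withr::local_seed(11)
  for (i in 1:25) {
    cfg <- scenario_config(n_taxa = sample(5:15, 1), seed = i)
    tree <- simulate_tree(cfg)$tree
    back <- parse_newick(write_newick(tree))
    expect_setequal(back$tip.label, tree$tip.label)
    labs <- tree$tip.label
    expect_equal(patristic_matrix(back)[labs, labs],
                 patristic_matrix(tree)[labs, labs], tolerance = 1e-8)
  }
})

test_that("prune_tree keeps exactly the requested taxa and their distances", {
  tr <- toy_tree()
  same <- prune_tree(tr, c("A", "B", "C"))
  expect_setequal(same$tip.label, tr$tip.label)
  expect_equal(patristic_matrix(same)[c("A", "B"), c("A", "B")],
               patristic_matrix(tr)[c("A", "B"), c("A", "B")])

  two <- prune_tree(tr, c("A", "C"))
  expect_setequal(two$tip.label, c("A", "C"))
  expect_equal(unname(patristic_matrix(two)["A", "C"]), 4)

  expect_error(prune_tree(tr, c("A", "X")), "X")
  expect_error(prune_tree(tr, "A"), "two taxa")
})

test_that("prune_tree preserves patristic distances on random subsets", {
  withr::local_seed(21)
  for (i in 1:20) {
    tree <- ape::rtree(sample(8:20, 1))
    keep <- sample(tree$tip.label, sample(3:6, 1))
    D_full <- patristic_matrix(tree)[keep, keep]
    D_sub <- patristic_matrix(prune_tree(tree, keep))[keep, keep]
    expect_equal(D_sub, D_full, tolerance = 1e-9)
  }
})

test_that("timescale_mbl reproduces the hand-worked node ages", {
  tr <- parse_newick("((A:1,B:1):1,C:1);")
  ages <- tibble::tibble(taxon = c("A", "B", "C"), fad_ma = c(80, 75, 72))
  ts <- timescale_mbl(tr, ages, mbl = 1)
  expect_equal(node_ages(ts), c(82, 81))
  expect_equal(tip_ages(ts), c(A = 80, B = 75, C = 72))
  # branches: node->A 1, node->B 6, root->node 1, root->C 10
  expect_setequal(round(ts$edge.length, 9), c(1, 6, 1, 10))

  pair <- timescale_mbl(parse_newick("(A:1,B:1);"),
                        tibble::tibble(taxon = c("A", "B"), fad_ma = c(10, 5)),
                        mbl = 1)
  expect_equal(node_ages(pair), 11)
  expect_setequal(pair$edge.length, c(1, 6))

  # contemporaneous tips on a balanced topology: cherries at a+1, root a+2
  bal <- timescale_mbl(parse_newick("((A:1,B:1):1,(C:1,D:1):1);"),
                       tibble::tibble(taxon = LETTERS[1:4], fad_ma = 70),
                       mbl = 1)
  expect_setequal(node_ages(bal), c(72, 71, 71))

  expect_error(timescale_mbl(tr, ages[1:2, ], mbl = 1), "C")
  expect_error(timescale_mbl(tr, ages, mbl = 0), "positive")
})

test_that("timescale_mbl matches the closed-form constraint oracle", {
  withr::local_seed(31)
  for (i in 1:60) {
    tree <- ape::rtree(sample(4:15, 1))
    mbl <- runif(1, 0.2, 3)
    fad <- setNames(runif(ape::Ntip(tree), 60, 90), tree$tip.label)
    ages <- tibble::tibble(taxon = names(fad), fad_ma = unname(fad))
    ts <- timescale_mbl(tree, ages, mbl = mbl)
    expect_equal(node_ages(ts),
                 mbl_age_oracle(tree, fad, mbl), tolerance = 1e-9)
    expect_true(all(ts$edge.length >= mbl - 1e-9))
    # every node at least as old as its oldest descendant tip
    oldest <- mbl_age_oracle(tree, fad, 0)
    expect_true(all(node_ages(ts) >= oldest - 1e-9))
    # mbl -> 0 limit: nodes exactly at oldest descendant tip
    ts0 <- timescale_mbl(tree, ages, mbl = 1e-9)
    expect_equal(node_ages(ts0), oldest, tolerance = 1e-6)
  }
})

test_that("make_ultrametric extends terminals to the youngest tip only", {
  tr <- parse_newick("((A:1,B:1):1,C:1);")
  ages <- tibble::tibble(taxon = c("A", "B", "C"), fad_ma = c(80, 75, 72))
  ts <- timescale_mbl(tr, ages, mbl = 1)
  u <- make_ultrametric(ts)
  expect_true(is_ultrametric(u, tol = 1e-9))
  expect_equal(unname(tip_ages(u)), rep(72, 3))
  expect_equal(node_ages(u), node_ages(ts))
  # terminal branches A: 81-72, B: 81-72, C: 82-72
  term <- u$edge.length[match(1:3, u$edge[, 2])]
  expect_setequal(term, c(9, 9, 10))
  # idempotent
  expect_equal(make_ultrametric(u)$edge.length, u$edge.length)
})

test_that("make_ultrametric never shortens branches across random trees", {
  withr::local_seed(41)
  for (i in 1:40) {
    tree <- ape::rtree(sample(5:20, 1))
    ages <- tibble::tibble(taxon = tree$tip.label,
                           fad_ma = runif(ape::Ntip(tree), 66, 84))
    ts <- timescale_mbl(tree, ages, mbl = runif(1, 0.5, 2))
    u <- make_ultrametric(ts)
    expect_true(is_ultrametric(u, tol = 1e-9))
    expect_true(all(u$edge.length - ts$edge.length >= -1e-12))
    expect_equal(node_ages(u), node_ages(ts))
  }
})

test_that("patristic_matrix equals path sums and the ultrametric MRCA form", {
  D <- patristic_matrix(toy_tree())
  expect_equal(unname(D["A", "B"]), 2)
  expect_equal(unname(D["A", "C"]), 4)
  expect_equal(unname(D["B", "C"]), 4)
  expect_equal(unname(diag(D)), rep(0, 3))

  withr::local_seed(51)
  for (i in 1:10) {
    tree <- ape::rtree(sample(5:12, 1))
    expect_equal(patristic_matrix(tree)[tree$tip.label, tree$tip.label],
                 patristic_oracle(tree)[tree$tip.label, tree$tip.label],
                 tolerance = 1e-9)
  }
  # on an ultrametric tree d_ij = 2 * age of the MRCA
  for (i in 1:10) {
    tree <- ape::rtree(6)
    ages <- tibble::tibble(taxon = tree$tip.label, fad_ma = runif(6, 70, 80))
    u <- make_ultrametric(timescale_mbl(tree, ages, mbl = 1))
    D <- patristic_matrix(u)
    na <- node_ages(u)
    tip_age <- unname(tip_ages(u)[1])
    for (a in 1:5) {
      for (b in (a + 1):6) {
        mrca <- ape::getMRCA(u, c(u$tip.label[a], u$tip.label[b]))
        expect_equal(unname(D[u$tip.label[a], u$tip.label[b]]),
                     2 * (na[mrca - ape::Ntip(u)] - tip_age),
                     tolerance = 1e-9)
      }
    }
  }
})
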
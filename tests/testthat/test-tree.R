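quartet_matrix <- function() {
  m <- matrix(4, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(m) <- 0
  m["A", "B"] <- m["B", "A"] <- 2
  m["C", "D"] <- m["D", "C"] <- 2
  m
}

test_that("neighbor_joining is exact on the additive quartet", {
  tree <- neighbor_joining(quartet_matrix())
  truth <- parse_newick("((A:1,B:1):2,(C:1,D:1));")
  expect_equal(robinson_foulds(tree, truth), 0)
  cp <- ape::cophenetic.phylo(tree)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(cp, quartet_matrix(), tolerance = 1e-12)
  # internal edge length 2, leaf edges 1
  ntip <- 4L
  internal <- tree$edge[, 2] > ntip
  expect_equal(sort(unname(tree$edge.length[internal])), 2)
  expect_equal(unname(tree$edge.length[!internal]), rep(1, 4))
})

test_that("neighbor_joining handles the 3-taxon star and bad input", {
  m <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- neighbor_joining(m)
  expect_equal(tree$Nnode, 1L)
  # three-point formulas: a = (dAB + dAC - dBC)/2, etc.
  el <- setNames(tree$edge.length, tree$tip.label[tree$edge[, 2]])
  expect_equal(el[c("A", "B", "C")], c(A = 1, B = 2, C = 3))
  expect_error(neighbor_joining(m[1:2, 1:2]), "at least 3")
  m[1, 2] <- m[2, 1] <- NA
  expect_error(neighbor_joining(m), "non-finite")
})

test_that("neighbor_joining recovers random additive trees exactly", {
  for (seed in 1:10) {
    n <- 5 + (seed %% 6)
    oracle <- random_additive_tree(n, seed = seed)
    tree <- neighbor_joining(oracle$matrix)
    expect_equal(robinson_foulds(tree, oracle$tree), 0)
    cp <- ape::cophenetic.phylo(tree)
    cp <- cp[rownames(oracle$matrix), colnames(oracle$matrix)]
    expect_equal(cp, oracle$matrix, tolerance = 1e-9)
  }
})

test_that("majority_consensus keeps exactly the majority splits", {
  t1 <- parse_newick("((A,B),(C,D));")
  t2 <- parse_newick("((A,C),(B,D));")

  cons <- majority_consensus(list(t1, t1, t1))
  expect_equal(robinson_foulds(cons, t1), 0)
  expect_equal(sort(cons$node.label[!is.na(cons$node.label)]), 100)

  cons2 <- majority_consensus(list(t1, t1, t2))
  expect_equal(robinson_foulds(cons2, t1), 0)
  expect_equal(cons2$node.label[!is.na(cons2$node.label)], 200 / 3,
               tolerance = 1e-9)

  # no split above threshold: star tree
  t3 <- parse_newick("((A,D),(B,C));")
  star <- majority_consensus(list(t1, t2, t3))
  expect_equal(star$Nnode, 1L)

  # B = 1 degenerate case
  one <- majority_consensus(list(t1))
  expect_equal(robinson_foulds(one, t1), 0)
  expect_true(all(one$node.label[!is.na(one$node.label)] == 100))

  bad <- parse_newick("((A,B),(C,E));")
  expect_error(majority_consensus(list(t1, bad)), "tree 2")
})

test_that("majority_consensus agrees with ape::consensus on random trees", {
  for (seed in 1:5) {
    trees <- lapply(1:7, function(i)
      random_additive_tree(6, seed = seed * 20 + i %% 3)$tree)
    mine <- majority_consensus(trees)
    apes <- ape::consensus(trees, p = 0.5)
    expect_equal(robinson_foulds(mine, apes), 0)
  }
})

test_that("fit_branch_lengths is exact on additive input", {
  for (seed in 1:5) {
    oracle <- random_additive_tree(7, seed = seed + 300)
    fitted <- fit_branch_lengths(oracle$tree, oracle$matrix)
    cp <- ape::cophenetic.phylo(fitted)[rownames(oracle$matrix),
                                        colnames(oracle$matrix)]
    expect_equal(cp, oracle$matrix, tolerance = 1e-8)
    # and reproduces NJ's (equally exact) branch lengths via path distances
    nj <- neighbor_joining(oracle$matrix)
    cpn <- ape::cophenetic.phylo(nj)[rownames(oracle$matrix),
                                     colnames(oracle$matrix)]
    expect_equal(cp, cpn, tolerance = 1e-8)
  }
})

test_that("fit_branch_lengths matches unweighted NNLS when power = 0", {
  oracle <- random_additive_tree(6, seed = 41)
  noisy <- oracle$matrix + cgrphylo:::with_seed(42, {
    e <- matrix(runif(36, 0, 0.02), 6)
    e <- (e + t(e)) / 2
    diag(e) <- 0
    e
  })
  mine <- fit_branch_lengths(oracle$tree, noisy, power = 0)
  ref <- phangorn::nnls.tree(as.dist(noisy), oracle$tree)
  expect_equal(ape::cophenetic.phylo(mine)[rownames(noisy), colnames(noisy)],
               ape::cophenetic.phylo(ref)[rownames(noisy), colnames(noisy)],
               tolerance = 1e-6)
})

test_that("fit_branch_lengths recovers lengths under small noise", {
  sigma <- 0.01
  oracle <- random_additive_tree(8, seed = 77)
  noisy <- oracle$matrix + cgrphylo:::with_seed(78, {
    e <- matrix(rnorm(64, 0, sigma), 8)
    e <- (e + t(e)) / 2
    diag(e) <- 0
    e
  })
  noisy <- pmax(noisy, 0)
  fitted <- fit_branch_lengths(oracle$tree, noisy)
  expect_equal(fitted$edge.length, oracle$tree$edge.length,
               tolerance = 3 * sigma)
})

test_that("fit_branch_lengths warns on zero off-diagonal distances", {
  m <- quartet_matrix()
  m["A", "B"] <- m["B", "A"] <- 0
  topo <- parse_newick("((A,B),(C,D));")
  expect_warning(fit_branch_lengths(topo, m), "zero off-diagonal")
})

test_that("Newick writing and parsing round-trip trees", {
  star <- parse_newick("(A:1,B:1,C:1);")
  expect_equal(tree_to_newick(star), "(A:1,B:1,C:1);")

  # supports travel as internal node labels
  t1 <- parse_newick("((A,B),(C,D));")
  t2 <- parse_newick("((A,C),(B,D));")
  cons <- majority_consensus(list(t1, t1, t2))
  cons$edge.length <- rep(1, nrow(cons$edge))
  nwk <- tree_to_newick(cons)
  expect_match(nwk, "66\\.6")
  back <- parse_newick(nwk)
  expect_equal(robinson_foulds(back, cons), 0)
  expect_equal(sort(back$node.label[!is.na(back$node.label)]),
               sort(cons$node.label[!is.na(cons$node.label)]),
               tolerance = 1e-6)
  expect_false(grepl("66", tree_to_newick(cons, include_supports = FALSE)))

  # lengths survive within 1e-6 at 6 significant digits
  oracle <- random_additive_tree(6, seed = 90)
  back2 <- parse_newick(tree_to_newick(oracle$tree))
  expect_equal(robinson_foulds(back2, oracle$tree), 0)
  cp <- ape::cophenetic.phylo(back2)[rownames(oracle$matrix),
                                     colnames(oracle$matrix)]
  expect_equal(cp, oracle$matrix, tolerance = 1e-5)

  expect_error(parse_newick("((A,B,(C);"), "parse error")
})

test_that("robinson_foulds counts unshared splits symmetrically", {
  t1 <- parse_newick("((A,B),(C,D));")
  t2 <- parse_newick("((A,C),(B,D));")
  expect_equal(robinson_foulds(t1, t1), 0)
  expect_equal(robinson_foulds(t1, t2), 2)
  expect_equal(robinson_foulds(t2, t1), 2)
  for (seed in 1:5) {
    a <- random_additive_tree(7, seed = 400 + seed)$tree
    b <- random_additive_tree(7, seed = 500 + seed)$tree
    expect_equal(robinson_foulds(a, b),
                 as.integer(phangorn::RF.dist(a, b)))
  }
})
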
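test_that("euclidean_distance matches the hand-derived value and contracts", {
  a <- make_fcgr(matrix(c(2, 1, 0, 1), 2), k = 1, standardized = TRUE)
  b <- make_fcgr(matrix(1, 2, 2), k = 1, standardized = TRUE)
  expect_equal(euclidean_distance(a, b), sqrt(2) / 2)
  expect_equal(euclidean_distance(b, a), euclidean_distance(a, b))
  expect_equal(euclidean_distance(a, a), 0)

  raw <- make_fcgr(matrix(1, 2, 2), k = 1)
  expect_error(euclidean_distance(a, raw), "standardized")
  b2 <- make_fcgr(matrix(1, 4, 4), k = 2, standardized = TRUE)
  expect_error(euclidean_distance(a, b2), "different k")
})

test_that("pearson_distance matches the hand-derived value and contracts", {
  # 2-cell profiles x=(1,2), y=(2,1): weighted correlation is exactly -1
  expect_equal(cgrphylo:::pearson_distance_vec(c(1, 2), c(2, 1)), 2)
  a <- compute_fcgr(rand_dna(500, 1), 2)
  b <- compute_fcgr(rand_dna(500, 2), 2)
  expect_equal(pearson_distance(a, a), 0)
  expect_equal(pearson_distance(a, b), pearson_distance(b, a))
  expect_error(pearson_distance(standardize_fcgr(a), b), "non-standardized")
  expect_error(cgrphylo:::pearson_distance_vec(c(1, 0), c(0, 1)),
               "no shared support")
  expect_error(cgrphylo:::pearson_distance_vec(c(2, 2), c(2, 2)),
               "degenerate")
})

test_that("pearson_distance is invariant under joint positive rescaling", {
  for (seed in 1:10) {
    x <- fcgr_vector(compute_fcgr(rand_dna(400, seed + 10), 2))
    y <- fcgr_vector(compute_fcgr(rand_dna(400, seed + 110), 2))
    d <- cgrphylo:::pearson_distance_vec(x, y)
    expect_gte(d, 0)
    expect_lte(d, 2)
    c0 <- 0.5 + seed / 5
    expect_equal(cgrphylo:::pearson_distance_vec(c0 * x, c0 * y), d)
  }
})

test_that("both metrics satisfy the basic axioms on random profiles", {
  profs <- random_profiles(6, k = 2, len = 800, seed0 = 40)
  std <- lapply(profs, standardize_fcgr)
  for (metric in c("euclidean", "pearson")) {
    dm <- build_distance_matrix(if (metric == "euclidean") std else profs,
                                metric)
    expect_identical(dm$values, t(dm$values))
    expect_equal(unname(diag(dm$values)), rep(0, 6))
    expect_true(all(dm$values >= 0))
  }
})

test_that("Euclidean distance satisfies the triangle inequality", {
  profs <- lapply(1:12, function(i)
    standardize_fcgr(compute_fcgr(rand_dna(600, 200 + i,
                                           gc = 0.3 + 0.04 * (i %% 10)), 2)))
  combos <- t(combn(12, 3))
  for (r in seq_len(nrow(combos))) {
    i <- combos[r, 1]; j <- combos[r, 2]; l <- combos[r, 3]
    dij <- euclidean_distance(profs[[i]], profs[[j]])
    dil <- euclidean_distance(profs[[i]], profs[[l]])
    djl <- euclidean_distance(profs[[j]], profs[[l]])
    expect_lte(dij, dil + djl + 1e-12)
  }
})

test_that("build_distance_matrix validates input and separates GC groups", {
  profs <- random_profiles(3, k = 2, seed0 = 60)
  expect_true(all(build_distance_matrix(profs, "pearson")$values[
    upper.tri(diag(3))] >= 0))
  identical3 <- list(a = profs[[1]], b = profs[[1]], c = profs[[1]])
  expect_equal(max(build_distance_matrix(identical3, "pearson")$values), 0)

  dup <- profs
  names(dup) <- c("a", "a", "b")
  expect_error(build_distance_matrix(dup, "pearson"), "duplicate")
  mixed <- list(a = profs[[1]], b = profs[[2]],
                c = compute_fcgr(rand_dna(300, 1), 3))
  expect_error(build_distance_matrix(mixed, "pearson"), "inconsistent k")
  expect_error(build_distance_matrix(profs[1:2], "pearson"), "at least 3")

  # two GC-composition groups: within-group < between-group distances
  gcs <- c(0.35, 0.35, 0.65, 0.65)
  profs4 <- lapply(1:4, function(i)
    standardize_fcgr(compute_fcgr(rand_dna(3000, 300 + i, gc = gcs[i]), 3)))
  names(profs4) <- c("lo1", "lo2", "hi1", "hi2")
  v <- build_distance_matrix(profs4, "euclidean")$values
  within <- c(v["lo1", "lo2"], v["hi1", "hi2"])
  between <- c(v["lo1", "hi1"], v["lo1", "hi2"], v["lo2", "hi1"],
               v["lo2", "hi2"])
  expect_lt(max(within), min(between))
})

test_that("PHYLIP square matrices round-trip within 1e-6", {
  profs <- random_profiles(4, k = 2, seed0 = 70)
  dm <- build_distance_matrix(lapply(profs, standardize_fcgr), "euclidean")
  text <- write_phylip(dm)
  expect_match(text, "^4\n")
  expect_match(text, "\ntx2       ")
  path <- tempfile(fileext = ".phy")
  write_phylip(dm, path)
  back <- read_phylip(path)
  expect_lt(max(abs(back - dm$values)), 1e-6)  # 6-decimal format: absolute

  zero <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_match(write_phylip(zero), "^3\nA         0\\.000000")

  clash <- matrix(0, 3, 3)
  rownames(clash) <- colnames(clash) <-
    c("Brassica_rapa_x", "Brassica_rapa_y", "Z")
  expect_error(write_phylip(clash), "Brassica_r")
})

test_that("rescaling a distance matrix leaves the NJ topology unchanged", {
  # the Euclidean prefactor is inert for tree topologies
  profs <- lapply(1:6, function(i)
    standardize_fcgr(compute_fcgr(rand_dna(2000, 500 + i,
                                           gc = 0.3 + 0.06 * i), 3)))
  names(profs) <- paste0("t", 1:6)
  dm <- build_distance_matrix(profs, "euclidean")
  base_tree <- neighbor_joining(dm)
  for (c0 in c(0.01, 3, 1000)) {
    scaled <- dm
    scaled$values <- dm$values * c0
    expect_equal(robinson_foulds(neighbor_joining(scaled), base_tree), 0)
  }
})
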
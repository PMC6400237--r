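test_that("p-distance and Poisson correction follow their definitions", {
  m <- new_msa(c(a = "MKLVWAARTY", b = "MKLVWAARTY"))
  expect_true(all(distance_matrix(m) == 0))

  # 2 mismatches over 10 compared columns
  m2 <- new_msa(c(a = "MKLVWAARTY", b = "MKLVWAARGG"))
  expect_equal(distance_matrix(m2)["a", "b"], 0.2)
  expect_equal(distance_matrix(m2, "poisson")["a", "b"], -log(0.8))

  # gap columns are excluded pairwise
  m3 <- new_msa(c(a = "MK-VW", b = "MKL-W"))
  expect_equal(distance_matrix(m3)["a", "b"], 0)

  m4 <- new_msa(c(a = "MK---", b = "--LVW"))
  expect_error(distance_matrix(m4), "no overlapping columns")
})

test_that("neighbor joining solves the 3-taxon closed form and recovers additive trees", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(d)
  # three-point formulas: la = (dab + dac - dbc)/2 etc.
  got <- setNames(t3$edge.length[match(seq_len(3), t3$edge[, 2])],
                  t3$tip.label)
  expect_equal(got[c("a", "b", "c")], c(a = 1, b = 2, c = 3))
  expect_error(nj_tree(d[1:2, 1:2]), ">= 3 taxa")

  set.seed(30)
  for (i in 1:25) {
    tr <- ape::rtree(sample(4:8, 1))
    dm <- ape::cophenetic.phylo(tr)
    dm <- dm[tr$tip.label, tr$tip.label]
    inf <- nj_tree(dm)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), inf)), 0)
    # additivity: inferred path lengths reproduce the input distances
    expect_equal(ape::cophenetic.phylo(inf)[rownames(dm), colnames(dm)],
                 dm, tolerance = 1e-8)
    # cross-check against ape's NJ topology
    expect_equal(as.numeric(ape::dist.topo(ape::nj(dm), inf)), 0)
  }
})

test_that("negative NJ branch lengths are clamped with the deficit on the sister edge", {
  # a distance matrix known to induce a negative NJ branch estimate
  d <- matrix(c(0, 0.1, 1, 1.05,
                0.1, 0, 1.1, 1,
                1, 1.1, 0, 0.02,
                1.05, 1, 0.02, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("midpoint rooting halves the diameter and matches brute-force edge search", {
  # two leaves joined by branches 1 and 3: root splits the path 2 + 2
  t2 <- ape::read.tree(text = "((a:1,b:3):0,c:0);")
  r2 <- midpoint_root(t2)
  dep <- ape::node.depth.edgelength(r2)
  expect_equal(max(dep[seq_len(3)]), 2)

  set.seed(31)
  for (i in 1:50) {
    tr <- ape::unroot(ape::rtree(sample(4:10, 1)))
    rooted <- midpoint_root(tr)
    ntip <- length(tr$tip.label)
    depths <- ape::node.depth.edgelength(rooted)[seq_len(ntip)]
    expect_equal(max(depths), oracle_minmax_depth(tr), tolerance = 1e-8)
    # ... which equals half the tree diameter
    expect_equal(max(depths), max(ape::cophenetic.phylo(tr)) / 2,
                 tolerance = 1e-8)
  }

  tz <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  expect_warning(midpoint_root(ape::unroot(tz)), "zero")
})

test_that("bootstrap supports separate planted deep clades and are seed-reproducible", {
  fam <- simulate_chain_families(seed = 32, between = 0.5, within = 0.02)
  bt <- bootstrap_support(fam, n_reps = 100, seed = 99)
  cl <- attr(fam, "clades")
  for (lab in names(cl)) {
    mono <- is_monophyletic(bt, cl[[lab]])
    expect_true(mono$monophyletic)
    expect_gte(as.numeric(mono$support), 95)
  }
  bt2 <- bootstrap_support(fam, n_reps = 100, seed = 99)
  expect_identical(bt$node.label, bt2$node.label)
  expect_identical(ape::write.tree(bt), ape::write.tree(bt2))

  # degenerate: identical sequences still produce a tree without error
  same <- new_msa(setNames(rep(substr(fam[[1]], 1, 40), 4), paste0("t", 1:4)))
  expect_s3_class(suppressWarnings(bootstrap_support(same, n_reps = 5,
                                                     seed = 1)), "phylo")
})

test_that("bootstrap supports are equivariant under leaf relabeling", {
  fam <- simulate_chain_families(seed = 33)
  cl <- attr(fam, "clades")
  perm <- sample(seq_along(fam))
  fam2 <- new_msa(unclass(fam)[perm])
  b1 <- bootstrap_support(fam, n_reps = 50, seed = 7)
  b2 <- bootstrap_support(fam2, n_reps = 50, seed = 7)
  for (lab in names(cl)) {
    expect_identical(is_monophyletic(b1, cl[[lab]])$support,
                     is_monophyletic(b2, cl[[lab]])$support)
  }
})

test_that("monophyly testing returns the smallest containing clade", {
  tr <- midpoint_root(nj_tree(distance_matrix(
    simulate_chain_families(seed = 34, n_per_clade = 3))))
  a_tips <- paste0("A_", 1:3)
  b_tips <- paste0("B_", 1:3)
  expect_true(is_monophyletic(tr, a_tips)$monophyletic)
  expect_true(is_monophyletic(tr, b_tips)$monophyletic)
  mixed <- is_monophyletic(tr, c("A_1", "B_1"))
  expect_false(mixed$monophyletic)
  expect_gt(length(mixed$clade), 2L)
  expect_true(is_monophyletic(tr, "A_1")$monophyletic)
  expect_true(is_monophyletic(tr, tr$tip.label)$monophyletic)
  expect_error(is_monophyletic(tr, "nope"), "unknown leaf")
})

test_that("chain-type assignment picks the nearest reference with documented tie-breaks", {
  set.seed(35)
  refs <- c(A = random_protein(150), B = random_protein(150),
            L2 = random_protein(220))
  expect_identical(assign_chain_type(refs[["L2"]], refs)$type, "L2")
  mut <- unclass(evolve_protein(refs[["L2"]], 0.1))[[1]]
  expect_identical(assign_chain_type(mut, refs)$type, "L2")
  # exact tie between a coarse chain and a subtype prefers the coarse chain
  tie_refs <- c(A1 = refs[["A"]], A = refs[["A"]])
  expect_identical(assign_chain_type(refs[["A"]], tie_refs)$type, "A")
  expect_error(assign_chain_type("MA", c(Z9 = "MA")), "chain types")
})
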
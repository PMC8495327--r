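# AAF distances, NJ, bootstrap, identity trees, RF, polyploid topology
# classification, maternal inference, age scaling.

test_that("aaf_distance is a symmetric premetric with a cap", {
  set.seed(8)
  g <- random_dna(20000, 0.4)
  p <- build_profile(g, k = 21)
  expect_equal(aaf_distance(p, p), 0)
  q <- build_profile(random_dna(20000, 0.4), k = 21)
  expect_equal(aaf_distance(p, q), aaf_distance(q, p))
  expect_gte(aaf_distance(p, q), 0)
  # disjoint profiles -> cap
  a <- build_profile(strrep("A", 100), k = 21)
  b <- build_profile(strrep("C", 100), k = 21)
  expect_equal(aaf_distance(a, b, d_cap = 1), 1)
  expect_equal(aaf_distance(a, b, d_cap = 0.5), 0.5)
  # k mismatch and empty profiles are errors
  expect_error(aaf_distance(p, build_profile(g, k = 17)), "different k")
  expect_error(aaf_distance(p, build_profile(character(0), k = 21)), "empty")
})

test_that("aaf_distance recovers JC distances and increases with divergence", {
  set.seed(13)
  g <- random_dna(50000, 0.4)
  p0 <- build_profile(g, k = 21)
  dhat <- vapply(c(0.01, 0.02, 0.05, 0.1), function(d) {
    m <- skimploid:::jc_mutate_cpp(g, skimploid:::jc_subst_prob(d))
    aaf_distance(p0, build_profile(m, k = 21))
  }, numeric(1))
  expect_true(all(diff(dhat) > 0))   # strict monotonicity
  expect_lt(abs(dhat[3] - 0.05), 0.005)
})

test_that("neighbor_joining matches closed forms and recovers additive trees", {
  # 3 taxa: branch to A = (D_AB + D_AC - D_BC) / 2
  D <- matrix(c(0, .3, .5, .3, 0, .6, .5, .6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(bl[["A"]], (.3 + .5 - .6) / 2)
  expect_equal(bl[["B"]], (.3 + .6 - .5) / 2)
  expect_equal(bl[["C"]], (.5 + .6 - .3) / 2)
  # additive matrix from ((A,B),(C,D)) with all branches 1
  D4 <- matrix(c(0, 2, 3, 3,  2, 0, 3, 3,  3, 3, 0, 2,  3, 3, 2, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  t4 <- neighbor_joining(D4)
  ref <- ape::read.tree(text = "((A:1,B:1):1,C:1,D:1);")
  expect_equal(robinson_foulds(t4, ref), 0)
  expect_equal(sort(t4$edge.length), c(1, 1, 1, 1, 1))
  expect_error(neighbor_joining(D4[1:2, 1:2]), ">= 3")
})

test_that("NJ is consistent on random additive matrices (path-sum oracle)", {
  set.seed(99)
  ok <- vapply(1:25, function(i) {
    tr <- ape::rtree(8, br = function(n) runif(n, 0.05, 1))
    D <- ape::cophenetic.phylo(tr)
    D <- D[sort(rownames(D)), sort(colnames(D))]
    robinson_foulds(neighbor_joining(D), ape::unroot(tr)) == 0
  }, logical(1))
  expect_true(all(ok))
})

test_that("robinson_foulds counts asymmetric bipartitions", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(robinson_foulds(t1, t1), 0)
  expect_equal(robinson_foulds(t1, t2), 2)
  expect_error(robinson_foulds(t1, ape::read.tree(text = "((A,B),(C,E));")),
               "leaf sets")
})

test_that("robinson_foulds agrees with an independent implementation", {
  # all 5-taxon topologies x a sample of pairs, oracle = phangorn::RF.dist
  trees <- phangorn::allTrees(5, rooted = FALSE,
                              tip.label = paste0("t", 1:5))
  set.seed(3)
  for (i in 1:40) {
    a <- trees[[sample(length(trees), 1)]]
    b <- trees[[sample(length(trees), 1)]]
    expect_equal(robinson_foulds(a, b), as.numeric(phangorn::RF.dist(a, b)))
  }
})

test_that("bootstrap supports are deterministic and saturate on clean data", {
  set.seed(17)
  root <- random_dna(8000, 0.4)
  seqs <- list()
  for (nm in c("a1", "a2", "b1", "b2"))
    seqs[[nm]] <- skimploid:::jc_mutate_cpp(root, skimploid:::jc_subst_prob(
      c(a1 = 0.004, a2 = 0.005, b1 = 0.054, b2 = 0.055)[[nm]]))
  profs <- lapply(seqs, build_profile, k = 21)
  b1 <- bootstrap_supports(profs, B = 30, seed = 7)
  b2 <- bootstrap_supports(profs, B = 30, seed = 7)
  expect_identical(b1$supports, b2$supports)
  # well-separated clades: the true split gets full support
  expect_true(all(b1$supports$support >= 95))
  # B replicates of identical profiles -> all supports 100
  same <- list(x = profs[[1]], y = profs[[1]], z = profs[[2]], w = profs[[3]])
  expect_true(all(bootstrap_supports(same, B = 5, seed = 1)$supports$support == 100))
})

test_that("global_identity computes NW identity over alignment columns", {
  set.seed(23)
  s <- random_dna(1000, 0.5)
  expect_equal(global_identity(s, s), 100)
  t <- s; substr(t, 500, 500) <- if (substr(t, 500, 500) == "A") "C" else "A"
  expect_equal(global_identity(s, t), 99.9)
  # one 5-bp deletion in 1,000 bp -> 995 matches / 1,000 columns
  del <- paste0(substr(s, 1, 400), substr(s, 406, 1000))
  expect_equal(global_identity(s, del), 99.5)
})

test_that("identity_tree recovers the generating topology and matches AAF", {
  set.seed(29)
  ts <- species_tree_spec(
    "((v:0.01,w:0.012):0.02,((x:0.015,y:0.01):0.01,z:0.03):0.01);")
  tr <- ape::reorder.phylo(ts$tree, "cladewise")
  ntip <- 5L
  states <- vector("list", ntip + tr$Nnode)
  states[[ntip + 1L]] <- random_dna(4000, 0.4)
  for (e in seq_len(nrow(tr$edge)))
    states[[tr$edge[e, 2]]] <- skimploid:::jc_mutate_cpp(
      states[[tr$edge[e, 1]]], skimploid:::jc_subst_prob(tr$edge.length[e]))
  seqs <- setNames(unlist(states[1:ntip]), tr$tip.label)
  it <- identity_tree(seqs)
  expect_equal(robinson_foulds(it, ts$tree), 0)
  # identical sequences -> star tree with zero lengths
  star <- identity_tree(c(a = seqs[[1]], b = seqs[[1]], c = seqs[[1]]))
  expect_true(all(star$edge.length == 0))
  # cross-method congruence with the AAF tree on the same sequences
  at <- neighbor_joining(aaf_distance_matrix(
    lapply(seqs, build_profile, k = 21)))
  expect_equal(robinson_foulds(it, at), 0)
})

test_that("classify_polyploid_topology labels sister-group membership", {
  cI <- c("a1", "a2"); cII <- c("b1", "b2")
  t1 <- ape::read.tree(text = "((P,(a1,a2)),(b1,b2),o);")
  expect_equal(classify_polyploid_topology(t1, "P", cI, cII), "cladeI_like")
  t2 <- ape::read.tree(text = "((a1,a2),(P,(b1,b2)),o);")
  expect_equal(classify_polyploid_topology(t2, "P", cI, cII), "cladeII_like")
  # attached between both clades -> unresolved
  t3 <- ape::read.tree(text = "((a1,a2),P,(b1,b2));")
  expect_equal(classify_polyploid_topology(t3, "P", cI, cII), "unresolved")
  # a sister polyploid is skipped when finding the enclosing diploid group
  t4 <- ape::read.tree(text = "(((P,Q),(a1,a2)),(b1,b2),o);")
  expect_equal(classify_polyploid_topology(t4, "P", cI, cII), "cladeI_like")
  expect_error(classify_polyploid_topology(t1, "missing", cI, cII), "absent")
})

test_that("infer_maternal_parent takes the argmin with a tie set", {
  D <- matrix(c(0, .001, .05, .001, 0, .049, .05, .049, 0), 3, 3,
              dimnames = list(c("P", "A", "B"), c("P", "A", "B")))
  r <- infer_maternal_parent(D, "P", c("A", "B"), rel_tolerance = 0.1)
  expect_equal(r$maternal, "A")
  expect_equal(r$ties, "A")
  # near-equal distances are reported as a tie set
  D2 <- D; D2["P", "B"] <- D2["B", "P"] <- 0.00105
  r2 <- infer_maternal_parent(D2, "P", c("A", "B"), rel_tolerance = 0.1)
  expect_setequal(r2$ties, c("A", "B"))
})

test_that("scale_tree_ages calibrates the root exactly and keeps ratios", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1.5,D:1.5):0.5);")
  dated <- scale_tree_ages(tr, root_age = 12.4)
  ages <- attr(dated, "node_ages")
  expect_equal(max(ages), 12.4)
  # node heights 2 : 1 : 1.5 -> ages 12.4 : 6.2 : 9.3
  expect_setequal(round(ages, 6), round(c(12.4, 6.2, 9.3), 6))
  # leaves at age zero: root-to-tip path = root age
  depths <- ape::node.depth.edgelength(dated)
  expect_equal(unique(round(depths[1:4], 9)), 12.4)
  expect_error(scale_tree_ages(ape::read.tree(text = "(A:0,B:0);")), "root height")
})
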
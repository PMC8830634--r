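sp3 <- read_newick("((A,B)AB,C)R;")
sp2 <- read_newick("(A,B)R;")

test_that("a congruent single-copy tree reconciles with zero cost", {
  G <- read_newick("((A|g1,B|g1),C|g1);")
  r <- lca_reconcile(G, sp3)
  expect_equal(r$total_cost, 0L)
  expect_true(all(r$gains_per_branch == 0))
  expect_true(all(r$losses_per_branch == 0))
  expect_true(all(r$ancestral_copies == 1))
  expect_true(all(r$node_events$event == "speciation"))
})

test_that("a within-species duplication is charged to that species branch", {
  G <- read_newick("((A|a1,A|a2),B|b1);")
  r <- lca_reconcile(G, sp2)
  expect_equal(sum(r$gains_per_branch), 1L)
  expect_equal(unname(r$gains_per_branch["A"]), 1L)
  expect_equal(sum(r$losses_per_branch), 0L)
  expect_equal(r$total_cost, 1L)
  expect_equal(brute_force_dl_cost(G, sp2), 1L)
})

test_that("a family absent from one subtree is charged one stem loss", {
  G <- read_newick("(A|a1,B|b1);")
  r <- lca_reconcile(G, sp3)
  expect_equal(sum(r$gains_per_branch), 0L)
  expect_equal(unname(r$losses_per_branch["C"]), 1L)
  expect_equal(r$total_cost, 1L)
  expect_equal(brute_force_dl_cost(G, sp3), 1L)
  expect_equal(unname(r$ancestral_copies["C"]), 0L)
})

test_that("an ancient duplication maps above the species split", {
  G <- read_newick("((A|a1,B|b1),(A|a2,B|b2));")
  r <- lca_reconcile(G, sp2)
  expect_equal(r$total_cost, 1L)
  expect_equal(unname(r$gains_per_branch["R"]), 1L)
  expect_equal(unname(r$ancestral_copies["R"]), 2L)
  expect_equal(brute_force_dl_cost(G, sp2), 1L)
})

test_that("the LCA cost matches brute force on enumerated small trees", {
  sa <- famevol:::species_arrays(sp3)
  for (n in 2:4) {
    for (t in enumerate_gene_trees(n)) {
      ga <- nested_to_gene_arrays(t, sa)
      mine <- famevol:::reconcile_core(ga, sa)$total
      oracle <- famevol:::cpp_brute_min_cost(ga$kids, ga$species, ga$root,
                                             sa$lca, sa$depth, sa$anc)
      expect_equal(mine, oracle)
    }
  }
})

test_that("the fast C++ cost kernel agrees with the R reconciliation", {
  set.seed(31)
  sa <- famevol:::species_arrays(default_species_tree())
  for (i in 1:20) {
    sim <- simulate_gene_tree(default_species_tree(), 0.3, 0.1)
    if (sim$extinct || length(sim$tree$tip.label) < 2) next
    r <- lca_reconcile(sim$tree, default_species_tree())
    ga <- r$gene_arrays
    expect_equal(famevol:::cpp_dl_cost(ga$kids, ga$species, ga$root,
                                       sa$lca, sa$depth),
                 r$total_cost)
  }
})

test_that("total cost is invariant under species-preserving relabeling", {
  G1 <- read_newick("(((A|x,A|y),B|b1),(C|c1,A|z));")
  G2 <- read_newick("(((A|p,A|q),B|k9),(C|m2,A|r));")
  expect_equal(lca_reconcile(G1, sp3)$total_cost,
               lca_reconcile(G2, sp3)$total_cost)
})

test_that("a trifurcation resolves congruently at zero cost", {
  G <- read_newick("(A|a1,B|b1,C|c1);")
  res <- resolve_polytomies_min_cost(G, sp3)
  expect_true(ape::is.binary(res))
  expect_equal(lca_reconcile(res, sp3)$total_cost, 0L)
  expect_equal(exhaustive_resolution_cost(G, sp3), 0L)
  # already binary input is unchanged
  Gb <- read_newick("((A|a1,B|b1),C|c1);")
  expect_equal(ape::dist.topo(resolve_polytomies_min_cost(Gb, sp3), Gb),
               0, ignore_attr = TRUE)
})

test_that("polytomy resolution matches the exhaustive oracle", {
  set.seed(17)
  for (i in 1:25) {
    G <- read_newick(random_multifurcating_tree(sample(4:7, 1)))
    res <- resolve_polytomies_min_cost(G, sp3)
    expect_true(ape::is.binary(res))
    expect_equal(lca_reconcile(res, sp3)$total_cost,
                 exhaustive_resolution_cost(G, sp3))
  }
})

test_that("resolution cost never exceeds that of random resolutions", {
  set.seed(23)
  for (i in 1:5) {
    G <- read_newick(random_multifurcating_tree(6))
    best <- lca_reconcile(resolve_polytomies_min_cost(G, sp3),
                          sp3)$total_cost
    for (j in 1:20) {
      rand <- ape::multi2di(G, random = TRUE)
      expect_lte(best, lca_reconcile(rand, sp3)$total_cost)
    }
  }
})

test_that("rooting minimises cost and a zero-cost rooting is found", {
  G <- ape::unroot(read_newick("((A|g1,B|g1),C|g1);"))
  rooted <- root_for_min_cost(G, sp3)
  expect_equal(lca_reconcile(rooted, sp3)$total_cost, 0L)
  # two parallel single-copy families: any central rooting costs 1 dup
  G2 <- read_newick("((A|a1,B|b1),(A|a2,B|b2));")
  rooted2 <- root_for_min_cost(ape::unroot(G2), sp2)
  expect_equal(lca_reconcile(rooted2, sp2)$total_cost, 1L)
  # exhaustive check: no rooting beats the returned one
  adj <- famevol:::tree_adjacency(ape::unroot(G2))
  sa <- famevol:::species_arrays(sp2)
  ids <- famevol:::species_id_lookup(sa, leaf_species_map(G2$tip.label))
  costs <- vapply(seq_len(nrow(adj$edges)), function(e) {
    rt <- famevol:::root_at_edge(adj, e)
    ga <- famevol:::rtree_arrays(rt, ids)
    famevol:::cpp_dl_cost(ga$kids, ga$species, ga$root, sa$lca, sa$depth)
  }, 0L)
  expect_equal(min(costs), 1L)
})

test_that("rooting is deterministic", {
  G <- ape::unroot(read_newick("((A|a1,B|b1),(A|a2,(B|b2,C|c1)));"))
  expect_identical(ape::write.tree(root_for_min_cost(G, sp3)),
                   ape::write.tree(root_for_min_cost(G, sp3)))
})

test_that("collapsing then resolving never costs more than the binary tree", {
  set.seed(41)
  S <- default_species_tree()
  for (i in 1:10) {
    sim <- simulate_gene_tree(S, 0.3, 0.15)
    if (sim$extinct || length(sim$tree$tip.label) < 4) next
    G <- sim$tree
    binary_cost <- lca_reconcile(G, S)$total_cost
    # plant random supports, collapse and re-resolve
    G$node.label <- as.character(sample(c(20, 50, 95, 100), G$Nnode, TRUE))
    cond <- collapse_low_support(G, 70)
    res <- resolve_polytomies_min_cost(cond, S)
    expect_lte(lca_reconcile(res, S)$total_cost, binary_cost)
  }
})

test_that("genus-specific expansion shows up in ancestral copy numbers", {
  S <- default_species_tree()
  # one gene everywhere, but three copies in each Acyrthosiphon species
  # from two duplications on the genus stem
  acy <- paste0("(((A_pisum|g1,A_kondoi|g1),(A_pisum|g2,A_kondoi|g2)),",
                "(A_pisum|g3,A_kondoi|g3))")
  G <- read_newick(paste0(
    "(((", acy, ",S_avenae|g1),(M_persicae|g1,D_noxia|g1)),",
    "((A_glycines|g1,A_gossypii|g1),(R_padi|g1,S_graminum|g1)));"))
  r <- lca_reconcile(G, S)
  cp <- ancestral_copy_numbers(r)
  expect_equal(unname(cp["Acyrthosiphon"]), 3L)
  expect_true(all(cp[setdiff(names(cp), c("Acyrthosiphon", "A_pisum",
                                          "A_kondoi"))] == 1))
  expect_equal(unname(r$gains_per_branch["Acyrthosiphon"]), 2L)
})

test_that("leaf copy numbers always satisfy the propagation identity", {
  set.seed(53)
  S <- default_species_tree()
  sa <- famevol:::species_arrays(S)
  for (i in 1:10) {
    sim <- simulate_gene_tree(S, 0.25, 0.1)
    if (sim$extinct || length(sim$tree$tip.label) < 2) next
    r <- lca_reconcile(sim$tree, S)
    cp <- ancestral_copy_numbers(r)
    for (v in seq_len(sa$ntip)) {
      parent <- sa$names[sa$parent[v]]
      leaf <- sa$names[v]
      expect_equal(cp[[leaf]],
                   cp[[parent]] + r$gains_per_branch[[leaf]] -
                     r$losses_per_branch[[leaf]])
    }
  }
})
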
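test_that("the default species tree has the expected clades", {
  S <- default_species_tree()
  expect_equal(sort(S$tip.label),
               sort(c("A_pisum", "A_kondoi", "S_avenae", "M_persicae",
                      "D_noxia", "A_glycines", "A_gossypii", "R_padi",
                      "S_graminum")))
  expect_true(ape::is.binary(S) && ape::is.rooted(S))
  expect_true(ape::is.ultrametric(S))
  clade_of <- function(tips) {
    node <- ape::getMRCA(S, tips)
    sort(ape::extract.clade(S, node)$tip.label)
  }
  # the Acyrthosiphon genus is a clade and its sister group holds S_avenae
  expect_equal(clade_of(c("A_pisum", "A_kondoi")), c("A_kondoi", "A_pisum"))
  expect_equal(clade_of(c("A_pisum", "A_kondoi", "S_avenae")),
               c("A_kondoi", "A_pisum", "S_avenae"))
  # the Aphis genus is a clade
  expect_equal(clade_of(c("A_glycines", "A_gossypii")),
               c("A_glycines", "A_gossypii"))
})

test_that("a zero-rate family gives one congruent copy per species", {
  S <- default_species_tree()
  sim <- simulate_gene_tree(S, 0, 0, root_copies = 1, rng_seed = 1)
  expect_false(sim$extinct)
  expect_equal(nrow(sim$extant), 9L)
  expect_equal(sort(sim$extant$species), sort(S$tip.label))
  expect_true(all(sim$births == 0) && all(sim$losses == 0))
  relab <- sim$tree
  relab$tip.label <- sub("\\|.*$", "", relab$tip.label)
  expect_equal(ape::dist.topo(ape::unroot(relab), ape::unroot(S)), 0,
               ignore_attr = TRUE)
  expect_equal(lca_reconcile(sim$tree, S)$total_cost, 0L)
})

test_that("no loss events are recorded when mu = 0", {
  for (seed in 1:5) {
    sim <- simulate_gene_tree(default_species_tree(), 0.4, 0,
                              rng_seed = seed)
    expect_true(all(sim$losses == 0))
    expect_false(sim$extinct)
  }
})

test_that("per-leaf event bookkeeping is exact", {
  S <- default_species_tree()
  sp <- famevol:::species_rtree_named(S)
  check <- function(sim, root_copies) {
    walk <- function(nd, path) {
      path <- c(path, nd$label)
      if (length(nd$kids) == 0L) {
        onpath <- path[-1]                     # branches below the root
        expect_equal(sum(sim$extant$species == nd$label),
                     root_copies + sum(sim$births[onpath]) -
                       sum(sim$losses[onpath]))
      } else {
        for (k in nd$kids) walk(k, path)
      }
    }
    walk(sp, character(0))
  }
  for (seed in 1:10) {
    rc <- 1L + seed %% 3L
    sim <- simulate_gene_tree(S, 0.35, 0.2, root_copies = rc,
                              rng_seed = 100 + seed)
    check(sim, rc)
  }
})

test_that("mean extant copies match the birth-death expectation", {
  # depth-3 two-species tree, lambda = 0.3, mu = 0.1: E[N] = e^{0.2 * 3}
  S <- read_newick("(A:3,B:3)R;")
  set.seed(77)
  counts <- replicate(2000, {
    sim <- simulate_gene_tree(S, 0.3, 0.1)
    sum(sim$extant$species == "A")
  })
  expected <- exp((0.3 - 0.1) * 3)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("sequence evolution is seeded, rate-0-exact and saturating", {
  tr <- read_newick("(A|x:0.5,B|y:1.5);")
  root <- random_protein(200, seed = 3)
  p0 <- simulate_sequences(tr, root, 0, rng_seed = 5)
  expect_true(all(p0$sequence == root))
  p1 <- simulate_sequences(tr, root, 0.5, rng_seed = 5)
  p2 <- simulate_sequences(tr, root, 0.5, rng_seed = 5)
  expect_identical(p1$sequence, p2$sequence)
  expect_false(all(p1$sequence == root))
  # observed divergence from the root tracks the saturation curve
  tr2 <- read_newick("(A|far:0.5,B|anchor:0);")
  rootL <- random_protein(2000, seed = 8)
  sim <- simulate_sequences(tr2, rootL, 1, rng_seed = 9)
  p_obs <- mean(strsplit(sim$sequence[sim$gene_id == "far"], "")[[1]] !=
                  strsplit(rootL, "")[[1]])
  p_exp <- (19 / 20) * (1 - exp(-(20 / 19) * 0.5))
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 2000))
  # anchor tip at distance 0 is the root sequence
  expect_equal(sim$sequence[sim$gene_id == "anchor"], rootL)
})

test_that("the JTT model runs and diverges more slowly than Poisson at
           matched rate-time", {
  tr <- read_newick("(A|x:1,B|y:0);")
  root <- random_protein(1500, seed = 2)
  pj <- simulate_sequences(tr, root, 1, model = "jtt", rng_seed = 3)
  expect_equal(nchar(pj$sequence[1]), 1500L)
  dj <- mean(strsplit(pj$sequence[pj$gene_id == "x"], "")[[1]] !=
               strsplit(root, "")[[1]])
  expect_true(dj > 0.3 && dj < 0.75)
})

test_that("decoys are appended with disjoint ids and no domains", {
  prot <- list(sp1 = tiny_proteome(random_protein(60), species = "sp1"),
               sp2 = tiny_proteome(random_protein(60), species = "sp2"))
  out <- add_decoys(prot, 3, c(50, 80), rng_seed = 4)
  expect_equal(nrow(out$sp1), 4L)
  expect_equal(sum(grepl("^decoy_", out$sp2$gene_id)), 3L)
  expect_length(intersect(prot$sp1$gene_id, paste0("decoy_0", 1:3)), 0)
  expect_identical(add_decoys(prot, 0), prot)
  study <- cached_default_study()
  decoy_labels <- unlist(lapply(study$proteomes, function(p) {
    full_id(p[grepl("^decoy_", p$gene_id), ])
  }))
  expect_length(intersect(decoy_labels, names(study$domains)), 0)
})

test_that("fixtures regenerate byte-identically with validated checksums", {
  cfg <- default_sim_config(seed = 42)
  cfg$families <- cfg$families[3, ]            # one slow family: fast
  cfg$subfamilies <- cfg$subfamilies["GST"]
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- make_fixture(cfg, d1)
  m2 <- make_fixture(cfg, d2)
  expect_equal(m1$md5, m2$md5)
  recomputed <- unname(tools::md5sum(file.path(d1, m1$file)))
  expect_equal(recomputed, m1$md5)
})

test_that("higher substitution rates give lower among-species identity", {
  study <- cached_default_study()
  means <- vapply(c("P450", "CCE", "GST"), function(fam) {
    members <- do.call(rbind, lapply(study$proteomes, function(p) {
      p[p$family %in% fam, , drop = FALSE]
    }))
    mean(suppressWarnings(among_species_identities(members))$values)
  }, 0)
  # planted rates: P450 0.15 > CCE 0.08 > GST 0.03
  expect_true(means[["P450"]] < means[["CCE"]])
  expect_true(means[["CCE"]] < means[["GST"]])
})
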
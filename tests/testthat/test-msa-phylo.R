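test_that("identical sequences align without gaps", {
  p <- tiny_proteome(rep(random_protein(50, seed = 3), 4)[1:4])
  al <- progressive_msa(p)
  expect_equal(nchar(al$seqs[1]), 50L)
  expect_true(all(!grepl("-", al$seqs, fixed = TRUE)))
  expect_equal(length(unique(al$seqs)), 1L)
})

test_that("two records reduce to the pairwise global alignment", {
  a <- "MKVLITAGPTREPLDPVRYISNRSSGKMGYAI"
  b <- sub("REPL", "", a)            # internal deletion
  al <- progressive_msa(tiny_proteome(a, b))
  expect_equal(gsub("-", "", al$seqs[2], fixed = TRUE), b)
  expect_equal(al$seqs[1], a)        # longer sequence is gap-free
  expect_equal(nchar(al$seqs[1]), nchar(al$seqs[2]))
})

test_that("MSA width is at least the longest input", {
  set.seed(9)
  seqs <- vapply(1:5, function(i) random_protein(sample(40:60, 1)), "")
  al <- progressive_msa(tiny_proteome(seqs))
  expect_gte(nchar(al$seqs[1]), max(nchar(seqs)))
  expect_error(progressive_msa(tiny_proteome("MKV")), "at least 2")
})

test_that("gap-rich columns are trimmed at the configured threshold", {
  al <- msa(c("a", "b", "c", "d"),
            c("MK-V", "MKAV", "MK-V", "MK-V"))
  out <- trim_poor_columns(al, 0.5)
  expect_equal(out$seqs, c("MKV", "MKV", "MKV", "MKV"),
               ignore_attr = TRUE)
  expect_equal(trim_poor_columns(al, 1.0)$seqs, al$seqs)
  gapfree <- msa(c("a", "b"), c("MKV", "MKV"))
  expect_equal(trim_poor_columns(gapfree, 0.5)$seqs, gapfree$seqs)
  allgap <- msa(c("a", "b", "c"), c("-A", "-A", "B-"))
  expect_error(trim_poor_columns(allgap, 0.2), "every column")
})

test_that("Poisson-corrected distances follow the closed form", {
  al <- msa(c("a", "b"), c("AAAA", "AAAA"))
  expect_equal(msa_distances(al)["a", "b"], 0)
  al2 <- msa(c("a", "b"), c("AACC", "AADD"))   # p = 0.5
  expect_equal(msa_distances(al2)["a", "b"], log(2))
  # monotone in p, and capped
  p_of <- function(k) {
    s1 <- paste(rep("A", 10), collapse = "")
    s2 <- paste(c(rep("C", k), rep("A", 10 - k)), collapse = "")
    msa_distances(msa(c("a", "b"), c(s1, s2)))["a", "b"]
  }
  d <- vapply(0:9, p_of, 0)
  expect_true(all(diff(d) > 0))
  expect_equal(p_of(10), 10)        # p = 1 hits the cap
})

test_that("neighbor joining solves the three-taxon closed form", {
  # leaf edge lengths a=2, b=3, c=4 give the additive matrix below
  D <- matrix(c(0, 5, 6, 5, 0, 7, 6, 7, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  el <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(el[c("A", "B", "C")], c(A = 2, B = 3, C = 4))
})

test_that("neighbor joining recovers additive quartets (LS oracle)", {
  set.seed(4)
  for (rep in 1:10) {
    tr0 <- ape::rtree(4, br = function(n) runif(n, 0.5, 2))
    D <- ape::cophenetic.phylo(tr0)
    # oracle: least-squares fit over the three quartet topologies
    tips <- rownames(D)
    fits <- vapply(list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3)),
                   function(q) {
      ab <- D[tips[q[1]], tips[q[2]]] ; cd <- D[tips[q[3]], tips[q[4]]]
      ac <- D[tips[q[1]], tips[q[3]]] ; bd <- D[tips[q[2]], tips[q[4]]]
      ad <- D[tips[q[1]], tips[q[4]]] ; bc <- D[tips[q[2]], tips[q[3]]]
      max(0, (ac + bd + ad + bc) / 2 - ab - cd)   # 2x internal edge, >= 0
    }, 0)
    best <- which.max(fits)
    pair <- list(c(1, 2), c(1, 3), c(1, 4))[[best]]
    tr <- neighbor_joining(D)
    # the oracle's cherry must be a cherry in the NJ tree
    keys <- famevol:::bipartition_keys(tr)
    expect_true(paste(sort(setdiff(tips, tips[pair])), collapse = ",") %in%
                  keys ||
                paste(sort(tips[pair]), collapse = ",") %in% keys)
    expect_equal(ape::dist.topo(ape::unroot(tr0), tr), 0,
                 ignore_attr = TRUE)
  }
})

test_that("neighbor joining is invariant to input label order", {
  set.seed(11)
  tr0 <- ape::rtree(6, br = function(n) runif(n, 0.5, 2))
  D <- ape::cophenetic.phylo(tr0)
  tr1 <- neighbor_joining(D)
  perm <- sample(nrow(D))
  tr2 <- neighbor_joining(D[perm, perm])
  expect_equal(ape::dist.topo(tr1, tr2), 0, ignore_attr = TRUE)
  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")
  D2 <- D; D2[1, 2] <- D2[2, 1] <- Inf
  expect_error(neighbor_joining(D2), "non-finite")
})

test_that("bootstrap supports are reproducible, bounded, and strong for
           deeply divergent clades", {
  tr <- read_newick(
    "((A|x:0.05,A|y:0.05):1.0,(B|v:0.05,B|w:0.05):1.0);")
  set.seed(2)
  prot <- simulate_sequences(tr, random_protein(500), rate = 1)
  al <- progressive_msa(prot)
  t1 <- bootstrap_supports(al, n_reps = 100, rng_seed = 99)
  t2 <- bootstrap_supports(al, n_reps = 100, rng_seed = 99)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  sup <- suppressWarnings(as.numeric(t1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  expect_gte(max(sup), 95)   # the central split is essentially certain
})

test_that("bootstrap supports do not depend on row order", {
  set.seed(5)
  seqs <- vapply(1:5, function(i) mutate_seq(random_protein(80), 0.2), "")
  al <- msa(paste0("s", 1:5), seqs)
  perm <- c(3, 1, 5, 2, 4)
  al2 <- msa(al$ids[perm], al$seqs[perm])
  t1 <- bootstrap_supports(al, n_reps = 50, rng_seed = 7)
  t2 <- bootstrap_supports(al2, n_reps = 50, rng_seed = 7)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})
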
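test_that("a seed identical to a target protein is a perfect hit", {
  target_seq <- random_protein(200, seed = 10)
  target <- proteome(c("t1", "t2"), "sp2",
                     c(target_seq, random_protein(180)))
  seeds <- proteome("s1", "sp1", target_seq)
  hits <- seed_search(seeds, target)
  self <- hits[hits$sseqid == "sp2|t1", ]
  expect_equal(nrow(self), 1L)
  expect_equal(self$pident, 100)
  expect_lte(self$evalue, 1e-5)
})

test_that("relaxing the E-value threshold never removes hits", {
  set.seed(12)
  seeds <- tiny_proteome(random_protein(150), species = "sp1")
  target <- proteome(paste0("t", 1:6), "sp2", c(
    mutate_seq(seeds$sequence, 0.2), mutate_seq(seeds$sequence, 0.5),
    mutate_seq(seeds$sequence, 0.7), vapply(1:3, function(i)
      random_protein(150), "")))
  strict <- seed_search(seeds, target, search_params(1e-5))
  loose <- seed_search(seeds, target, search_params(1e-3))
  key <- function(h) paste(h$qseqid, h$sseqid)
  expect_true(all(key(strict) %in% key(loose)))
})

test_that("a random sequence finds nothing in a simulated family", {
  set.seed(1)
  fam_root <- random_protein(300)
  fam <- proteome(sprintf("f%02d", 1:50), "sp2",
                  vapply(1:50, function(i) mutate_seq(fam_root, 0.3), ""))
  probe <- proteome("probe", "sp1", random_protein(300))
  hits <- seed_search(probe, fam, search_params(1e-5))
  expect_equal(nrow(hits), 0L)
})

test_that("an empty target proteome warns and returns no hits", {
  seeds <- tiny_proteome(random_protein(100), species = "sp1")
  empty <- proteome(character(), character(), character())
  expect_warning(hits <- seed_search(seeds, empty), "empty target")
  expect_equal(nrow(hits), 0L)
})

test_that("reciprocal expansion recovers chain homologs found only
           through the intermediate species", {
  # A = X+Y, B = Y+Z, C = Z+W: A-B and B-C share a 150-residue block,
  # A-C share nothing
  set.seed(33)
  X <- random_protein(150); Y <- random_protein(150)
  Z <- random_protein(150); W <- random_protein(150)
  seed_prot <- proteome(c("A", "C"), "sp1",
                        c(paste0(X, Y), paste0(Z, W)))
  target_prot <- proteome("B", "sp2", paste0(Y, Z))
  seeds <- seed_prot[1, ]                      # only A is a known seed
  r1 <- seed_search(seeds, target_prot)
  expect_equal(unique(r1$sseqid), "sp2|B")
  expect_equal(nrow(seed_search(seeds, seed_prot[2, ])), 0L)  # A !~ C
  cand <- reciprocal_expand(seed_prot, target_prot, r1)
  expect_true(all(c("B", "C") %in% cand$gene_id))
  expect_equal(cand$round_found[cand$gene_id == "B"], 1L)
  expect_equal(cand$round_found[cand$gene_id == "C"], 2L)
  # fixed point: re-applying adds nothing
  cand2 <- reciprocal_expand(seed_prot, target_prot, r1)
  expect_equal(cand2, cand)
  # empty round-1 hits give an empty candidate set
  expect_equal(nrow(reciprocal_expand(seed_prot, target_prot,
                                      famevol:::empty_hit_table())), 0L)
})

test_that("domain filtering keeps exactly the annotated candidates", {
  cand <- data.frame(species = "sp", gene_id = c("a", "b", "c"),
                     stringsAsFactors = FALSE)
  doms <- list("sp|a" = c("IPR1", "IPR9"), "sp|b" = "IPR2")
  out <- suppressMessages(domain_filter(cand, doms, "IPR1"))
  expect_equal(out$gene_id, "a")                 # b lacks it, c unknown
  all_in <- domain_filter(cand[1:2, ], doms, c("IPR1", "IPR2"))
  expect_equal(all_in, cand[1:2, ])
  expect_error(domain_filter(cand, doms, character(0)))
})

test_that("decoys are removed and true members kept on simulated data", {
  set.seed(60)
  root <- random_protein(250)
  true <- proteome(sprintf("t%02d", 1:10), "sp",
                   vapply(1:10, function(i) mutate_seq(root, 0.2), ""))
  decoys <- proteome(sprintf("d%02d", 1:5), "sp",
                     vapply(1:5, function(i) random_protein(250), ""))
  cand <- rbind(true[, c("species", "gene_id")],
                decoys[, c("species", "gene_id")])
  doms <- setNames(rep(list("IPRX"), 10), full_id(true))
  out <- suppressMessages(domain_filter(cand, doms, "IPRX"))
  expect_equal(sort(out$gene_id), sort(true$gene_id))
})

test_that("family count tables have species-ordered rows and zero fills", {
  asg <- data.frame(family = c("F1", "F1", "F1", "F2"),
                    species = c("spA", "spA", "spB", "spB"),
                    gene_id = c("a", "b", "c", "d"),
                    stringsAsFactors = FALSE)
  tab <- family_count_table(asg, species_order = c("spB", "spA", "spC"))
  expect_equal(tab$species, c("spB", "spA", "spC"))
  expect_equal(tab$F1, c(1L, 2L, 0L))
  expect_equal(tab$F2, c(1L, 0L, 0L))
  empty <- family_count_table(asg[0, ], species_order = c("spA", "spB"),
                              families = "F1")
  expect_true(all(empty$F1 == 0))
})

test_that("annotation recovers the simulated truth exactly", {
  study <- cached_default_study()
  cand <- annotate_families(study$proteomes, study$seed_sets,
                            study$domains, study$required_domains)
  found <- paste(cand$family, cand$species, cand$gene_id)
  truth <- do.call(rbind, lapply(names(study$truth$families), function(f) {
    ex <- study$truth$families[[f]]$extant
    data.frame(key = paste(f, ex$species, ex$gene_id))
  }))
  expect_setequal(found, truth$key)            # precision and recall 1
  counts <- family_count_table(cand, study$species_tree$tip.label)
  for (f in names(study$truth$families)) {
    truth_tab <- table(study$truth$families[[f]]$extant$species)
    for (sp in counts$species) {
      expected <- if (sp %in% names(truth_tab)) truth_tab[[sp]] else 0L
      expect_equal(counts[counts$species == sp, f], expected)
    }
  }
})
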
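# Birth-death simulation of gene-family histories along a species tree,
# with sequence evolution along the resulting gene trees. Gene lineages
# duplicate (rate lambda) and die (rate mu) independently with
# exponential waiting times on every species branch; lineages surviving
# to a species leaf become extant genes. Every event is recorded on its
# species branch, so extant counts satisfy, exactly,
#   count(leaf) = root_copies + births(path) - losses(path).

#' Nine-taxon aphid-like species tree
#'
#' A rooted, binary, ultrametric fixture tree (height 4 time units) with
#' labelled internal nodes: the Macrosiphini side holds the
#' (A_pisum, A_kondoi) genus clade with S_avenae as its sister plus the
#' (M_persicae, D_noxia) pair; the Aphidini side holds the
#' (A_glycines, A_gossypii) genus clade and (R_padi, S_graminum).
#' Branch lengths are integer time units chosen so that every leaf is
#' equidistant from the root.
#'
#' @return a `phylo`
#' @export
default_species_tree <- function() {
  read_newick(paste0(
    "((((A_pisum:1,A_kondoi:1)Acyrthosiphon:1,S_avenae:2)AcySav:1,",
    "(M_persicae:1,D_noxia:1)MperDnox:2)Macrosiphini:1,",
    "((A_glycines:1,A_gossypii:1)Aphis:2,",
    "(R_padi:1,S_graminum:1)RpadSgra:2)Aphidini:1)Aphidinae;"))
}

# nested species tree with guaranteed-unique node names in $label
species_rtree_named <- function(S) {
  rt <- as_rtree(S)
  k <- 0L
  fix <- function(nd) {
    if (length(nd$kids) > 0L) {
      if (!nzchar(nd$label)) {
        k <<- k + 1L
        nd$label <- paste0("N", k)
      }
      nd$kids <- lapply(nd$kids, fix)
    }
    nd
  }
  fix(rt)
}

#' Simulate a gene family along the species tree
#'
#' Linear birth-death evolution: every gene lineage on a species branch
#' draws exponential waiting times; a birth splits the lineage in two
#' (both continue on the same branch), a death removes it. Lineages
#' surviving at a species node continue into both child branches
#' (speciation); at a species leaf they become extant genes named
#' `"species|family_gNNN"`. Each of the `root_copies` independent root
#' lineages is labelled with one subfamily; with `subfamily_stem > 0` the
#' root lineages are joined above the species root by stems of that
#' length (ancient duplications predating the clade).
#'
#' @param S rooted binary species tree with branch lengths (`phylo`)
#' @param lambda,mu per-lineage birth and loss rates (>= 0)
#' @param root_copies number of independent root lineages (>= 1)
#' @param rng_seed optional seed; omit to use the current RNG stream
#' @param family family name used in gene ids
#' @param subfamilies labels for the root lineages (recycled;
#'   default "sub1", "sub2", ...)
#' @param subfamily_stem extra stem length above the species root
#' @return list with `tree` (rooted binary `phylo`, or `NULL` if the
#'   family went extinct), `births` and `losses` (named per-branch event
#'   counts; branch = name of the species node below it), `extant`
#'   (data.frame: species, gene_id, subfamily, label), `extinct` flag
#' @export
simulate_gene_tree <- function(S, lambda, mu, root_copies = 1L,
                               rng_seed = NULL, family = "fam",
                               subfamilies = NULL, subfamily_stem = 0) {
  stopifnot(lambda >= 0, mu >= 0, root_copies >= 1L)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (is.null(subfamilies)) {
    subfamilies <- paste0("sub", seq_len(root_copies))
  }
  subfamilies <- rep_len(subfamilies, root_copies)
  sp <- species_rtree_named(S)
  branch_names <- character(0)
  collect <- function(nd) {
    branch_names <<- c(branch_names, nd$label)
    for (k in nd$kids) collect(k)
  }
  collect(sp)
  births <- setNames(integer(length(branch_names)), branch_names)
  losses <- setNames(integer(length(branch_names)), branch_names)
  counter <- 0L
  extant <- list()
  current_subfam <- NA_character_
  gene_leaf <- function(species) {
    counter <<- counter + 1L
    id <- sprintf("%s_g%03d", family, counter)
    label <- paste0(species, "|", id)
    extant[[length(extant) + 1L]] <<-
      data.frame(species = species, gene_id = id,
                 subfamily = current_subfam, label = label,
                 stringsAsFactors = FALSE)
    list(label = label, len = 0, support = NA_real_, kids = list())
  }
  join2 <- function(a, b, len) list(label = "", len = len,
                                    support = NA_real_, kids = list(a, b))
  at_node <- function(nd_sp) {
    if (length(nd_sp$kids) == 0L) return(gene_leaf(nd_sp$label))
    parts <- lapply(nd_sp$kids, function(k) on_branch(k, k$len))
    parts <- parts[!vapply(parts, is.null, TRUE)]
    if (length(parts) == 0L) return(NULL)
    if (length(parts) == 1L) return(parts[[1L]])
    Reduce(function(a, b) join2(a, b, 0), parts)
  }
  on_branch <- function(nd_sp, t_remain) {
    rate <- lambda + mu
    wait <- if (rate > 0) rexp(1L, rate) else Inf
    if (wait >= t_remain) {
      res <- at_node(nd_sp)
      if (is.null(res)) return(NULL)
      res$len <- res$len + t_remain
      return(res)
    }
    if (runif(1L) < lambda / rate) {
      births[nd_sp$label] <<- births[nd_sp$label] + 1L
      l <- on_branch(nd_sp, t_remain - wait)
      r <- on_branch(nd_sp, t_remain - wait)
      if (is.null(l) && is.null(r)) return(NULL)
      if (is.null(l)) { r$len <- r$len + wait; return(r) }
      if (is.null(r)) { l$len <- l$len + wait; return(l) }
      return(join2(l, r, wait))
    }
    losses[nd_sp$label] <<- losses[nd_sp$label] + 1L
    NULL
  }
  roots <- list()
  for (i in seq_len(root_copies)) {
    current_subfam <- subfamilies[i]
    sub <- at_node(sp)
    if (!is.null(sub)) {
      sub$len <- sub$len + subfamily_stem
      roots[[length(roots) + 1L]] <- sub
    }
  }
  extant_df <- if (length(extant)) do.call(rbind, extant) else
    data.frame(species = character(), gene_id = character(),
               subfamily = character(), label = character(),
               stringsAsFactors = FALSE)
  if (length(roots) == 0L) {
    return(list(tree = NULL, births = births, losses = losses,
                extant = extant_df, extinct = TRUE))
  }
  combined <- if (length(roots) == 1L) roots[[1L]] else
    Reduce(function(a, b) join2(a, b, 0), roots)
  list(tree = gene_tree_phylo(combined), births = births, losses = losses,
       extant = extant_df, extinct = FALSE)
}

# nested gene tree -> phylo, handling the single-leaf case
gene_tree_phylo <- function(nd) {
  if (length(nd$kids) == 0L) {
    return(ape::read.tree(text = sprintf("(%s:%.10g);", nd$label, nd$len)))
  }
  rtree_to_phylo(nd)
}

#' Evolve protein sequences along a gene tree
#'
#' Sites evolve independently under a continuous-time Markov chain with
#' total substitution rate `rate` per site per time unit, starting from
#' `root_seq`: either the equal-rates 20-state chain (`"poisson"`,
#' default) or the empirical JTT exchangeabilities (`"jtt"`), via
#' `phangorn::simSeq`.
#'
#' @param tree rooted `phylo` with branch lengths in time units
#' @param root_seq amino-acid string at the root (20 standard residues)
#' @param rate substitution rate per site per time unit (>= 0)
#' @param model `"poisson"` or `"jtt"`
#' @param rng_seed optional seed; omit to use the current RNG stream
#' @return a proteome `data.frame` with one row per gene-tree leaf
#' @export
simulate_sequences <- function(tree, root_seq, rate,
                               model = c("poisson", "jtt"),
                               rng_seed = NULL) {
  model <- match.arg(model)
  stopifnot(rate >= 0)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  rs <- strsplit(toupper(root_seq), "")[[1]]
  if (!all(rs %in% AA_RESIDUES)) stop("root_seq must use the 20 residues")
  if (rate == 0) {
    seqs <- setNames(rep(root_seq, length(tree$tip.label)), tree$tip.label)
  } else {
    sim <- if (model == "poisson") {
      phangorn::simSeq(tree, l = length(rs), type = "AA",
                       bf = rep(1 / 20, 20), Q = rep(1, 190),
                       rootseq = rs, rate = rate)
    } else {
      phangorn::simSeq(tree, l = length(rs), type = "AA", model = "JTT",
                       rootseq = rs, rate = rate)
    }
    m <- toupper(as.character(sim))
    seqs <- setNames(apply(m, 1, paste, collapse = ""), rownames(m))
    seqs <- seqs[tree$tip.label]
  }
  sp <- sub("\\|.*$", "", names(seqs))
  id <- sub("^.*\\|", "", names(seqs))
  proteome(id, sp, unname(seqs))
}

#' Append random decoy proteins to each proteome
#'
#' Decoys have uniform residue composition, ids `"decoy_NN"`, and no
#' entry in any domain table, so they exercise the domain filter.
#'
#' @param proteomes named list of proteome `data.frame`s
#' @param n_decoys decoys per species (0 = unchanged)
#' @param length_range integer range of decoy lengths
#' @param rng_seed optional seed
#' @return the proteome list with decoys appended
#' @export
add_decoys <- function(proteomes, n_decoys, length_range = c(150L, 450L),
                       rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (n_decoys == 0L) return(proteomes)
  for (sp in names(proteomes)) {
    lens <- sample(length_range[1]:length_range[2], n_decoys, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(AA_RESIDUES, L, replace = TRUE), collapse = "")
    }, "")
    dec <- proteome(sprintf("decoy_%02d", seq_len(n_decoys)),
                    rep(sp, n_decoys), seqs)
    proteomes[[sp]] <- rbind(proteomes[[sp]], dec)
  }
  proteomes
}

#' Default simulation configuration
#'
#' Three families spanning the three default substitution-rate levels
#' (fast / intermediate / slow, echoing the observed ordering of the
#' detoxification families), two subfamilies each planted as independent
#' root lineages, moderate birth-death turnover, and five decoys per
#' species. Rates are chosen so that cross-species identities fall in
#' the 30-80% range typical of real detoxification families, keeping all
#' members detectable by the seeded search.
#'
#' @param seed RNG seed for the whole study
#' @param species_tree species tree (default [default_species_tree()])
#' @param n_decoys decoys per species
#' @param seq_length root sequence length (amino acids)
#' @return a named list understood by [simulate_study()] and
#'   [make_fixture()]
#' @export
default_sim_config <- function(seed = 1L,
                               species_tree = default_species_tree(),
                               n_decoys = 5L, seq_length = 300L) {
  list(
    species_tree = species_tree,
    families = data.frame(
      name = c("P450", "CCE", "GST"),
      birth_rate = 0.2, loss_rate = 0.05, root_copies = 2L,
      subst_rate = c(0.15, 0.08, 0.03),
      seq_length = seq_length,
      required_domain = c("IPR001128", "IPR002018", "IPR004045"),
      stringsAsFactors = FALSE),
    subfamilies = list(P450 = c("CYP3", "CYP4"),
                       CCE = c("CCEA", "CCEB"),
                       GST = c("Delta", "Sigma")),
    subfamily_stem = 2,
    n_decoys = n_decoys,
    decoy_length = c(150L, 450L),
    seed_species = "A_pisum",
    seed = as.integer(seed))
}

#' Simulate a complete in-memory study set
#'
#' Runs the birth-death and sequence simulators for every configured
#' family under one seeded RNG stream and assembles the objects every
#' pipeline stage consumes: per-species proteomes (with decoys), the
#' domain table, per-family seed sets (the seed species' members), the
#' subfamily reference labels, and the full ground truth. A family whose
#' lineages all die out is resimulated (the truth records the number of
#' attempts).
#'
#' @param config a list as from [default_sim_config()]
#' @return list with `proteomes`, `domains`, `seed_sets`,
#'   `required_domains`, `references`, `species_tree`, `truth`
#' @export
simulate_study <- function(config = default_sim_config()) {
  set.seed(config$seed)
  S <- config$species_tree
  species <- S$tip.label
  fam_truth <- list()
  proteome_rows <- list()
  domains <- list()
  seed_sets <- list()
  required <- list()
  references <- list()
  for (i in seq_len(nrow(config$families))) {
    f <- config$families[i, ]
    attempts <- 0L
    repeat {
      attempts <- attempts + 1L
      sim <- simulate_gene_tree(S, f$birth_rate, f$loss_rate,
                                root_copies = f$root_copies,
                                family = f$name,
                                subfamilies = config$subfamilies[[f$name]],
                                subfamily_stem = config$subfamily_stem)
      if (!sim$extinct || attempts >= 100L) break
    }
    if (sim$extinct) stop("family ", f$name, " went extinct 100 times")
    root_seq <- paste(sample(AA_RESIDUES, f$seq_length, replace = TRUE),
                      collapse = "")
    prot <- simulate_sequences(sim$tree, root_seq, f$subst_rate)
    prot$family <- f$name
    prot$subfamily <- sim$extant$subfamily[match(full_id(prot),
                                                 sim$extant$label)]
    proteome_rows[[f$name]] <- prot
    for (lab in sim$extant$label) domains[[lab]] <- f$required_domain
    # curated seed sets cover every subfamily: the seed species' members,
    # plus (as a second seed species) the best-populated species for any
    # subfamily the seed species happens to lack
    seed_rows <- prot[prot$species == config$seed_species, , drop = FALSE]
    for (sub in setdiff(unique(prot$subfamily), unique(seed_rows$subfamily))) {
      sub_rows <- prot[prot$subfamily == sub, , drop = FALSE]
      best <- names(sort(table(sub_rows$species), decreasing = TRUE))[1]
      seed_rows <- rbind(seed_rows,
                         sub_rows[sub_rows$species == best, , drop = FALSE])
    }
    seed_sets[[f$name]] <- seed_rows
    required[[f$name]] <- f$required_domain
    ref <- seed_rows
    references <- c(references, as.list(setNames(ref$subfamily,
                                                 full_id(ref))))
    fam_truth[[f$name]] <- list(
      tree = ape::write.tree(sim$tree),
      births = as.list(sim$births), losses = as.list(sim$losses),
      extant = sim$extant, subst_rate = f$subst_rate,
      attempts = attempts)
  }
  proteomes <- lapply(setNames(species, species), function(sp) {
    rows <- lapply(proteome_rows, function(p) {
      p[p$species == sp, , drop = FALSE]
    })
    df <- do.call(rbind, rows)
    rownames(df) <- NULL
    df
  })
  proteomes <- add_decoys(proteomes, config$n_decoys, config$decoy_length)
  list(proteomes = proteomes, domains = domains, seed_sets = seed_sets,
       required_domains = required,
       references = unlist(references),
       species_tree = S,
       truth = list(families = fam_truth,
                    species_tree = ape::write.tree(S),
                    seed = config$seed))
}

#' Write a simulated study bundle to disk
#'
#' Writes per-species proteome FASTAs, the domain table, per-family seed
#' FASTAs, the subfamily reference table, the species tree, the ground
#' truth JSON, a JSON echo of the configuration, and a manifest with an
#' MD5 checksum per file. Regenerating with the same seed reproduces the
#' bundle byte for byte.
#'
#' @param config a list as from [default_sim_config()]
#' @param dir output directory (created if needed)
#' @return invisibly, the manifest data.frame
#' @export
make_fixture <- function(config = default_sim_config(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- simulate_study(config)
  files <- character(0)
  wr <- function(fname) { files <<- c(files, fname); file.path(dir, fname) }
  write_newick(bundle$species_tree, wr("species_tree.nwk"))
  for (sp in names(bundle$proteomes)) {
    write_fasta(bundle$proteomes[[sp]], wr(sprintf("proteome_%s.fasta", sp)))
  }
  for (fam in names(bundle$seed_sets)) {
    write_fasta(bundle$seed_sets[[fam]], wr(sprintf("seeds_%s.fasta", fam)))
  }
  write_domain_table(bundle$domains, wr("domains.tsv"))
  writeLines(paste0(names(bundle$references), "\t", bundle$references),
             wr("references.tsv"))
  jsonlite::write_json(
    list(families = config$families,
         subfamilies = config$subfamilies,
         subfamily_stem = config$subfamily_stem,
         n_decoys = config$n_decoys,
         decoy_length = config$decoy_length,
         seed_species = config$seed_species,
         required_domains = bundle$required_domains,
         seed = config$seed),
    wr("config.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(bundle$truth, wr("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(dir, files))),
    stringsAsFactors = FALSE)
  write.table(manifest, file.path(dir, "MANIFEST.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
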
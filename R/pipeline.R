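# End-to-end orchestration over an on-disk study bundle: annotate ->
# gene trees -> reconciliation -> rate comparison. Every stage reads its
# inputs from files, writes fixed-precision outputs (identities to 3
# decimals) and a provenance JSON (config echo, seed, package version,
# input checksums), so a run is reproducible byte for byte from
# config + seed.

#' Pipeline run configuration
#'
#' @param fixture_dir directory holding the study bundle (as written by
#'   [make_fixture()]): `species_tree.nwk`, `proteome_*.fasta`,
#'   `seeds_*.fasta`, `domains.tsv`, `references.tsv`, `config.json`
#' @param out_dir output directory (created if needed)
#' @param e_threshold,min_alignment_columns search parameters
#' @param collapse_threshold bootstrap support below which branches are
#'   collapsed before reconciliation (default 70)
#' @param bootstrap_reps bootstrap replicates for gene trees
#' @param max_gap_fraction column-trimming threshold for MSAs
#' @param seed RNG seed for every stochastic stage
#' @return an object of class `run_config`
#' @export
run_config <- function(fixture_dir, out_dir,
                       e_threshold = 1e-5, min_alignment_columns = 30L,
                       collapse_threshold = 70, bootstrap_reps = 1000L,
                       max_gap_fraction = 0.5, seed = 1L) {
  stopifnot(dir.exists(fixture_dir))
  structure(list(fixture_dir = fixture_dir, out_dir = out_dir,
                 e_threshold = e_threshold,
                 min_alignment_columns = as.integer(min_alignment_columns),
                 collapse_threshold = collapse_threshold,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 max_gap_fraction = max_gap_fraction,
                 seed = as.integer(seed)),
            class = "run_config")
}

pl_inputs <- function(cfg) {
  d <- cfg$fixture_dir
  need <- function(f) {
    p <- file.path(d, f)
    if (!file.exists(p)) stop("missing input: ", p)
    p
  }
  prot_files <- sort(list.files(d, pattern = "^proteome_.*\\.fasta$"))
  seed_files <- sort(list.files(d, pattern = "^seeds_.*\\.fasta$"))
  if (length(prot_files) == 0L) stop("no proteome_*.fasta in ", d)
  species_tree <- read_newick(need("species_tree.nwk"))
  proteomes <- lapply(file.path(d, prot_files), read_fasta)
  names(proteomes) <- sub("^proteome_(.*)\\.fasta$", "\\1", prot_files)
  seed_sets <- lapply(file.path(d, seed_files), read_fasta)
  names(seed_sets) <- sub("^seeds_(.*)\\.fasta$", "\\1", seed_files)
  fixture_cfg <- jsonlite::read_json(need("config.json"))
  required <- lapply(fixture_cfg$required_domains, unlist)
  refs_df <- read.delim(need("references.tsv"), header = FALSE,
                        col.names = c("label", "subfamily"),
                        stringsAsFactors = FALSE)
  list(species_tree = species_tree,
       proteomes = proteomes, seed_sets = seed_sets,
       domains = read_domain_table(need("domains.tsv")),
       required_domains = required,
       references = setNames(refs_df$subfamily, refs_df$label),
       input_files = file.path(d, c("species_tree.nwk", prot_files,
                                    seed_files, "domains.tsv",
                                    "references.tsv", "config.json")))
}

pl_provenance <- function(cfg, stage, inputs) {
  out <- file.path(cfg$out_dir, sprintf("provenance_%s.json", stage))
  jsonlite::write_json(
    list(stage = stage,
         package_version = as.character(utils::packageVersion("famevol")),
         seed = cfg$seed,
         config = unclass(cfg)[setdiff(names(unclass(cfg)), "out_dir")],
         input_checksums = as.list(tools::md5sum(inputs$input_files))),
    out, auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}

pl_members <- function(cand, proteomes) {
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    p <- proteomes[[cand$species[i]]]
    p[p$gene_id == cand$gene_id[i], c("gene_id", "species", "sequence")]
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

#' Run the annotation stage
#'
#' Seeded search + reciprocal expansion + domain filtering for every
#' family; writes `candidates.tsv` (family, species, gene_id,
#' round_found) and `counts.csv` (per-species family counts in species
#' tree tip order).
#'
#' @param cfg a [run_config()]
#' @return invisibly, the candidate data.frame
#' @export
run_annotate <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- pl_inputs(cfg)
  params <- search_params(cfg$e_threshold,
                          min_alignment_columns = cfg$min_alignment_columns)
  cand <- annotate_families(inputs$proteomes, inputs$seed_sets,
                            inputs$domains, inputs$required_domains, params)
  cand <- cand[order(cand$family, cand$species, cand$gene_id), ]
  write.table(cand, file.path(cfg$out_dir, "candidates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  counts <- family_count_table(cand,
                               species_order = inputs$species_tree$tip.label,
                               families = sort(names(inputs$seed_sets)))
  write.table(counts, file.path(cfg$out_dir, "counts.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  pl_provenance(cfg, "annotate", inputs)
  invisible(cand)
}

#' Run the gene-tree stage
#'
#' Per family: progressive alignment of all members, gap-column
#' trimming, NJ tree with bootstrap supports. Writes
#' `msa_<family>.fasta` and `genetree_<family>.nwk`.
#'
#' @param cfg a [run_config()]
#' @return invisibly, a named list of `phylo` trees
#' @export
run_tree <- function(cfg) {
  inputs <- pl_inputs(cfg)
  cand <- read.delim(file.path(cfg$out_dir, "candidates.tsv"),
                     stringsAsFactors = FALSE)
  trees <- list()
  fams <- sort(unique(cand$family))
  for (k in seq_along(fams)) {
    fam <- fams[k]
    members <- pl_members(cand[cand$family == fam, ], inputs$proteomes)
    if (nrow(members) < 3L) {
      warning("family ", fam, " has fewer than 3 members; no tree built")
      next
    }
    gt <- build_gene_tree(members, n_reps = cfg$bootstrap_reps,
                          rng_seed = cfg$seed + k,
                          max_gap_fraction = cfg$max_gap_fraction)
    set <- Biostrings::AAStringSet(gt$msa$seqs)
    names(set) <- gt$msa$ids
    Biostrings::writeXStringSet(set, file.path(cfg$out_dir,
                                               sprintf("msa_%s.fasta", fam)),
                                width = 70L)
    write_newick(gt$tree, file.path(cfg$out_dir,
                                    sprintf("genetree_%s.nwk", fam)))
    trees[[fam]] <- gt$tree
  }
  pl_provenance(cfg, "tree", inputs)
  invisible(trees)
}

#' Run the reconciliation stage
#'
#' Per family: collapse branches below the support threshold, root at
#' minimum DL cost (resolving polytomies exactly), reconcile, and write
#' `events_<family>.csv` (branch, gains, losses), ancestral copies, and
#' a cross-family `reconciliation_summary.csv`.
#'
#' @param cfg a [run_config()]
#' @return invisibly, a named list of `reconciliation` objects
#' @export
run_reconcile <- function(cfg) {
  inputs <- pl_inputs(cfg)
  tree_files <- sort(list.files(cfg$out_dir, pattern = "^genetree_.*\\.nwk$"))
  out <- list()
  summary_rows <- list()
  for (f in tree_files) {
    fam <- sub("^genetree_(.*)\\.nwk$", "\\1", f)
    G <- read_newick(file.path(cfg$out_dir, f))
    res <- reconcile_gene_tree(G, inputs$species_tree,
                               collapse_threshold = cfg$collapse_threshold)
    ev <- data.frame(branch = names(res$gains_per_branch),
                     gains = unname(res$gains_per_branch),
                     losses = unname(res$losses_per_branch),
                     stringsAsFactors = FALSE)
    write.table(ev, file.path(cfg$out_dir, sprintf("events_%s.csv", fam)),
                sep = ",", quote = FALSE, row.names = FALSE)
    cp <- data.frame(node = names(res$ancestral_copies),
                     copies = unname(res$ancestral_copies),
                     stringsAsFactors = FALSE)
    write.table(cp, file.path(cfg$out_dir,
                              sprintf("ancestral_copies_%s.csv", fam)),
                sep = ",", quote = FALSE, row.names = FALSE)
    summary_rows[[fam]] <- data.frame(
      family = fam, duplications = sum(res$gains_per_branch),
      losses = sum(res$losses_per_branch), total_cost = res$total_cost,
      stringsAsFactors = FALSE)
    out[[fam]] <- res
  }
  write.table(do.call(rbind, summary_rows),
              file.path(cfg$out_dir, "reconciliation_summary.csv"),
              sep = ",", quote = FALSE, row.names = FALSE)
  pl_provenance(cfg, "reconcile", inputs)
  invisible(out)
}

#' Run the rate-comparison stage
#'
#' Builds identity samples for every family and every subfamily (leaves
#' classified against the labelled reference genes on the family tree),
#' writes the raw identities, the per-group summaries, and the
#' within-versus-among rank report with its inversion count.
#'
#' @param cfg a [run_config()]
#' @return invisibly, the summary data.frame
#' @export
run_rates <- function(cfg) {
  inputs <- pl_inputs(cfg)
  cand <- read.delim(file.path(cfg$out_dir, "candidates.tsv"),
                     stringsAsFactors = FALSE)
  fams <- sort(unique(cand$family))
  groups <- list()
  for (fam in fams) {
    members <- pl_members(cand[cand$family == fam, ], inputs$proteomes)
    groups[[fam]] <- list(kind = "family", members = members)
    tf <- file.path(cfg$out_dir, sprintf("genetree_%s.nwk", fam))
    if (file.exists(tf)) {
      tr <- read_newick(tf)
      cls <- classify_subfamilies(tr, inputs$references)
      for (sub in setdiff(sort(unique(cls)), "unassigned")) {
        ids <- names(cls)[cls == sub]
        groups[[sub]] <- list(kind = "subfamily",
                              members = members[full_id(members) %in% ids, ])
      }
    }
  }
  id_rows <- list(); sum_rows <- list()
  for (g in names(groups)) {
    members <- groups[[g]]$members
    for (scope in c("within", "among")) {
      sample <- if (scope == "within") within_all_identities(members) else
        suppressMessages(among_species_identities(members))
      if (length(sample$values) == 0L) next
      id_rows[[paste(g, scope)]] <- data.frame(
        group = g, kind = groups[[g]]$kind, scope = scope,
        pident = sprintf("%.3f", sample$values), stringsAsFactors = FALSE)
      s <- summarize_identities(sample)
      sum_rows[[paste(g, scope)]] <- data.frame(
        group = g, kind = groups[[g]]$kind, scope = scope,
        mean = sprintf("%.3f", s$mean), sd = sprintf("%.3f", s$sd),
        lower_quartile = sprintf("%.3f", s$lower_quartile),
        median = sprintf("%.3f", s$median),
        upper_quartile = sprintf("%.3f", s$upper_quartile),
        count = s$count, stringsAsFactors = FALSE)
    }
  }
  identities <- do.call(rbind, id_rows)
  summaries <- do.call(rbind, sum_rows)
  rownames(identities) <- rownames(summaries) <- NULL
  write.table(identities, file.path(cfg$out_dir, "identities.csv"),
              sep = ",", quote = FALSE, row.names = FALSE)
  write.table(summaries, file.path(cfg$out_dir, "identity_summaries.csv"),
              sep = ",", quote = FALSE, row.names = FALSE)
  rank_rows <- list()
  for (kind in unique(summaries$kind)) {
    sk <- summaries[summaries$kind == kind, ]
    wi <- sk[sk$scope == "within", c("group", "mean")]
    am <- sk[sk$scope == "among", c("group", "mean")]
    shared <- intersect(wi$group, am$group)
    if (length(shared) < 2L) next
    wi <- wi[wi$group %in% shared, ]; am <- am[am$group %in% shared, ]
    wi$mean <- as.numeric(wi$mean); am$mean <- as.numeric(am$mean)
    cmp <- compare_within_vs_among(wi, am)
    rank_rows[[kind]] <- data.frame(
      kind = kind,
      within_order = paste(cmp$within_order, collapse = " > "),
      among_order = paste(cmp$among_order, collapse = " > "),
      n_inversions = cmp$n_inversions, stringsAsFactors = FALSE)
  }
  ranks <- do.call(rbind, rank_rows)
  rownames(ranks) <- NULL
  write.table(ranks, file.path(cfg$out_dir, "rank_report.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  pl_provenance(cfg, "rates", inputs)
  invisible(summaries)
}

#' Run the full pipeline
#'
#' Chains [run_annotate()], [run_tree()], [run_reconcile()] and
#' [run_rates()]. With a fixed seed the run is reproducible byte for
#' byte.
#'
#' @param cfg a [run_config()]
#' @return invisibly, `cfg`
#' @export
run_all <- function(cfg) {
  run_annotate(cfg)
  run_tree(cfg)
  run_reconcile(cfg)
  run_rates(cfg)
  invisible(cfg)
}
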